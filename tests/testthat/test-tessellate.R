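test_that("repeated detections of one steady emitter collapse to one", {
  locs <- data.frame(frame = 0:4, x_um = 1 + c(0, 1, -1, 2, 0) * 0.01,
                     y_um = 2, intensity = 1, sigma_um = 0,
                     molecule_id = 1L)
  m <- mergeBlinkingDetections(locs, tessConfig(merge_radius_um = 0.05))
  expect_identical(nrow(m), 1L)
  expect_identical(m$n_merged, 5L)
  expect_equal(m$x_um, mean(locs$x_um))
})

test_that("simultaneous distant detections stay separate", {
  locs <- data.frame(frame = c(0L, 0L), x_um = c(1, 2), y_um = 1,
                     intensity = 1, sigma_um = 0, molecule_id = 1:2)
  m <- mergeBlinkingDetections(locs, tessConfig(merge_radius_um = 0.05))
  expect_identical(nrow(m), 2L)
})

test_that("blinking within the gap limit merges, beyond it splits", {
  mk <- function(dark) data.frame(frame = c(0L, 1L, 2L + dark, 3L + dark),
                                  x_um = 1, y_um = 1, intensity = 1,
                                  sigma_um = 0, molecule_id = 1L)
  cfg <- tessConfig(merge_radius_um = 0.05, merge_max_gap_frames = 3)
  expect_identical(nrow(mergeBlinkingDetections(mk(3), cfg)), 1L)
  expect_identical(nrow(mergeBlinkingDetections(mk(4), cfg)), 2L)
})

test_that("merged output of a simulated blinking field matches truth", {
  sim <- simulateTracks(sptSimConfig(n_frames = 200, n_molecules = 15,
                                     fov_um = 12, d_mobile = 0,
                                     d_immobile = 0, f_immobile = 1,
                                     loc_sigma_um = 0.005,
                                     p_activate = 0.02, p_bleach = 0.05,
                                     p_blink_off = 0.2, p_blink_on = 0.6,
                                     seed = 71))
  m <- mergeBlinkingDetections(sim$localizations,
                               tessConfig(merge_radius_um = 0.05,
                                          merge_max_gap_frames = 3))
  # merging can only reduce rows, never below the molecule count
  expect_lte(nrow(m), nrow(sim$localizations))
  expect_gte(nrow(m), length(unique(sim$localizations$molecule_id)))
})

test_that("interior cells of a square grid have exact area and density", {
  s <- 0.5
  g <- expand.grid(x = s / 2 + s * 0:5, y = s / 2 + s * 0:5)
  vm <- voronoiDensities(cbind(g$x, g$y), region = c(0, 3, 0, 3))
  interior <- !borderCells(vm)
  expect_gt(sum(interior), 0)
  expect_equal(cellAreas(vm)[interior], rep(s^2, sum(interior)),
               tolerance = 1e-9)
  expect_equal(localDensities(vm)[interior], rep(1 / s^2, sum(interior)),
               tolerance = 1e-9)
})

test_that("a bare triangle is clipped everywhere and fully border-flagged", {
  xy <- rbind(c(0.2, 0.2), c(0.8, 0.3), c(0.5, 0.8))
  vm <- voronoiDensities(xy, region = c(0, 1, 0, 1))
  expect_true(all(borderCells(vm)))
  expect_equal(sum(cellAreas(vm)), 1, tolerance = 1e-3)
})

test_that("clipped cell areas sum to the region area", {
  for (s in 1:3) {
    p <- simulatePattern(patternSimConfig(mode = "thomas", seed = s))
    vm <- voronoiDensities(p$localizations, region = c(0, 10, 0, 10))
    expect_equal(sum(cellAreas(vm)), 100, tolerance = 1e-3)
  }
})

test_that("Poisson-Voronoi interior mean cell area is 1/lambda", {
  p <- simulatePattern(patternSimConfig(mode = "csr",
                                        background_intensity = 30,
                                        seed = 72))
  expect_gte(nrow(p$localizations), 2000)
  vm <- voronoiDensities(p$localizations, region = c(0, 10, 0, 10))
  lam <- nrow(p$localizations) / 100
  interior <- !borderCells(vm)
  expect_equal(mean(cellAreas(vm)[interior]) * lam, 1, tolerance = 0.05)
})

test_that("degenerate point sets are rejected informatively", {
  line <- cbind(1:5, 2 * (1:5))
  expect_error(voronoiDensities(line), "collinear")
  expect_error(voronoiDensities(cbind(1, 1)), "at least 3")
  dup <- rbind(c(1, 1), c(1, 1), c(2, 2), c(3, 1))
  expect_warning(vm <- voronoiDensities(dup, region = c(0, 4, 0, 4)),
                 "duplicated")
  expect_identical(nrow(vm@points), 3L)
})

test_that("a uniform grid contains no nanodomains", {
  g <- expand.grid(x = 0.25 + 0.5 * 0:5, y = 0.25 + 0.5 * 0:5)
  vm <- voronoiDensities(cbind(g$x, g$y), region = c(0, 3, 0, 3))
  nd <- segmentNanodomains(vm, tessConfig())
  expect_identical(nDomains(nd), 0L)
})

test_that("one dense blob yields exactly one domain above 25 detections", {
  blob <- simulatePattern(patternSimConfig(mode = "thomas",
                                           region_um = c(0, 4, 0, 4),
                                           background_intensity = 2,
                                           n_clusters = 1,
                                           points_per_cluster_mean = 60,
                                           cluster_sigma_um = 0.04,
                                           seed = 73))
  vm <- voronoiDensities(blob$localizations, region = c(0, 4, 0, 4))
  nd <- segmentNanodomains(vm, tessConfig())
  expect_identical(nDomains(nd), 1L)
  expect_gte(domains(nd)$n_detections, 25)
  # same geometry but too few members fails the detection-count filter
  small <- simulatePattern(patternSimConfig(mode = "thomas",
                                            region_um = c(0, 4, 0, 4),
                                            background_intensity = 2,
                                            n_clusters = 1,
                                            points_per_cluster_mean = 20,
                                            cluster_sigma_um = 0.04,
                                            seed = 73))
  vm2 <- voronoiDensities(small$localizations, region = c(0, 4, 0, 4))
  nd2 <- segmentNanodomains(vm2, tessConfig())
  expect_identical(nDomains(nd2), 0L)
})

test_that("domain components equal an exhaustive adjacency search", {
  p <- simulatePattern(patternSimConfig(mode = "thomas",
                                        region_um = c(0, 3, 0, 3),
                                        background_intensity = 5,
                                        n_clusters = 3,
                                        points_per_cluster_mean = 40,
                                        cluster_sigma_um = 0.05,
                                        seed = 74))
  expect_lte(nrow(p$localizations), 200)
  vm <- voronoiDensities(p$localizations, region = c(0, 3, 0, 3))
  cfg <- tessConfig(min_detections = 5)
  nd <- segmentNanodomains(vm, cfg)
  seeds <- which(localDensities(vm) > 50 * avgDensity(vm))
  adj <- cellAdjacency(vm)
  edges <- adj[adj[, 1] %in% seeds & adj[, 2] %in% seeds, , drop = FALSE]
  comp <- oracleComponents(seeds, edges)
  comp <- comp[lengths(comp) >= 5]
  norm <- function(l) unname(lapply(l[order(vapply(l, min, numeric(1)))],
                                    function(v) sort(as.integer(v))))
  expect_identical(norm(domainMembers(nd)), norm(comp))
})

test_that("stricter thresholds never create more domains", {
  p <- simulatePattern(patternSimConfig(mode = "thomas", seed = 75))
  vm <- voronoiDensities(p$localizations, region = c(0, 10, 0, 10))
  n50 <- nDomains(segmentNanodomains(vm, tessConfig(density_factor = 50)))
  n80 <- nDomains(segmentNanodomains(vm, tessConfig(density_factor = 80)))
  expect_lte(n80, n50)
  n_min40 <- nDomains(segmentNanodomains(vm, tessConfig(min_detections = 40)))
  expect_lte(n_min40, n50)
})

test_that("domain metrics follow their definitions", {
  g <- expand.grid(x = 0.25 + 0.5 * 0:5, y = 0.25 + 0.5 * 0:5)
  vm <- voronoiDensities(cbind(g$x, g$y), region = c(0, 3, 0, 3))
  nd0 <- segmentNanodomains(vm, tessConfig())
  met0 <- nanodomainMetrics(nd0, vm)
  expect_true(is.na(met0$mean_diameter_um))
  expect_identical(met0$relative_count, 0)
  expect_identical(met0$domain_density_um2, 0)

  blob <- simulatePattern(patternSimConfig(mode = "thomas",
                                           region_um = c(0, 4, 0, 4),
                                           background_intensity = 2,
                                           n_clusters = 1,
                                           points_per_cluster_mean = 60,
                                           cluster_sigma_um = 0.04,
                                           seed = 73))
  vm1 <- voronoiDensities(blob$localizations, region = c(0, 4, 0, 4))
  nd1 <- segmentNanodomains(vm1, tessConfig())
  met1 <- nanodomainMetrics(nd1, vm1)
  expect_equal(met1$relative_count,
               domains(nd1)$n_detections / nrow(vm1@points))
  expect_equal(met1$domain_density_um2, 1 / 16)
  expect_equal(domains(nd1)$equiv_diameter_um,
               2 * sqrt(domains(nd1)$area_um2 / pi))
})
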
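test_that("zero-diffusion, zero-noise molecules never move", {
  sim <- simulateTracks(sptSimConfig(n_frames = 30, n_molecules = 20,
                                     d_mobile = 0, d_immobile = 0,
                                     loc_sigma_um = 0, p_activate = 1,
                                     p_bleach = 0, p_blink_off = 0,
                                     seed = 1))
  spread <- tapply(sim$localizations$x_um, sim$localizations$molecule_id,
                   function(v) diff(range(v)))
  expect_true(all(spread == 0))
  spread_y <- tapply(sim$localizations$y_um, sim$localizations$molecule_id,
                     function(v) diff(range(v)))
  expect_true(all(spread_y == 0))
})

test_that("mixture fraction boundaries produce pure populations", {
  s0 <- simulateTracks(sptSimConfig(n_frames = 5, n_molecules = 50,
                                    f_immobile = 0, seed = 2))
  expect_false(any(s0$truth$molecules$class == "immobile"))
  s1 <- simulateTracks(sptSimConfig(n_frames = 5, n_molecules = 50,
                                    f_immobile = 1, seed = 2))
  expect_true(all(s1$truth$molecules$class == "immobile"))
})

test_that("per-step mean squared displacement matches 4 D dt", {
  sim <- calibSim(n_molecules = 600, n_frames = 12, d_mobile = 0.05,
                  loc_sigma_um = 0, fov_um = 30, seed = 3)
  pos <- sim$truth$positions
  d2 <- unlist(lapply(split(pos, pos$molecule_id), function(p) {
    diff(p$x_true)^2 + diff(p$y_true)^2
  }))
  expect_equal(mean(d2), 4 * 0.05 * 0.03, tolerance = 0.05)
})

test_that("identical config and seed give byte-identical output", {
  cfg <- sptSimConfig(n_frames = 40, n_molecules = 30, seed = 11,
                      p_activate = 0.1)
  expect_identical(simulateTracks(cfg), simulateTracks(cfg))
})

test_that("every localization maps to a known ground-truth molecule", {
  sim <- simulateTracks(sptSimConfig(n_frames = 100, n_molecules = 40,
                                     p_activate = 0.05, seed = 4))
  expect_true(all(sim$localizations$molecule_id %in%
                    sim$truth$molecules$molecule_id))
  expect_lte(length(unique(sim$localizations$molecule_id)), 40)
})

test_that("time-averaged MSD grows linearly with lag for mobile tracks", {
  sim <- calibSim(n_molecules = 500, n_frames = 25, d_mobile = 0.05,
                  loc_sigma_um = 0.02, seed = 5)
  ts <- filterTracks(trueTracks(sim$localizations), 7)
  locs <- localizations(ts)
  msd_by_lag <- sapply(1:4, function(k) {
    d2 <- unlist(lapply(split(locs, locs$track_id), function(p) {
      p <- p[order(p$frame), ]
      n <- nrow(p)
      if (n <= k) return(NULL)
      (p$x_um[(1 + k):n] - p$x_um[1:(n - k)])^2 +
        (p$y_um[(1 + k):n] - p$y_um[1:(n - k)])^2
    }))
    mean(d2)
  })
  fit <- summary(lm(msd_by_lag ~ I(1:4)))
  expect_gt(fit$r.squared, 0.99)
})

test_that("invalid physical parameters are rejected by field name", {
  expect_error(sptSimConfig(d_mobile = -1), "d_mobile")
  expect_error(sptSimConfig(p_bleach = 1.4), "p_bleach")
  expect_error(sptSimConfig(frame_interval_s = 0), "frame_interval_s")
  expect_error(sptSimConfig(f_immobile = 2), "f_immobile")
})

test_that("CSR point count is Poisson with intensity lambda area", {
  lam <- 40
  p <- simulatePattern(patternSimConfig(mode = "csr",
                                        background_intensity = lam,
                                        region_um = c(0, 10, 0, 10),
                                        seed = 6))
  n <- nrow(p$localizations)
  expect_lt(abs(n - lam * 100), 4 * sqrt(lam * 100))
  expect_true(all(p$truth$points$cluster_id == 0))
})

test_that("single-cluster pattern stays near its centre", {
  p <- simulatePattern(patternSimConfig(mode = "thomas",
                                        background_intensity = 0,
                                        n_clusters = 1,
                                        points_per_cluster_mean = 50,
                                        cluster_sigma_um = 0.04, seed = 7))
  expect_true(all(p$truth$points$cluster_id == 1))
  ctr <- p$truth$centers
  r <- sqrt((p$localizations$x_um - ctr$cx)^2 +
              (p$localizations$y_um - ctr$cy)^2)
  expect_lt(max(r), 5 * 0.04)
})

test_that("clustered patterns have far smaller NN distances than CSR", {
  p <- simulatePattern(patternSimConfig(mode = "thomas", seed = 8))
  xy <- cbind(p$localizations$x_um, p$localizations$y_um)
  nn_med <- median(oracleNN(xy))
  lam_hat <- nrow(xy) / 100
  csr_expect <- 1 / (2 * sqrt(lam_hat))
  expect_lt(nn_med, csr_expect / 2)
})

test_that("rendering obeys closed-form expectations", {
  # empty input, zero background
  st0 <- renderFrames(data.frame(frame = integer(), x_um = numeric(),
                                 y_um = numeric()),
                      bg_level = 0, noise = FALSE, dims = c(16, 16))
  expect_true(all(st0@data == 0))
  # single spot at a pixel centre: maximum at that pixel
  loc <- data.frame(frame = 0L, x_um = 0.8, y_um = 0.5)
  st1 <- renderFrames(loc, psf_sigma_um = 0.15, photons = 300,
                      bg_level = 0, pixel_um = 0.1, dims = c(32, 32),
                      noise = FALSE)
  m <- getFrame(st1, 1)
  expect_equal(unname(which(m == max(m), arr.ind = TRUE)[1, ]),
               c(0.5 / 0.1 + 1, 0.8 / 0.1 + 1))
  # flux conservation within integration truncation
  expect_equal(sum(m), 300, tolerance = 0.01)
  # frame count = max frame index + 1
  st2 <- renderFrames(data.frame(frame = c(0L, 4L), x_um = 1, y_um = 1),
                      bg_level = 0, noise = FALSE, dims = c(16, 16))
  expect_identical(nFrames(st2), 5L)
})

test_that("out-of-field localizations are clipped with a message", {
  loc <- data.frame(frame = 0L, x_um = c(1, 99), y_um = c(1, 1))
  expect_message(st <- renderFrames(loc, bg_level = 0, noise = FALSE,
                                    dims = c(16, 16)),
                 "clipped")
})
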
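test_that("an empty stack yields an empty localization table", {
  st <- methods::new("ImageStack", data = array(0, c(16, 16, 3)),
                     pixelUm = 0.1, channel = "t")
  det <- detectSpots(st, linkConfig())
  expect_identical(nrow(det), 0L)
})

test_that("a noise-free spot is found within half a pixel", {
  loc <- data.frame(frame = 0L, x_um = 2.13, y_um = 1.67)
  st <- renderFrames(loc, psf_sigma_um = 0.15, photons = 500,
                     bg_level = 0, pixel_um = 0.1, dims = c(48, 48),
                     noise = FALSE)
  det <- detectSpots(st, linkConfig())
  expect_identical(nrow(det), 1L)
  expect_lt(abs(det$x_um - 2.13), 0.05)
  expect_lt(abs(det$y_um - 1.67), 0.05)
})

test_that("a field of well-separated spots is fully recovered", {
  g <- expand.grid(x = 0.8 + 0:4 * 1.0, y = 0.8 + 0:4 * 1.0)
  locs <- data.frame(frame = 0L, x_um = g$x, y_um = g$y)
  set.seed(21)
  st <- renderFrames(locs, psf_sigma_um = 0.15, photons = 2000,
                     bg_level = 20, pixel_um = 0.1, dims = c(60, 60),
                     noise = TRUE)
  det <- detectSpots(st, linkConfig())
  expect_identical(nrow(det), 25L)
  # brute-force match: each detection to its nearest true spot
  d <- sapply(seq_len(nrow(det)), function(i)
    min(sqrt((g$x - det$x_um[i])^2 + (g$y - det$y_um[i])^2)))
  expect_true(all(d < 0.1))
  expect_identical(length(unique(apply(
    cbind(det$x_um, det$y_um), 1, function(p)
      which.min((g$x - p[1])^2 + (g$y - p[2])^2)))), 25L)
})

test_that("one continuously visible molecule becomes one track", {
  f <- 0:19
  locs <- data.frame(frame = f, x_um = 1 + 0.02 * f, y_um = 2,
                     intensity = 1, sigma_um = 0, molecule_id = 1L)
  ts <- linkTracks(locs, linkConfig(max_disp_um = 0.1))
  expect_identical(nTracks(ts), 1L)
  expect_identical(trackInfo(ts)$n_locs, 20L)
})

test_that("blink gaps are bridged up to max_gap and split beyond it", {
  mk <- function(dark) {
    f <- c(0:4, (5 + dark):(9 + dark))
    data.frame(frame = f, x_um = 1, y_um = 1, intensity = 1,
               sigma_um = 0, molecule_id = 1L)
  }
  cfg <- linkConfig(max_disp_um = 0.3, max_gap = 3)
  bridged <- linkTracks(mk(3), cfg)
  expect_identical(nTracks(bridged), 1L)
  expect_identical(trackInfo(bridged)$gaps[[1]], 3L)
  split <- linkTracks(mk(4), cfg)
  expect_identical(nTracks(split), 2L)
})

test_that("distant parallel molecules never swap identity", {
  max_disp <- 0.3
  f <- 0:99
  locs <- data.frame(frame = rep(f, 2),
                     x_um = rep(0.05 * f, 2),
                     y_um = rep(c(1, 1 + 10 * max_disp), each = 100),
                     intensity = 1, sigma_um = 0,
                     molecule_id = rep(1:2, each = 100))
  ts <- linkTracks(locs, linkConfig(max_disp_um = max_disp))
  expect_identical(nTracks(ts), 2L)
  locs_out <- localizations(ts)
  y_by_track <- tapply(locs_out$y_um, locs_out$track_id,
                       function(v) diff(range(v)))
  expect_true(all(y_by_track == 0))
})

test_that("links equal the exhaustive minimal-displacement assignment", {
  set.seed(31)
  for (rep in 1:5) {
    n_mol <- sample(2:4, 1)
    n_f <- 25
    # generously separated molecules with small diffusive steps
    base_y <- seq_len(n_mol) * 3
    locs <- do.call(rbind, lapply(seq_len(n_mol), function(m) {
      data.frame(frame = 0:(n_f - 1),
                 x_um = cumsum(c(m, rnorm(n_f - 1, 0, 0.05))),
                 y_um = cumsum(c(base_y[m], rnorm(n_f - 1, 0, 0.05))),
                 intensity = 1, sigma_um = 0, molecule_id = m)
    }))
    locs <- locs[order(locs$frame), ]
    rownames(locs) <- seq_len(nrow(locs))
    ts <- linkTracks(locs, linkConfig(max_disp_um = 0.5, max_gap = 0))
    expect_identical(nTracks(ts), n_mol)
    mine <- lapply(split(seq_len(nrow(locs)),
                         localizations(ts)$track_id),
                   as.integer)
    oracle <- oracleLinkSmall(locs)
    norm <- function(l) unname(l[order(vapply(l, min, numeric(1)))])
    expect_identical(norm(mine), norm(oracle))
  }
})

test_that("every localization joins at most one track, gaps bounded", {
  sim <- simulateTracks(sptSimConfig(n_frames = 80, n_molecules = 25,
                                     fov_um = 8, p_activate = 0.3,
                                     p_blink_off = 0.1, p_blink_on = 0.4,
                                     p_bleach = 0.02, seed = 41))
  cfg <- linkConfig(max_gap = 3)
  ts <- linkTracks(sim$localizations, cfg)
  locs <- localizations(ts)
  expect_identical(nrow(locs), nrow(sim$localizations))
  expect_false(any(duplicated(
    locs[, c("frame", "x_um", "y_um", "track_id")])))
  jumps <- unlist(tapply(locs$frame, locs$track_id, diff))
  expect_lte(max(jumps), cfg$max_gap + 1L)
})

test_that("the step filter keeps exactly the long-enough tracks", {
  mk <- function(n, id, y) data.frame(frame = seq_len(n) - 1L, x_um = 1,
                                      y_um = y, intensity = 1,
                                      sigma_um = 0, molecule_id = id)
  locs <- rbind(mk(8, 1L, 1), mk(7, 2L, 5), mk(2, 3L, 9))
  ts <- linkTracks(locs, linkConfig(max_disp_um = 0.5))
  kept <- filterTracks(ts, min_steps = 7)
  expect_identical(nTracks(kept), 1L)         # 7 steps = 8 localizations
  expect_identical(trackInfo(kept)$n_steps, 7L)
  empty <- filterTracks(kept, min_steps = 100)
  expect_identical(nTracks(empty), 0L)
  expect_identical(nrow(localizations(empty)), 0L)
})

test_that("duplicate rows are collapsed with a warning", {
  locs <- data.frame(frame = c(0L, 0L, 1L), x_um = c(1, 1, 1.01),
                     y_um = 1, intensity = 1, sigma_um = 0,
                     molecule_id = 1L)
  expect_warning(ts <- linkTracks(locs, linkConfig(max_disp_um = 0.1)),
                 "duplicate")
  expect_identical(nrow(localizations(ts)), 2L)
})
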
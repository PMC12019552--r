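# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# exhaustive ordered-pair MSD
oracleMSD <- function(frame, x, y, dt_s) {
  ks <- sort(unique(as.vector(outer(frame, frame, "-"))))
  ks <- ks[ks > 0]
  out <- NULL
  for (k in ks) {
    s <- 0; n <- 0
    for (i in seq_along(frame)) for (j in seq_along(frame)) {
      if (frame[j] - frame[i] == k) {
        s <- s + (x[j] - x[i])^2 + (y[j] - y[i])^2
        n <- n + 1
      }
    }
    out <- rbind(out, c(k * dt_s, s / n, n))
  }
  data.frame(lag_s = out[, 1], msd_um2 = out[, 2], n_pairs = out[, 3])
}

# brute-force nearest-neighbour distances
oracleNN <- function(xy) {
  n <- nrow(xy)
  vapply(seq_len(n), function(i) {
    d2 <- (xy[-i, 1] - xy[i, 1])^2 + (xy[-i, 2] - xy[i, 2])^2
    sqrt(min(d2))
  }, numeric(1))
}

# exhaustive minimal-total-displacement frame-to-frame assignment for
# tiny instances: at every frame all permutations of (previous point ->
# current point) matchings are scored; no gaps, equal point counts
oracleLinkSmall <- function(locs) {
  frames <- sort(unique(locs$frame))
  prev <- locs[locs$frame == frames[1], ]
  track_of <- list()
  for (i in seq_len(nrow(prev))) track_of[[i]] <- rownames(prev)[i]
  prev_track <- seq_len(nrow(prev))
  for (f in frames[-1]) {
    cur <- locs[locs$frame == f, ]
    stopifnot(nrow(cur) == nrow(prev))
    perms <- .permutations(nrow(cur))
    cost <- apply(perms, 1, function(p)
      sum(sqrt((prev$x_um - cur$x_um[p])^2 + (prev$y_um - cur$y_um[p])^2)))
    best <- perms[which.min(cost), ]
    new_track <- integer(nrow(cur))
    for (i in seq_len(nrow(prev))) {
      t <- prev_track[i]
      track_of[[t]] <- c(track_of[[t]], rownames(cur)[best[i]])
      new_track[best[i]] <- t
    }
    prev <- cur
    prev_track <- new_track
  }
  lapply(track_of, as.integer)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

# exhaustive connected components over an undirected edge list
oracleComponents <- function(nodes, edges) {
  comp <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      a <- as.character(edges[e, 1]); b <- as.character(edges[e, 2])
      if (comp[a] != comp[b]) {
        m <- min(comp[a], comp[b])
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(nodes, comp)
}

# exact two-sided permutation p-value for a difference in means
oraclePermutationP <- function(a, b) {
  v <- c(a, b)
  n <- length(a)
  obs <- abs(mean(a) - mean(b))
  idx <- utils::combn(length(v), n)
  stat <- apply(idx, 2, function(i)
    abs(mean(v[i]) - mean(v[-i])))
  mean(stat >= obs - 1e-12)
}

# shared generator for diffusion-calibration style simulations:
# continuous tracks (no blinking/bleaching), every molecule active from
# frame 0, in a field large enough that boundary losses are rare
calibSim <- function(n_molecules, n_frames, d_mobile, f_immobile = 0,
                     d_immobile = 0.001, loc_sigma_um = 0.02, fov_um = 20,
                     seed = 1) {
  simulateTracks(sptSimConfig(
    frame_interval_s = 0.03, n_frames = n_frames, fov_um = fov_um,
    n_molecules = n_molecules, d_mobile = d_mobile,
    d_immobile = d_immobile, f_immobile = f_immobile,
    loc_sigma_um = loc_sigma_um, p_activate = 1, p_bleach = 0,
    p_blink_off = 0, p_blink_on = 0, seed = seed))
}

# render a tracking field, detect, link, and score link correctness
# against ground truth (attribution radius 0.2 um = 2 px)
linkAccuracy <- function(seed, photons = 2000, n_molecules = 12) {
  cfg <- sptSimConfig(n_frames = 60, n_molecules = n_molecules,
                      fov_um = 6.3, p_activate = 1, p_bleach = 0,
                      p_blink_off = 0.05, p_blink_on = 0.5,
                      d_mobile = 0.08, f_immobile = 0.3,
                      loc_sigma_um = 0, seed = seed)
  sim <- simulateTracks(cfg)
  set.seed(seed + 7777)
  stack <- renderFrames(sim$localizations, psf_sigma_um = 0.15,
                        photons = photons, bg_level = 20, pixel_um = 0.1,
                        dims = c(64, 64), noise = TRUE)
  det <- detectSpots(stack, linkConfig())
  ts <- linkTracks(det, linkConfig())
  locs <- localizations(ts)
  locs$mol <- NA_integer_
  for (i in seq_len(nrow(locs))) {
    tr <- sim$localizations[sim$localizations$frame == locs$frame[i], ]
    d <- sqrt((tr$x_um - locs$x_um[i])^2 + (tr$y_um - locs$y_um[i])^2)
    if (length(d) && min(d) < 0.2)
      locs$mol[i] <- tr$molecule_id[which.min(d)]
  }
  ok <- tot <- 0
  for (id in trackInfo(ts)$track_id) {
    m <- locs$mol[locs$track_id == id]
    m <- m[order(locs$frame[locs$track_id == id])]
    if (length(m) < 2) next
    good <- !is.na(m[-length(m)]) & !is.na(m[-1]) & m[-length(m)] == m[-1]
    ok <- ok + sum(good); tot <- tot + length(good)
  }
  c(ok = ok, tot = tot)
}

# synthetic FRET cell field: disks of elevated Venus signal with a fixed
# true FRET/Venus ratio, Poisson noise in both channels
fretField <- function(ratio, n_cells = 6, seed = 1, side = 200,
                      bg_f = 40, bg_v = 50, amp = 400) {
  set.seed(seed)
  ven <- matrix(bg_v, side, side)
  fre <- matrix(bg_f, side, side)
  masks <- list()
  for (i in seq_len(n_cells)) {
    cx <- 30 + ((i - 1) %% 3) * 65
    cy <- 30 + ((i - 1) %/% 3) * 65
    m <- outer(seq_len(side), seq_len(side),
               function(r, c) (r - cy)^2 + (c - cx)^2 <= 20^2)
    ven[m] <- ven[m] + amp
    fre[m] <- fre[m] + ratio * amp
    masks[[i]] <- m
  }
  list(venus = matrix(rpois(side^2, ven), side),
       fret = matrix(rpois(side^2, fre), side),
       masks = masks, bg = c(bg_f, bg_v))
}
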
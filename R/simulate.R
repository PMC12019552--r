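## Ground-truthed synthetic sptPALM data. Molecules diffuse in an
## unbounded plane; only localizations falling inside the square field of
## view are emitted, which avoids reflecting-boundary artefacts in MSD
## statistics. Photophysics is an explicit per-frame Markov chain:
## inactive -> (p_activate) -> emitting <-> dark, with an absorbing
## bleached state reachable from the emitting state.

.STATE_INACTIVE <- 0L
.STATE_ON <- 1L
.STATE_DARK <- 2L
.STATE_BLEACHED <- 3L

#' Simulate sptPALM trajectories with ground truth
#'
#' Generates a localization table emulating a sparse photoactivation
#' acquisition: each molecule is mobile or immobile (two-population
#' Brownian mixture), activates stochastically, blinks and bleaches,
#' and every emitted localization is the true position plus isotropic
#' Gaussian localization noise. Dark (blinked) frames emit nothing.
#'
#' @param config an [sptSimConfig()] object.
#' @return a list with elements \code{localizations} (data.frame
#'   \code{frame, x_um, y_um, intensity, sigma_um, molecule_id}) and
#'   \code{truth} (list of \code{molecules} — per-molecule class, true
#'   D, start position, activation frame — and \code{positions}, the
#'   noise-free trajectory at every emitting frame, including points
#'   that left the field of view).
#' @examples
#' sim <- simulateTracks(sptSimConfig(n_frames = 50, n_molecules = 20,
#'                                    p_activate = 0.2, seed = 1))
#' head(sim$localizations)
#' @export
simulateTracks <- function(config) {
  stopifnot(inherits(config, "SptSimConfig"))
  if (!is.null(config$seed)) set.seed(config$seed)
  nm <- config$n_molecules
  nf <- config$n_frames
  dt <- config$frame_interval_s

  immobile <- stats::runif(nm) < config$f_immobile
  d_true <- ifelse(immobile, config$d_immobile, config$d_mobile)
  x0 <- stats::runif(nm, 0, config$fov_um)
  y0 <- stats::runif(nm, 0, config$fov_um)

  ## photophysics: one uniform draw per molecule per frame drives the
  ## transition out of its current state
  state <- rep(.STATE_INACTIVE, nm)
  on_mat <- matrix(FALSE, nrow = nf, ncol = nm)
  for (f in seq_len(nf)) {
    u <- stats::runif(nm)
    inact <- state == .STATE_INACTIVE
    state[inact & u < config$p_activate] <- .STATE_ON
    on_mat[f, ] <- state == .STATE_ON
    on <- state == .STATE_ON
    dark <- state == .STATE_DARK
    u2 <- stats::runif(nm)
    state[on & u2 < config$p_bleach] <- .STATE_BLEACHED
    still_on <- state == .STATE_ON & on
    state[still_on & u2 >= config$p_bleach &
            u2 < config$p_bleach + (1 - config$p_bleach) * config$p_blink_off] <-
      .STATE_DARK
    state[dark & u2 < config$p_blink_on] <- .STATE_ON
  }

  ## Brownian paths: per-axis step SD sqrt(2 D dt), simulated for every
  ## frame whether or not the molecule is visible
  step_sd <- sqrt(2 * d_true * dt)
  xs <- matrix(stats::rnorm(nf * nm, sd = rep(step_sd, each = nf)), nf, nm)
  ys <- matrix(stats::rnorm(nf * nm, sd = rep(step_sd, each = nf)), nf, nm)
  xs[1, ] <- x0; ys[1, ] <- y0
  xt <- apply(xs, 2, cumsum)
  yt <- apply(ys, 2, cumsum)
  if (nf == 1L) { xt <- matrix(xt, 1); yt <- matrix(yt, 1) }

  idx <- which(on_mat, arr.ind = TRUE)  # (frame, molecule) of emissions
  true_x <- xt[idx]; true_y <- yt[idx]
  obs_x <- true_x + stats::rnorm(nrow(idx), sd = config$loc_sigma_um)
  obs_y <- true_y + stats::rnorm(nrow(idx), sd = config$loc_sigma_um)
  inside <- obs_x >= 0 & obs_x <= config$fov_um &
    obs_y >= 0 & obs_y <= config$fov_um

  n_out <- sum(inside)
  locs <- data.frame(frame = as.integer(idx[inside, 1] - 1L),
                     x_um = obs_x[inside], y_um = obs_y[inside],
                     intensity = stats::rgamma(n_out, shape = 4,
                                               scale = 250),
                     sigma_um = rep(config$loc_sigma_um, n_out),
                     molecule_id = as.integer(idx[inside, 2]))
  locs <- locs[order(locs$frame, locs$molecule_id), , drop = FALSE]
  rownames(locs) <- NULL

  first_on <- rep(NA_integer_, nm)
  if (nrow(idx)) {
    fo <- tapply(idx[, 1], idx[, 2], min)
    first_on[as.integer(names(fo))] <- as.integer(fo) - 1L
  }
  molecules <- data.frame(molecule_id = seq_len(nm),
                          class = ifelse(immobile, "immobile", "mobile"),
                          d_true = d_true, x0 = x0, y0 = y0,
                          activation_frame = first_on)
  positions <- data.frame(molecule_id = idx[, 2], frame = idx[, 1] - 1L,
                          x_true = true_x, y_true = true_y)
  positions <- positions[order(positions$molecule_id, positions$frame), ,
                         drop = FALSE]
  rownames(positions) <- NULL
  list(localizations = locs,
       truth = list(molecules = molecules, positions = positions,
                    config = config))
}

#' Simulate spatial point patterns (CSR or Thomas clusters)
#'
#' CSR mode draws a homogeneous Poisson process over the rectangle.
#' Thomas mode places \code{n_clusters} centres uniformly, disperses a
#' Poisson(\code{points_per_cluster_mean}) number of offspring around
#' each with an isotropic Gaussian, and adds a CSR background; offspring
#' landing outside the region are discarded (the cluster spread is tiny
#' relative to the region, so the loss is negligible).
#'
#' @param config a [patternSimConfig()] object.
#' @return a list with \code{localizations} (all points at frame 0) and
#'   \code{truth} (data.frame \code{point_id, cluster_id}; cluster 0 is
#'   background, and for CSR all points are cluster 0; plus the centre
#'   coordinates in \code{centers}).
#' @export
simulatePattern <- function(config) {
  stopifnot(inherits(config, "PatternSimConfig"))
  if (!is.null(config$seed)) set.seed(config$seed)
  r <- config$region_um
  area <- (r[2] - r[1]) * (r[4] - r[3])

  n_bg <- stats::rpois(1, config$background_intensity * area)
  x <- stats::runif(n_bg, r[1], r[2])
  y <- stats::runif(n_bg, r[3], r[4])
  cluster_id <- rep(0L, n_bg)
  centers <- data.frame(cluster_id = integer(), cx = numeric(),
                        cy = numeric())

  if (config$mode == "thomas" && config$n_clusters > 0) {
    cx <- stats::runif(config$n_clusters, r[1], r[2])
    cy <- stats::runif(config$n_clusters, r[3], r[4])
    n_off <- stats::rpois(config$n_clusters, config$points_per_cluster_mean)
    ox <- rep(cx, n_off) + stats::rnorm(sum(n_off),
                                        sd = config$cluster_sigma_um)
    oy <- rep(cy, n_off) + stats::rnorm(sum(n_off),
                                        sd = config$cluster_sigma_um)
    oid <- rep(seq_len(config$n_clusters), n_off)
    keep <- ox >= r[1] & ox <= r[2] & oy >= r[3] & oy <= r[4]
    x <- c(x, ox[keep]); y <- c(y, oy[keep])
    cluster_id <- c(cluster_id, oid[keep])
    centers <- data.frame(cluster_id = seq_len(config$n_clusters),
                          cx = cx, cy = cy)
  }

  n <- length(x)
  locs <- data.frame(frame = rep(0L, n), x_um = x, y_um = y,
                     intensity = rep(1, n), sigma_um = rep(0, n),
                     molecule_id = rep(-1L, n))
  list(localizations = locs,
       truth = list(points = data.frame(point_id = seq_len(n),
                                        cluster_id = cluster_id),
                    centers = centers, config = config))
}

#' Render localizations into a synthetic image stack
#'
#' Draws each localization as a pixel-integrated 2-D Gaussian point
#' spread function scaled to \code{photons}, over a constant background,
#' with optional Poisson shot noise on signal plus background. Pixel
#' (row, col) (0-based) is centred at (col*pixel_um, row*pixel_um).
#'
#' @param locs localization data.frame with \code{frame, x_um, y_um}.
#' @param psf_sigma_um PSF Gaussian SD, µm.
#' @param photons expected photon count per localization.
#' @param bg_level expected background photons per pixel per frame.
#' @param pixel_um pixel size, µm (> 0).
#' @param dims image size \code{c(ny, nx)} in pixels.
#' @param noise apply Poisson shot noise (TRUE) or return noise-free
#'   expectations (FALSE).
#' @param n_frames number of frames; default max frame index + 1.
#' @return an [ImageStack-class]; localizations outside the field are
#'   clipped and their count reported via a message.
#' @export
renderFrames <- function(locs, psf_sigma_um = 0.15, photons = 500,
                         bg_level = 10, pixel_um = 0.1,
                         dims = c(64L, 64L), noise = TRUE,
                         n_frames = NULL) {
  .checkPos(pixel_um, "pixel_um")
  .checkPos(psf_sigma_um, "psf_sigma_um")
  ny <- as.integer(dims[1]); nx <- as.integer(dims[2])
  if (is.null(n_frames))
    n_frames <- if (nrow(locs)) max(locs$frame) + 1L else 1L
  stack <- array(bg_level, dim = c(ny, nx, n_frames))

  xmax <- (nx - 1) * pixel_um; ymax <- (ny - 1) * pixel_um
  out <- locs$x_um < -pixel_um / 2 | locs$x_um > xmax + pixel_um / 2 |
    locs$y_um < -pixel_um / 2 | locs$y_um > ymax + pixel_um / 2
  if (any(out))
    message(sum(out), " localization(s) outside the field were clipped")
  use <- locs[!out, , drop = FALSE]

  half <- ceiling(4 * psf_sigma_um / pixel_um)
  for (i in seq_len(nrow(use))) {
    cx <- use$x_um[i] / pixel_um   # pixel coordinates (0-based centres)
    cy <- use$y_um[i] / pixel_um
    cols <- max(0L, floor(cx) - half):min(nx - 1L, ceiling(cx) + half)
    rows <- max(0L, floor(cy) - half):min(ny - 1L, ceiling(cy) + half)
    s <- psf_sigma_um / pixel_um
    px <- stats::pnorm(cols + 0.5, cx, s) - stats::pnorm(cols - 0.5, cx, s)
    py <- stats::pnorm(rows + 0.5, cy, s) - stats::pnorm(rows - 0.5, cy, s)
    f <- use$frame[i] + 1L
    stack[rows + 1L, cols + 1L, f] <- stack[rows + 1L, cols + 1L, f] +
      photons * outer(py, px)
  }
  if (noise)
    stack[] <- stats::rpois(length(stack), lambda = stack)
  methods::new("ImageStack", data = stack, pixelUm = pixel_um,
               channel = "synthetic")
}
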
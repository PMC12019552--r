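## Parameter bundles are validated plain lists: cheap to build in scripts
## and YAML round-trippable. Each constructor rejects invalid physics with
## a message naming the offending field.

.checkProb <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  x
}

.checkPos <- function(x, name, strict = TRUE) {
  ok <- length(x) == 1L && is.finite(x) && (if (strict) x > 0 else x >= 0)
  if (!ok)
    stop(sprintf("'%s' must be a finite %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  x
}

#' Configuration for sptPALM trajectory simulation
#'
#' Defaults emulate the acquisition geometry of a root-cell sptPALM
#' experiment with a photoconvertible mEOS2 tag: 7000 frames at 30 ms
#' exposure, localization precision about 20 nm, and a two-population
#' (mobile/immobile) Brownian mixture whose diffusion coefficients
#' straddle the 0.01 µm²/s mobility threshold. mEOS2 photophysics rates
#' are not published for this system; the activation, blinking and
#' bleaching defaults are stated assumptions chosen to give sparse
#' activation and track lengths comparable to experiment, not measured
#' values.
#'
#' @param frame_interval_s frame interval Δt in seconds.
#' @param n_frames number of acquisition frames.
#' @param fov_um side of the square field of view, µm.
#' @param n_molecules number of ground-truth molecules in the field.
#' @param d_mobile,d_immobile diffusion coefficients of the two
#'   populations, µm²/s (d_mobile > d_immobile >= 0). The immobile
#'   default is kept slightly above zero so log-D histograms stay
#'   well defined; exact zero is reserved for analytic tests.
#' @param f_immobile fraction of molecules in the immobile population.
#' @param loc_sigma_um isotropic Gaussian localization noise SD, µm.
#' @param p_activate per-frame photoactivation probability of a
#'   not-yet-activated molecule.
#' @param p_bleach per-frame irreversible bleaching probability while
#'   emitting (absorbing state).
#' @param p_blink_off,p_blink_on per-frame blinking transition
#'   probabilities (on->dark, dark->on).
#' @param max_true_gap frames a blinked molecule may stay dark and
#'   still count as one emitter in ground-truth bookkeeping.
#' @param seed RNG seed (integer) or NULL to leave the RNG state alone.
#' @return a validated list of class "SptSimConfig".
#' @export
sptSimConfig <- function(frame_interval_s = 0.03, n_frames = 7000,
                         fov_um = 10, n_molecules = 200,
                         d_mobile = 0.08, d_immobile = 0.001,
                         f_immobile = 0.3, loc_sigma_um = 0.02,
                         p_activate = 0.002, p_bleach = 0.05,
                         p_blink_off = 0.1, p_blink_on = 0.5,
                         max_true_gap = 3, seed = NULL) {
  .checkPos(frame_interval_s, "frame_interval_s")
  .checkPos(fov_um, "fov_um")
  .checkPos(n_frames, "n_frames"); .checkPos(n_molecules, "n_molecules")
  .checkPos(d_mobile, "d_mobile", strict = FALSE)
  .checkPos(d_immobile, "d_immobile", strict = FALSE)
  if (d_mobile < d_immobile)
    stop("'d_mobile' must be >= 'd_immobile'", call. = FALSE)
  .checkProb(f_immobile, "f_immobile")
  .checkPos(loc_sigma_um, "loc_sigma_um", strict = FALSE)
  .checkProb(p_activate, "p_activate")
  .checkProb(p_bleach, "p_bleach")
  .checkProb(p_blink_off, "p_blink_off")
  .checkProb(p_blink_on, "p_blink_on")
  .checkPos(max_true_gap, "max_true_gap", strict = FALSE)
  structure(list(frame_interval_s = frame_interval_s,
                 n_frames = as.integer(n_frames), fov_um = fov_um,
                 n_molecules = as.integer(n_molecules),
                 d_mobile = d_mobile, d_immobile = d_immobile,
                 f_immobile = f_immobile, loc_sigma_um = loc_sigma_um,
                 p_activate = p_activate, p_bleach = p_bleach,
                 p_blink_off = p_blink_off, p_blink_on = p_blink_on,
                 max_true_gap = as.integer(max_true_gap), seed = seed),
            class = "SptSimConfig")
}

#' Configuration for spatial point-pattern simulation
#'
#' Generates either complete spatial randomness (homogeneous Poisson
#' process) or a Thomas-style cluster pattern: \code{n_clusters} cluster
#' centres placed uniformly in the region, each with a
#' Poisson(\code{points_per_cluster_mean}) number of offspring dispersed
#' by an isotropic Gaussian of SD \code{cluster_sigma_um}, on top of a
#' CSR background of intensity \code{background_intensity}.
#'
#' @param mode "csr" or "thomas".
#' @param region_um rectangle \code{c(xmin, xmax, ymin, ymax)}, µm.
#' @param background_intensity background point intensity, points/µm².
#' @param n_clusters number of cluster centres (thomas mode).
#' @param points_per_cluster_mean mean offspring per cluster.
#' @param cluster_sigma_um Gaussian cluster spread, µm.
#' @param seed RNG seed or NULL.
#' @return a validated list of class "PatternSimConfig".
#' @export
patternSimConfig <- function(mode = c("csr", "thomas"),
                             region_um = c(0, 10, 0, 10),
                             background_intensity = 5,
                             n_clusters = 30, points_per_cluster_mean = 60,
                             cluster_sigma_um = 0.04, seed = NULL) {
  mode <- match.arg(mode)
  if (length(region_um) != 4L || region_um[2] <= region_um[1] ||
      region_um[4] <= region_um[3])
    stop("'region_um' must be c(xmin, xmax, ymin, ymax) with positive area",
         call. = FALSE)
  .checkPos(background_intensity, "background_intensity", strict = FALSE)
  if (mode == "thomas") {
    .checkPos(n_clusters, "n_clusters", strict = FALSE)
    .checkPos(points_per_cluster_mean, "points_per_cluster_mean",
              strict = FALSE)
    .checkPos(cluster_sigma_um, "cluster_sigma_um")
  }
  structure(list(mode = mode, region_um = region_um,
                 background_intensity = background_intensity,
                 n_clusters = as.integer(n_clusters),
                 points_per_cluster_mean = points_per_cluster_mean,
                 cluster_sigma_um = cluster_sigma_um, seed = seed),
            class = "PatternSimConfig")
}

#' Configuration for spot detection and trajectory linking
#'
#' @param max_disp_um maximum frame-to-frame linking displacement, µm.
#'   The default corresponds to 3 sqrt(4 D Δt) for an expected mobile
#'   D of 0.08 µm²/s at Δt = 30 ms.
#' @param max_gap maximum number of consecutive dark frames bridged
#'   inside one track (mEOS2 blinking tolerance).
#' @param detect_threshold detection threshold as a multiple of the MAD
#'   of the band-passed frame above its median.
#' @param min_spot_separation_um minimum separation between accepted
#'   detections in one frame, µm.
#' @param gap_radius_scaling "linear" grows the gap-closing search
#'   radius as max_disp_um*(gap+1); "sqrt" as max_disp_um*sqrt(gap+1)
#'   (diffusive scaling).
#' @return a validated list of class "LinkConfig".
#' @export
linkConfig <- function(max_disp_um = 3 * sqrt(4 * 0.08 * 0.03),
                       max_gap = 3, detect_threshold = 8,
                       min_spot_separation_um = 0.3,
                       gap_radius_scaling = c("linear", "sqrt")) {
  .checkPos(max_disp_um, "max_disp_um")
  .checkPos(max_gap, "max_gap", strict = FALSE)
  .checkPos(detect_threshold, "detect_threshold")
  .checkPos(min_spot_separation_um, "min_spot_separation_um", strict = FALSE)
  structure(list(max_disp_um = max_disp_um, max_gap = as.integer(max_gap),
                 detect_threshold = detect_threshold,
                 min_spot_separation_um = min_spot_separation_um,
                 gap_radius_scaling = match.arg(gap_radius_scaling)),
            class = "LinkConfig")
}

#' Configuration for Voronoi nanodomain segmentation
#'
#' The segmentation thresholds follow the SR-Tesseler convention used
#' for plant membrane nanodomains: a localization seeds a domain when
#' its local density exceeds \code{density_factor} times the average
#' density of the analysis region, and a connected component is kept
#' as a nanodomain only when it holds at least \code{min_detections}
#' localizations.
#'
#' @param density_factor multiple of the average density a seed must
#'   exceed (default 50).
#' @param min_detections minimum detections per retained domain
#'   (default 25).
#' @param merge_radius_um spatial radius for collapsing repeated
#'   detections of one blinking emitter, µm.
#' @param merge_max_gap_frames dark-frame tolerance of the merge
#'   (defaults to the tracking gap tolerance, 3).
#' @param avg_mode how the reference average density is computed:
#'   "global" = N / region area; "per_point" = mean of local densities.
#' @return a validated list of class "TessConfig".
#' @export
tessConfig <- function(density_factor = 50, min_detections = 25,
                       merge_radius_um = 0.05, merge_max_gap_frames = 3,
                       avg_mode = c("global", "per_point")) {
  .checkPos(density_factor, "density_factor")
  if (min_detections < 1) stop("'min_detections' must be >= 1", call. = FALSE)
  .checkPos(merge_radius_um, "merge_radius_um")
  .checkPos(merge_max_gap_frames, "merge_max_gap_frames", strict = FALSE)
  structure(list(density_factor = density_factor,
                 min_detections = as.integer(min_detections),
                 merge_radius_um = merge_radius_um,
                 merge_max_gap_frames = as.integer(merge_max_gap_frames),
                 avg_mode = match.arg(avg_mode)),
            class = "TessConfig")
}
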
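#' Time-averaged mean squared displacement of one track
#'
#' For each lag k (frames), averages the squared planar displacement
#' over all ordered localization pairs (i, j) with frame_j - frame_i =
#' k. Pairs spanning bridged blink gaps contribute at their true frame
#' difference; lags with no admissible pair are omitted.
#'
#' @param track data.frame with \code{frame, x_um, y_um} (one track).
#' @param dt_s frame interval, seconds.
#' @param max_lag largest lag (frames) to evaluate; default: the track's
#'   full frame span.
#' @return data.frame \code{lag_s, msd_um2, n_pairs} with strictly
#'   increasing lags.
#' @export
computeMSD <- function(track, dt_s, max_lag = Inf) {
  f <- track$frame
  if (length(f) < 2L)
    stop("track has fewer than 2 localizations; MSD undefined")
  x <- track$x_um; y <- track$y_um
  span <- max(f) - min(f)
  K <- min(span, max_lag)
  lag <- msd <- np <- numeric(0)
  for (k in seq_len(K)) {
    j <- match(f + k, f)
    ok <- which(!is.na(j))
    if (!length(ok)) next
    jj <- j[ok]
    d2 <- (x[jj] - x[ok])^2 + (y[jj] - y[ok])^2
    lag <- c(lag, k * dt_s)
    msd <- c(msd, mean(d2))
    np <- c(np, length(ok))
  }
  data.frame(lag_s = lag, msd_um2 = msd, n_pairs = as.integer(np))
}

#' Fit the instantaneous diffusion coefficient from an MSD curve
#'
#' Ordinary least squares through the first \code{n_points} available
#' (lag, MSD) pairs, with a free intercept by default. For 2-D Brownian
#' motion MSD = 4 D tau + 4 sigma_loc^2, so D = slope /
#' \code{dim_factor} with dim_factor = 4. Non-positive slopes are
#' floored to \code{d_floor} and flagged, which keeps log-D histograms
#' defined; floored tracks are far below any mobility threshold and
#' classify as immobile.
#'
#' @param msd an MSD curve from [computeMSD()].
#' @param n_points number of initial lags fitted (default 4).
#' @param dim_factor MSD-to-D conversion constant (4 for 2-D).
#' @param fit_intercept fit a free intercept (TRUE) or force it
#'   through zero (FALSE).
#' @param d_floor floor for non-positive slope estimates, µm²/s.
#' @param threshold mobility classification threshold, µm²/s.
#' @param track_id id carried into the result.
#' @return one-row data.frame \code{track_id, d_um2_s, intercept_um2,
#'   mobility, flag, n_fit_points}.
#' @export
fitDiffusion <- function(msd, n_points = 4, dim_factor = 4,
                         fit_intercept = TRUE, d_floor = 1e-5,
                         threshold = 0.01, track_id = NA_integer_) {
  if (nrow(msd) < n_points)
    stop(sprintf("track %s: %d MSD lag(s) available, %d required for the fit",
                 track_id, nrow(msd), n_points))
  tau <- msd$lag_s[seq_len(n_points)]
  m <- msd$msd_um2[seq_len(n_points)]
  if (fit_intercept) {
    mt <- mean(tau); mm <- mean(m)
    slope <- sum((tau - mt) * (m - mm)) / sum((tau - mt)^2)
    icpt <- mm - slope * mt
  } else {
    slope <- sum(tau * m) / sum(tau^2)
    icpt <- 0
  }
  flag <- slope <= 0
  d <- if (flag) d_floor else slope / dim_factor
  data.frame(track_id = track_id, d_um2_s = d, intercept_um2 = icpt,
             mobility = if (d < threshold) "immobile" else "mobile",
             flag = flag, n_fit_points = as.integer(n_points))
}

#' Per-track diffusion estimates for a whole TrackSet
#'
#' Runs [computeMSD()] and [fitDiffusion()] on every track; tracks with
#' fewer available lags than \code{n_points} are skipped with a count
#' reported via a message (they should normally be removed upstream by
#' [filterTracks()]).
#'
#' @param tracks a [TrackSet-class].
#' @param dt_s frame interval, seconds.
#' @param ... passed to [fitDiffusion()].
#' @param n_points number of initial MSD lags fitted.
#' @return data.frame with one row per fitted track.
#' @export
fitTracksDiffusion <- function(tracks, dt_s, n_points = 4, ...) {
  stopifnot(is(tracks, "TrackSet"))
  locs <- localizations(tracks)
  linked <- !is.na(locs$track_id)
  o <- order(locs$track_id[linked], locs$frame[linked])
  f <- locs$frame[linked][o]
  x <- locs$x_um[linked][o]
  y <- locs$y_um[linked][o]
  id <- locs$track_id[linked][o]
  starts <- c(1L, which(diff(id) != 0) + 1L)
  ends <- c(starts[-1] - 1L, length(id))
  res <- vector("list", length(starts))
  skipped <- 0L
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- ends[i]
    msd <- computeMSD(data.frame(frame = f[s:e], x_um = x[s:e],
                                 y_um = y[s:e]),
                      dt_s, max_lag = n_points + 4)
    if (nrow(msd) < n_points) { skipped <- skipped + 1L; next }
    res[[i]] <- fitDiffusion(msd, n_points = n_points,
                             track_id = id[s], ...)
  }
  if (skipped)
    message(skipped, " track(s) skipped: fewer than ", n_points,
            " MSD lags available")
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- fitDiffusion(data.frame(lag_s = c(1, 2), msd_um2 = c(1, 2),
                                   n_pairs = c(1L, 1L)),
                        n_points = 2)[0, ]
  rownames(out) <- NULL
  out
}

#' Immobile fraction of a set of diffusion estimates
#'
#' Fraction of tracks whose fitted D lies strictly below the threshold
#' (0.01 µm²/s by convention), overall and optionally per group (cell,
#' genotype, treatment, ...).
#'
#' @param estimates data.frame with a \code{d_um2_s} column.
#' @param threshold mobility threshold, µm²/s.
#' @param group optional grouping factor/vector, one entry per estimate.
#' @return list with \code{overall} (single fraction, plus counts as
#'   attributes) and \code{per_group} (data.frame \code{group, n,
#'   n_immobile, fraction}; NULL if no grouping given).
#' @export
immobileFraction <- function(estimates, threshold = 0.01, group = NULL) {
  stopifnot(nrow(estimates) >= 1L)
  imm <- estimates$d_um2_s < threshold
  overall <- mean(imm)
  per_group <- NULL
  if (!is.null(group)) {
    stopifnot(length(group) == nrow(estimates))
    n <- tapply(imm, group, length)
    k <- tapply(imm, group, sum)
    per_group <- data.frame(group = names(n), n = as.integer(n),
                            n_immobile = as.integer(k),
                            fraction = as.numeric(k / n))
    rownames(per_group) <- NULL
  }
  list(overall = overall, n = length(imm), n_immobile = sum(imm),
       per_group = per_group)
}

#' Histogram of log diffusion coefficients
#'
#' Bin edges are deterministic multiples of \code{binwidth} in log
#' units, covering the data range, so identical inputs give identical
#' histograms regardless of sampling order.
#'
#' @param d vector of diffusion coefficients (> 0; floored upstream).
#' @param log_base logarithm base (default 2).
#' @param binwidth bin width in log units.
#' @return data.frame \code{lower, upper, mid, count} (log-scale bin
#'   coordinates), with the base stored in attribute \code{log_base}.
#' @export
diffusionHistogram <- function(d, log_base = 2, binwidth = 1) {
  stopifnot(all(d > 0))
  ld <- log(d, base = log_base)
  lo <- floor(min(ld) / binwidth) * binwidth
  hi <- ceiling(max(ld) / binwidth) * binwidth
  if (hi <= lo) hi <- lo + binwidth
  edges <- seq(lo, hi, by = binwidth)
  h <- hist(ld, breaks = edges, plot = FALSE, right = FALSE)
  out <- data.frame(lower = edges[-length(edges)], upper = edges[-1],
                    mid = h$mids, count = h$counts)
  attr(out, "log_base") <- log_base
  out
}

#' Local maxima (modes) of a diffusion histogram
#'
#' A mode is a bin (or plateau of equal bins) whose count exceeds both
#' flanking counts and reaches at least \code{min_frac} of the tallest
#' bin; the fraction filter suppresses single-count wiggles in sparse
#' tails. Used to check the bimodality of mobile/immobile mixtures.
#'
#' @param histogram output of [diffusionHistogram()].
#' @param min_frac minimum mode height as a fraction of the maximum
#'   bin count.
#' @return numeric vector of mode positions (log-scale bin mids).
#' @export
histogramModes <- function(histogram, min_frac = 0.05) {
  cnt <- histogram$count
  r <- rle(cnt)
  k <- length(r$lengths)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  is_max <- vapply(seq_len(k), function(i) {
    left <- if (i > 1) r$values[i - 1] else -Inf
    right <- if (i < k) r$values[i + 1] else -Inf
    r$values[i] > left && r$values[i] > right
  }, logical(1))
  is_max <- is_max & r$values >= min_frac * max(cnt) & r$values > 0
  mids <- (histogram$mid[starts] + histogram$mid[ends]) / 2
  mids[is_max]
}

#' Bimodality of a mobile/immobile log-D distribution
#'
#' TRUE when the histogram has at least one mode below and one mode
#' above the mobility threshold.
#'
#' @param histogram output of [diffusionHistogram()].
#' @param threshold mobility threshold on the D scale, µm²/s.
#' @param min_frac passed to [histogramModes()].
#' @return logical.
#' @export
isBimodal <- function(histogram, threshold = 0.01, min_frac = 0.05) {
  modes <- histogramModes(histogram, min_frac = min_frac)
  lt <- log(threshold, base = attr(histogram, "log_base"))
  any(modes < lt) && any(modes > lt)
}
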
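#' Detect single-molecule spots in an image stack
#'
#' Per frame: difference-of-Gaussians band-pass, local-maximum search
#' above a robust threshold (median + k MAD of the band-passed frame),
#' minimum-separation suppression (brightest first), then a subpixel
#' intensity-weighted centroid in a fixed window. A documented
#' substitute for interactive TrackMate detection.
#'
#' @param stack an [ImageStack-class] (single channel).
#' @param cfg a [linkConfig()]; \code{detect_threshold} and
#'   \code{min_spot_separation_um} are used here.
#' @param psf_sigma_px expected spot Gaussian SD in pixels; sets the
#'   band-pass scales (sigma and 3 sigma) and the centroid window.
#' @return localization data.frame \code{frame, x_um, y_um, intensity,
#'   sigma_um, molecule_id} (molecule_id = -1: unknown). An empty stack
#'   yields an empty table.
#' @export
detectSpots <- function(stack, cfg = linkConfig(), psf_sigma_px = 1.5) {
  stopifnot(is(stack, "ImageStack"))
  px <- pixelSize(stack)
  min_sep_px <- cfg$min_spot_separation_um / px
  win <- ceiling(2 * psf_sigma_px)
  out <- vector("list", nFrames(stack))
  for (f in seq_len(nFrames(stack))) {
    m <- getFrame(stack, f)
    if (all(m == 0)) next
    band <- EBImage::imageData(EBImage::gblur(m, sigma = psf_sigma_px)) -
      EBImage::imageData(EBImage::gblur(m, sigma = 3 * psf_sigma_px))
    ## two-pass robust background: a first MAD pass flags candidate
    ## signal, which is dilated and excluded so dense frames do not
    ## inflate the noise estimate
    med0 <- stats::median(band); mad0 <- stats::mad(band)
    sig <- band > med0 + 3 * mad0
    if (any(sig)) {
      br <- EBImage::makeBrush(2 * ceiling(3 * psf_sigma_px) + 1, "disc")
      sig <- EBImage::imageData(EBImage::dilate(sig + 0, br)) > 0
      bgv <- band[!sig]
      if (length(bgv) > 100) {
        med0 <- stats::median(bgv); mad0 <- stats::mad(bgv)
      }
    }
    thr <- med0 + cfg$detect_threshold * mad0
    cand <- .localMaxima(band, thr)
    ## the FFT-based band-pass wraps around the image edges; maxima
    ## within one filter radius of the border are artefactual
    margin <- ceiling(3 * psf_sigma_px) + 1
    cand <- cand[cand$row > margin & cand$row <= nrow(m) - margin &
                   cand$col > margin & cand$col <= ncol(m) - margin, ,
                 drop = FALSE]
    if (!nrow(cand)) next
    cand <- cand[order(-cand$value), , drop = FALSE]
    keep <- .suppressClose(cand$row, cand$col, min_sep_px)
    cand <- cand[keep, , drop = FALSE]
    cent <- .centroids(band, cand$row, cand$col, win)
    out[[f]] <- data.frame(frame = f - 1L,
                           x_um = (cent$col - 1) * px,
                           y_um = (cent$row - 1) * px,
                           intensity = cent$mass,
                           sigma_um = psf_sigma_px * px,
                           molecule_id = -1L)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(frame = integer(), x_um = numeric(), y_um = numeric(),
                      intensity = numeric(), sigma_um = numeric(),
                      molecule_id = integer())
  rownames(res) <- NULL
  res
}

## strict local maxima of a matrix above thr (8-neighbourhood)
.localMaxima <- function(m, thr) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  best <- TRUE
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    best <- best & (m >= pad[2:(nr + 1) + dr, 2:(nc + 1) + dc])
  }
  hit <- which(best & m > thr, arr.ind = TRUE)
  data.frame(row = hit[, 1], col = hit[, 2],
             value = m[hit])
}

## greedy minimum-separation suppression; input ordered by priority
.suppressClose <- function(rows, cols, min_sep) {
  n <- length(rows)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (rows[keep] - rows[i])^2 + (cols[keep] - cols[i])^2
    if (all(d2 >= min_sep^2)) keep[i] <- TRUE
  }
  keep
}

## intensity-weighted centroid in a (2*win+1)^2 window of the band image,
## negative band values clamped to zero
.centroids <- function(band, rows, cols, win) {
  nr <- nrow(band); nc <- ncol(band)
  n <- length(rows)
  crow <- ccol <- mass <- numeric(n)
  for (i in seq_len(n)) {
    rr <- max(1, rows[i] - win):min(nr, rows[i] + win)
    cc <- max(1, cols[i] - win):min(nc, cols[i] + win)
    w <- pmax(band[rr, cc, drop = FALSE], 0)
    s <- sum(w)
    if (s <= 0) { crow[i] <- rows[i]; ccol[i] <- cols[i]; mass[i] <- 0; next }
    crow[i] <- sum(rowSums(w) * rr) / s
    ccol[i] <- sum(colSums(w) * cc) / s
    mass[i] <- s
  }
  list(row = crow, col = ccol, mass = mass)
}
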
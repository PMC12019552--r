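#' Average the first frames of a stack
#'
#' Pixelwise mean of the first \code{n_frames} frames, the standard
#' preprocessing for TIRF cluster-density images (100 frames at 50 ms).
#'
#' @param stack an [ImageStack-class].
#' @param n_frames number of frames averaged (default 100).
#' @return numeric matrix \code{[y, x]}.
#' @export
averageStack <- function(stack, n_frames = 100) {
  stopifnot(is(stack, "ImageStack"))
  have <- nFrames(stack)
  if (have < n_frames)
    stop(sprintf("stack has %d frame(s); %d required for averaging",
                 have, n_frames))
  rowSums(stack@data[, , seq_len(n_frames), drop = FALSE], dims = 2) /
    n_frames
}

#' Segment fluorescent clusters in an averaged image
#'
#' Deterministic pipeline standing in for interactive machine-learning
#' segmentation: white-top-hat background flattening (disc structuring
#' element), global robust threshold (median + k MAD of the flattened
#' image), connected-component labelling and a minimum-area filter.
#' Identical image and parameters always give the identical mask.
#'
#' @param img numeric matrix \code{[y, x]}.
#' @param tophat_radius_px radius of the top-hat structuring element;
#'   choose larger than the cluster radius.
#' @param k_mad threshold in MADs above the median of the flattened
#'   image.
#' @param min_area_px minimum object area in pixels.
#' @return integer label matrix (0 = background, labels dense from 1).
#' @export
segmentClusters <- function(img, tophat_radius_px = 7, k_mad = 5,
                            min_area_px = 4) {
  stopifnot(is.matrix(img))
  sc <- max(img)
  if (sc <= 0)
    return(matrix(0L, nrow(img), ncol(img)))
  brush <- EBImage::makeBrush(2 * tophat_radius_px + 1, shape = "disc")
  flat <- EBImage::imageData(EBImage::whiteTopHat(img / sc, brush)) * sc
  thr <- stats::median(flat) + k_mad * stats::mad(flat)
  mask <- flat > thr
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area_px)
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(img), ncol(img))
  nz <- lab > 0
  out[nz] <- relabel[lab[nz]]
  out
}

#' Count clusters whose centroid falls in a pixel ROI
#'
#' @param mask integer label matrix from [segmentClusters()].
#' @param roi ROI as \code{c(x0, y0, w, h)} in 0-based pixel
#'   coordinates (default the 100 x 100 px ROI used for TIRF cluster
#'   density).
#' @param pixel_um optional pixel size to convert the ROI area to µm².
#' @return list of class "ClusterCount": \code{n_clusters}, \code{roi},
#'   \code{roi_area_px}, \code{roi_area_um2} (NA without pixel size),
#'   \code{density_per_um2} and the counted label ids.
#' @export
clusterDensity <- function(mask, roi = c(0, 0, 100, 100), pixel_um = NULL) {
  stopifnot(is.matrix(mask), length(roi) == 4L)
  x0 <- roi[1]; y0 <- roi[2]; w <- roi[3]; h <- roi[4]
  if (x0 < 0 || y0 < 0 || x0 + w > ncol(mask) || y0 + h > nrow(mask))
    stop("ROI extends outside the image")
  ids <- sort(unique(mask[mask > 0]))
  inside <- integer(0)
  if (length(ids)) {
    hit <- which(mask > 0, arr.ind = TRUE)
    lab <- mask[hit]
    cy <- tapply(hit[, 1] - 1, lab, mean)   # 0-based pixel coords
    cx <- tapply(hit[, 2] - 1, lab, mean)
    sel <- cx >= x0 & cx < x0 + w & cy >= y0 & cy < y0 + h
    inside <- as.integer(names(cx)[sel])
  }
  area_px <- w * h
  area_um2 <- if (is.null(pixel_um)) NA_real_ else area_px * pixel_um^2
  structure(list(n_clusters = length(inside), roi = roi,
                 roi_area_px = area_px, roi_area_um2 = area_um2,
                 density_per_um2 = if (is.na(area_um2)) NA_real_
                                   else length(inside) / area_um2,
                 labels = inside),
            class = "ClusterCount")
}

#' @export
print.ClusterCount <- function(x, ...) {
  cat(sprintf("ClusterCount: %d cluster(s) in a %g x %g px ROI at (%g, %g)\n",
              x$n_clusters, x$roi[3], x$roi[4], x$roi[1], x$roi[2]))
  if (!is.na(x$density_per_um2))
    cat(sprintf("  density: %.4g per um^2\n", x$density_per_um2))
  invisible(x)
}

#' Estimate the background level of an image
#'
#' @param img numeric matrix.
#' @param method "percentile" (low quantile of the considered pixels)
#'   or "mode" (peak of a kernel density estimate).
#' @param p probability for the percentile method.
#' @param exclude optional logical mask of pixels to ignore (e.g. the
#'   cells themselves, so the background comes from non-ROI pixels).
#' @return single background value.
#' @export
estimateBackground <- function(img, method = c("percentile", "mode"),
                               p = 0.01, exclude = NULL) {
  method <- match.arg(method)
  v <- if (is.null(exclude)) as.numeric(img) else as.numeric(img[!exclude])
  if (!length(v)) stop("no pixels left to estimate the background from")
  if (method == "percentile") return(unname(stats::quantile(v, p)))
  if (length(unique(v)) == 1L) return(v[1])
  dens <- stats::density(v)
  dens$x[which.max(dens$y)]
}

#' Pixelwise FRET/Venus ratio with per-ROI means
#'
#' Computes (FRET - bg) / (Venus - bg) per pixel; pixels whose
#' denominator falls below \code{denom_floor} are masked out (NA). When
#' ROI masks are supplied, the per-ROI mean ratio over unmasked pixels
#' is returned; a fully masked ROI yields NA with a warning.
#'
#' @param fret_img,venus_img registered same-size numeric matrices.
#' @param bg length-2 numeric background \code{c(fret, venus)}, or
#'   "auto" to estimate each channel's background with
#'   [estimateBackground()].
#' @param denom_floor smallest accepted background-subtracted Venus
#'   value.
#' @param roi either NULL, a list of logical masks, or an integer label
#'   matrix of ROIs.
#' @return list with \code{ratio} (matrix) and \code{per_roi}
#'   (data.frame \code{roi_id, mean_ratio, n_px}; NULL without ROIs).
#' @export
fretRatio <- function(fret_img, venus_img, bg = c(0, 0),
                      denom_floor = 1e-6, roi = NULL) {
  stopifnot(all(dim(fret_img) == dim(venus_img)))
  if (identical(bg, "auto"))
    bg <- c(estimateBackground(fret_img), estimateBackground(venus_img))
  num <- fret_img - bg[1]
  den <- venus_img - bg[2]
  ratio <- num / den
  ratio[den < denom_floor] <- NA_real_
  per_roi <- NULL
  if (!is.null(roi)) {
    masks <- if (is.list(roi)) roi else {
      ids <- sort(unique(roi[roi > 0]))
      lapply(ids, function(i) roi == i)
    }
    ids <- if (is.list(roi)) seq_along(masks) else sort(unique(roi[roi > 0]))
    mr <- vapply(masks, function(m) {
      v <- ratio[m]
      v <- v[!is.na(v)]
      if (!length(v)) NA_real_ else mean(v)
    }, numeric(1))
    np <- vapply(masks, function(m) sum(!is.na(ratio[m])), integer(1))
    if (anyNA(mr)) warning("ROI(s) fully masked: ratio undefined there")
    per_roi <- data.frame(roi_id = ids, mean_ratio = mr, n_px = np)
  }
  list(ratio = ratio, per_roi = per_roi)
}

#' Background-subtracted mean intensity in a region of interest
#'
#' The ROS (DHE) readout: estimate the background, subtract it, and
#' average over the ROI mask; negative results are clamped to zero and
#' flagged via the "clamped" attribute.
#'
#' @param img numeric matrix.
#' @param roi_mask logical mask of the measured region (non-empty).
#' @param bg_method "mode" (default: the density peak of the pixel
#'   histogram, unbiased when background pixels dominate),
#'   "percentile" (conservative: sits below the true background level
#'   by about 2.3 noise SDs at p = 0.01), or a fixed numeric value.
#' @param p percentile probability.
#' @param bg_from_non_roi estimate the background from pixels outside
#'   the ROI only (TRUE) or from the whole image (FALSE).
#' @return background-subtracted mean (single number, attributes
#'   \code{background} and \code{clamped}).
#' @export
meanIntensity <- function(img, roi_mask, bg_method = "mode",
                          p = 0.01, bg_from_non_roi = FALSE) {
  stopifnot(all(dim(img) == dim(roi_mask)))
  if (!any(roi_mask)) stop("ROI mask is empty")
  bg <- if (is.numeric(bg_method)) bg_method else
    estimateBackground(img, method = bg_method, p = p,
                       exclude = if (bg_from_non_roi) roi_mask else NULL)
  val <- mean(img[roi_mask]) - bg
  clamped <- val < 0
  structure(max(val, 0), background = bg, clamped = clamped)
}
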
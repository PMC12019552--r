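#' @import methods
NULL

#' ImageStack: a single-channel image time series
#'
#' Container for a fluorescence image stack as acquired in TIRF/sptPALM
#' experiments. Pixel values are stored as a numeric array indexed
#' \code{[y, x, frame]} (row = y increasing downwards, column = x to the
#' right), matching the coordinate convention used throughout the package:
#' origin at the centre of the top-left pixel, x right, y down, physical
#' units in micrometres.
#'
#' @slot data numeric array \code{[y, x, frame]}, non-negative.
#' @slot pixelUm physical pixel size in micrometres (> 0).
#' @slot channel free-text channel label (e.g. "mEOS2-561", "FRET").
#'
#' @seealso [renderFrames()], [averageStack()], [readImageStack()]
#' @export
setClass("ImageStack",
  representation(data = "array", pixelUm = "numeric", channel = "character"),
  prototype(data = array(0, c(1, 1, 1)), pixelUm = 0.1, channel = "unknown"))

setValidity("ImageStack", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3-D array [y, x, frame]")
  if (length(object@pixelUm) != 1L || !is.finite(object@pixelUm) ||
      object@pixelUm <= 0)
    msg <- c(msg, "pixelUm must be a single positive number")
  if (any(object@data < 0, na.rm = TRUE))
    msg <- c(msg, "pixel intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' TrackSet: linked single-molecule trajectories
#'
#' Holds a localization table together with its partition into tracks.
#' Each localization belongs to at most one track (track_id \code{NA}
#' marks unlinked points); member frames are strictly increasing within
#' a track and each dark gap bridged by the linker is recorded.
#'
#' @slot localizations data.frame with columns \code{frame} (0-based
#'   integer), \code{x_um}, \code{y_um}, \code{intensity},
#'   \code{sigma_um}, \code{molecule_id} (-1 when unknown) and
#'   \code{track_id}.
#' @slot trackInfo data.frame with one row per track: \code{track_id},
#'   \code{n_locs}, \code{n_steps} (= n_locs - 1) and \code{gaps}, a
#'   list-column of dark-gap lengths (frames) bridged inside the track.
#'
#' @seealso [linkTracks()], [filterTracks()], [trueTracks()]
#' @export
setClass("TrackSet",
  representation(localizations = "data.frame", trackInfo = "data.frame"))

setValidity("TrackSet", function(object) {
  locs <- object@localizations
  info <- object@trackInfo
  need <- c("frame", "x_um", "y_um", "track_id")
  if (!all(need %in% names(locs)))
    return(paste("localizations must contain columns:",
                 paste(need, collapse = ", ")))
  if (!all(c("track_id", "n_locs", "n_steps") %in% names(info)))
    return("trackInfo must contain track_id, n_locs, n_steps")
  if (nrow(info)) {
    if (anyDuplicated(info$track_id))
      return("duplicated track ids in trackInfo")
    if (!all(info$n_steps == info$n_locs - 1L))
      return("n_steps must equal n_locs - 1 for every track")
    linked <- locs[!is.na(locs$track_id), , drop = FALSE]
    cnt <- table(factor(linked$track_id, levels = info$track_id))
    if (!all(as.integer(cnt) == info$n_locs))
      return("trackInfo n_locs disagrees with localization table")
    bad <- tapply(linked$frame, linked$track_id,
                  function(f) is.unsorted(f, strictly = TRUE))
    if (any(unlist(bad)))
      return("member frames must be strictly increasing within a track")
  }
  TRUE
})

#' VoronoiMap: per-localization Voronoi cell areas and local densities
#'
#' Result of tessellating a planar localization pattern over a
#' rectangular analysis region. Each localization i owns the Voronoi
#' cell of its nearest-point territory, clipped to the region; its local
#' density is the inverse of the clipped cell area (SR-Tesseler
#' convention). The average density used for segmentation is either the
#' global N/area of the region (default) or the mean of the
#' per-localization densities.
#'
#' @slot points two-column matrix of localization positions (µm).
#' @slot area clipped Voronoi cell area per localization (µm²).
#' @slot density local density 1/area (µm^-2).
#' @slot border logical, TRUE for cells touching the region boundary.
#' @slot region analysis rectangle \code{c(xmin, xmax, ymin, ymax)} (µm).
#' @slot avgDensity reference average density used by segmentation.
#' @slot avgMode "global" (N / region area) or "per_point" (mean of
#'   local densities).
#' @slot adjacency two-column integer matrix of point indices whose
#'   cells share a Voronoi edge.
#'
#' @seealso [voronoiDensities()], [segmentNanodomains()]
#' @export
setClass("VoronoiMap",
  representation(points = "matrix", area = "numeric", density = "numeric",
                 border = "logical", region = "numeric",
                 avgDensity = "numeric", avgMode = "character",
                 adjacency = "matrix"))

setValidity("VoronoiMap", function(object) {
  n <- nrow(object@points)
  msg <- character()
  if (ncol(object@points) != 2L) msg <- c(msg, "points must have 2 columns")
  if (length(object@area) != n || length(object@density) != n ||
      length(object@border) != n)
    msg <- c(msg, "area/density/border must have one entry per point")
  if (any(!is.finite(object@area)) || any(object@area <= 0))
    msg <- c(msg, "cell areas must be finite and positive")
  if (length(object@region) != 4L ||
      object@region[2] <= object@region[1] ||
      object@region[4] <= object@region[3])
    msg <- c(msg, "region must be c(xmin, xmax, ymin, ymax) with positive extent")
  if (n > 0 && (length(object@avgDensity) != 1L || object@avgDensity <= 0))
    msg <- c(msg, "avgDensity must be a single positive number")
  if (nrow(object@adjacency) &&
      (min(object@adjacency) < 1L || max(object@adjacency) > n))
    msg <- c(msg, "adjacency indices out of range")
  if (length(msg)) msg else TRUE
})

#' NanodomainSet: segmented high-density membrane nanodomains
#'
#' Connected components of localizations whose Voronoi local density
#' exceeds \code{density_factor} times the average density, kept when
#' they hold at least \code{min_detections} localizations.
#'
#' @slot domains data.frame with one row per domain: \code{domain_id},
#'   \code{n_detections}, \code{area_um2} (summed member cell areas),
#'   \code{equiv_diameter_um} (= 2 sqrt(area/pi)), \code{cx_um},
#'   \code{cy_um} (member centroid).
#' @slot members list of integer vectors of member localization indices
#'   into the tessellated point set.
#' @slot assignment integer vector, one entry per tessellated
#'   localization: domain id or \code{NA} outside any domain.
#' @slot region the analysis rectangle inherited from the VoronoiMap.
#' @slot config the TessConfig the segmentation was run with.
#'
#' @seealso [segmentNanodomains()], [nanodomainMetrics()]
#' @export
setClass("NanodomainSet",
  representation(domains = "data.frame", members = "list",
                 assignment = "integer", region = "numeric",
                 config = "list"))

setValidity("NanodomainSet", function(object) {
  d <- object@domains
  need <- c("domain_id", "n_detections", "area_um2", "equiv_diameter_um",
            "cx_um", "cy_um")
  if (!all(need %in% names(d)))
    return(paste("domains must contain columns:", paste(need, collapse = ", ")))
  if (length(object@members) != nrow(d))
    return("one member vector per domain required")
  if (nrow(d) && !all(d$n_detections == lengths(object@members)))
    return("n_detections must equal the number of member localizations")
  TRUE
})
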
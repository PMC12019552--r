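#' @rdname TrackSet-class
#' @export
setMethod("localizations", "TrackSet", function(x) x@localizations)

#' @rdname TrackSet-class
#' @export
setMethod("trackInfo", "TrackSet", function(x) x@trackInfo)

#' @rdname TrackSet-class
#' @export
setMethod("nTracks", "TrackSet", function(x) nrow(x@trackInfo))

#' @rdname VoronoiMap-class
#' @export
setMethod("cellAreas", "VoronoiMap", function(x) x@area)

#' @rdname VoronoiMap-class
#' @export
setMethod("localDensities", "VoronoiMap", function(x) x@density)

#' @rdname VoronoiMap-class
#' @export
setMethod("avgDensity", "VoronoiMap", function(x) x@avgDensity)

#' @rdname VoronoiMap-class
#' @export
setMethod("borderCells", "VoronoiMap", function(x) x@border)

#' @rdname VoronoiMap-class
#' @export
setMethod("cellAdjacency", "VoronoiMap", function(x) x@adjacency)

#' @rdname VoronoiMap-class
#' @export
setMethod("analysisRegion", "VoronoiMap", function(x) x@region)

#' @rdname NanodomainSet-class
#' @export
setMethod("domains", "NanodomainSet", function(x) x@domains)

#' @rdname NanodomainSet-class
#' @export
setMethod("nDomains", "NanodomainSet", function(x) nrow(x@domains))

#' @rdname NanodomainSet-class
#' @export
setMethod("domainMembers", "NanodomainSet", function(x) x@members)

#' @rdname NanodomainSet-class
#' @export
setMethod("analysisRegion", "NanodomainSet", function(x) x@region)

#' @rdname ImageStack-class
#' @export
setMethod("pixelSize", "ImageStack", function(x) x@pixelUm)

#' @rdname ImageStack-class
#' @export
setMethod("nFrames", "ImageStack", function(x) dim(x@data)[3])

#' @rdname ImageStack-class
#' @export
setMethod("getFrame", "ImageStack", function(x, i) x@data[, , i])

#' @rdname ImageStack-class
#' @export
setMethod("dim", "ImageStack", function(x) dim(x@data))

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageStack: %d frame(s) of %d x %d px (%.4g um/px), channel '%s'\n",
              d[3], d[1], d[2], object@pixelUm, object@channel))
})

setMethod("show", "TrackSet", function(object) {
  n <- nrow(object@trackInfo)
  cat(sprintf("TrackSet: %d localization(s) in %d track(s)\n",
              nrow(object@localizations), n))
  if (n) {
    s <- object@trackInfo$n_steps
    cat(sprintf("  steps per track: min %d / median %g / max %d\n",
                min(s), stats::median(s), max(s)))
    gaps <- unlist(object@trackInfo$gaps)
    cat(sprintf("  bridged dark gaps: %d\n", length(gaps)))
  }
})

setMethod("show", "VoronoiMap", function(object) {
  cat(sprintf("VoronoiMap: %d localization(s) in [%g, %g] x [%g, %g] um\n",
              nrow(object@points), object@region[1], object@region[2],
              object@region[3], object@region[4]))
  cat(sprintf("  average density (%s): %.4g um^-2; %d border cell(s)\n",
              object@avgMode, object@avgDensity, sum(object@border)))
})

setMethod("show", "NanodomainSet", function(object) {
  cat(sprintf("NanodomainSet: %d domain(s) (density factor %g, min %d detections)\n",
              nrow(object@domains),
              object@config$density_factor, object@config$min_detections))
  if (nrow(object@domains)) {
    cat(sprintf("  detections in domains: %d; mean equivalent diameter %.4g um\n",
                sum(object@domains$n_detections),
                mean(object@domains$equiv_diameter_um)))
  }
})
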
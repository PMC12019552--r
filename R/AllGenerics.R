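#' @rdname TrackSet-class
#' @param object,x a package object
#' @export
setGeneric("localizations", function(x) standardGeneric("localizations"))

#' @rdname TrackSet-class
#' @export
setGeneric("trackInfo", function(x) standardGeneric("trackInfo"))

#' @rdname TrackSet-class
#' @export
setGeneric("nTracks", function(x) standardGeneric("nTracks"))

#' @rdname VoronoiMap-class
#' @export
setGeneric("cellAreas", function(x) standardGeneric("cellAreas"))

#' @rdname VoronoiMap-class
#' @export
setGeneric("localDensities", function(x) standardGeneric("localDensities"))

#' @rdname VoronoiMap-class
#' @export
setGeneric("avgDensity", function(x) standardGeneric("avgDensity"))

#' @rdname VoronoiMap-class
#' @export
setGeneric("borderCells", function(x) standardGeneric("borderCells"))

#' @rdname VoronoiMap-class
#' @export
setGeneric("cellAdjacency", function(x) standardGeneric("cellAdjacency"))

#' @rdname VoronoiMap-class
#' @export
setGeneric("analysisRegion", function(x) standardGeneric("analysisRegion"))

#' @rdname NanodomainSet-class
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))

#' @rdname NanodomainSet-class
#' @export
setGeneric("nDomains", function(x) standardGeneric("nDomains"))

#' @rdname NanodomainSet-class
#' @export
setGeneric("domainMembers", function(x) standardGeneric("domainMembers"))

#' @rdname ImageStack-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname ImageStack-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname ImageStack-class
#' @param i frame index (1-based)
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
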
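#' @rdname filterSingletonVOTUs
#' @export
setGeneric("filterSingletonVOTUs",
           function(x, ...) standardGeneric("filterSingletonVOTUs"))

#' @rdname filterLowRecoverySamples
#' @export
setGeneric("filterLowRecoverySamples",
           function(x, minFractionOfMedian = 0.25, ...)
             standardGeneric("filterLowRecoverySamples"))

#' @rdname relativeAbundance
#' @export
setGeneric("relativeAbundance",
           function(x, ...) standardGeneric("relativeAbundance"))

#' @rdname logTransform
#' @export
setGeneric("logTransform",
           function(x, scale = 100, ...) standardGeneric("logTransform"))

#' @rdname occupancy
#' @export
setGeneric("occupancy", function(x, ...) standardGeneric("occupancy"))

#' @rdname prevalentVOTUs
#' @export
setGeneric("prevalentVOTUs",
           function(x, threshold = 0.9, ...)
             standardGeneric("prevalentVOTUs"))

#' @rdname brayCurtis
#' @export
setGeneric("brayCurtis", function(x, ...) standardGeneric("brayCurtis"))

#' @rdname communityOverlap
#' @export
setGeneric("communityOverlap",
           function(x, ...) standardGeneric("communityOverlap"))
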
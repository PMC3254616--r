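#' @rdname timePoints
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname missingMask
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname sampleInterval
#' @export
setGeneric("sampleInterval", function(x) standardGeneric("sampleInterval"))

#' @rdname eigengenes
#' @export
setGeneric("eigengenes", function(object) standardGeneric("eigengenes"))

#' @rdname loadings-EigenSystem
#' @export
setGeneric("loadings", function(object) standardGeneric("loadings"))

#' @rdname singularValues
#' @export
setGeneric("singularValues", function(object) standardGeneric("singularValues"))

#' @rdname covarianceCaptured
#' @export
setGeneric("covarianceCaptured", function(object) standardGeneric("covarianceCaptured"))

#' @rdname estimatePropagator
#' @export
setGeneric("estimatePropagator", function(object, ...) standardGeneric("estimatePropagator"))

#' Rank of a truncated eigensystem
#' @param x an \linkS4class{EigenSystem}.
#' @return integer r, the number of retained eigengenes.
#' @export
setGeneric("eigenRank", function(x) standardGeneric("eigenRank"))
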
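#' @rdname GerminationReport-class
#' @param object,x an object.
#' @export
setGeneric("nGrain", function(x) standardGeneric("nGrain"))

#' @rdname GerminationReport-class
#' @export
setGeneric("nBud", function(x) standardGeneric("nBud"))

#' @rdname GerminationReport-class
#' @export
setGeneric("germinationRate", function(x) standardGeneric("germinationRate"))

#' @rdname GerminationReport-class
#' @export
setGeneric("sOpt", function(x) standardGeneric("sOpt"))

#' @rdname RefinementResult-class
#' @export
setGeneric("thresholdD", function(x) standardGeneric("thresholdD"))

#' @rdname AreaCurve-class
#' @export
setGeneric("areas", function(x) standardGeneric("areas"))

#' @rdname GroundTruth-class
#' @export
setGeneric("nGrains", function(x) standardGeneric("nGrains"))

#' @rdname GroundTruth-class
#' @export
setGeneric("nGerminated", function(x) standardGeneric("nGerminated"))
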
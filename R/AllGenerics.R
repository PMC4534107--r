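#' @rdname MethylomeTrack-class
#' @param object,x A \linkS4class{MethylomeTrack}.
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))

#' @rdname MethylomeTrack-class
#' @export
setGeneric("sampleName", function(x) standardGeneric("sampleName"))

#' @rdname MethylomeTrack-class
#' @export
setGeneric("methLevel", function(x) standardGeneric("methLevel"))

#' @rdname filterByCoverage
#' @export
setGeneric("filterByCoverage",
    function(x, minDepth = 5L) standardGeneric("filterByCoverage"))

#' @rdname thinCounts
#' @export
setGeneric("thinCounts",
    function(x, fraction, seed = NULL) standardGeneric("thinCounts"))

#' @rdname Segmentation-class
#' @export
setGeneric("changepoints", function(x) standardGeneric("changepoints"))

#' @rdname mdlVector
#' @export
setGeneric("mdlVector", function(x) standardGeneric("mdlVector"))
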
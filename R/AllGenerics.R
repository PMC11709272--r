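# Accessor generics. Slot access from user code is discouraged; these are
# the supported surface.

#' @rdname DAGOrdering-class
#' @param x,object a `DAGOrdering`
#' @export
setGeneric("orderedNodes", function(x) standardGeneric("orderedNodes"))

#' @rdname DAGOrdering-class
#' @export
setGeneric("nodeLayers", function(x) standardGeneric("nodeLayers"))

#' @rdname DAGOrdering-class
#' @export
setGeneric("granularity", function(x) standardGeneric("granularity"))

#' @rdname PrecisionFit-class
#' @param x,object a `PrecisionFit`
#' @export
setGeneric("precisionMatrix", function(x) standardGeneric("precisionMatrix"))

#' @rdname PrecisionFit-class
#' @export
setGeneric("precisionDiagonal",
           function(x) standardGeneric("precisionDiagonal"))

#' @rdname PrecisionFit-class
#' @export
setGeneric("penaltyLambda", function(x) standardGeneric("penaltyLambda"))

#' @rdname SEMParams-class
#' @param x,object a `SEMParams`
#' @export
setGeneric("modelGraph", function(x) standardGeneric("modelGraph"))

#' @rdname SEMParams-class
#' @export
setGeneric("coefficientMatrix",
           function(x) standardGeneric("coefficientMatrix"))

#' @rdname SEMParams-class
#' @export
setGeneric("errorSD", function(x) standardGeneric("errorSD"))

#' @rdname DAGFit-class
#' @param x,object a `DAGFit`
#' @export
setGeneric("estimatedDAG", function(x) standardGeneric("estimatedDAG"))

#' @rdname DAGFit-class
#' @export
setGeneric("novelEdges", function(x) standardGeneric("novelEdges"))

#' @rdname DAGFit-class
#' @export
setGeneric("retainedEdges", function(x) standardGeneric("retainedEdges"))

#' @rdname DAGFit-class
#' @export
setGeneric("fitOrdering", function(x) standardGeneric("fitOrdering"))

#' @rdname PathCoefficients-class
#' @param x,object a `PathCoefficients`
#' @export
setGeneric("pathMatrix", function(x) standardGeneric("pathMatrix"))

#' @rdname PathCoefficients-class
#' @export
setGeneric("trainMeans", function(x) standardGeneric("trainMeans"))
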
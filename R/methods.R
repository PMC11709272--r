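# Accessors and show() methods.

#' @rdname DAGOrdering-class
setMethod("orderedNodes", "DAGOrdering", function(x) x@order)

#' @rdname DAGOrdering-class
setMethod("nodeLayers", "DAGOrdering", function(x) {
  if (x@granularity == "layer") x@layers else as.list(x@order)
})

#' @rdname DAGOrdering-class
setMethod("granularity", "DAGOrdering", function(x) x@granularity)

setMethod("show", "DAGOrdering", function(object) {
  p <- length(object@order)
  if (object@granularity == "vertex") {
    cat(sprintf("DAGOrdering (vertex) over %d nodes\n", p))
    cat("  ", paste(head(object@order, 8L), collapse = " < "),
        if (p > 8L) " < ..." else "", "\n", sep = "")
  } else {
    cat(sprintf("DAGOrdering (layer) over %d nodes, depth %d\n",
                p, length(object@layers) - 1L))
    for (i in seq_along(head(object@layers, 6L)))
      cat(sprintf("  L%d: %s\n", i - 1L,
                  paste(object@layers[[i]], collapse = ", ")))
    if (length(object@layers) > 6L) cat("  ...\n")
  }
  invisible(NULL)
})

#' @rdname PrecisionFit-class
setMethod("precisionMatrix", "PrecisionFit", function(x) x@omega)

#' @rdname PrecisionFit-class
setMethod("precisionDiagonal", "PrecisionFit", function(x) diag(x@omega))

#' @rdname PrecisionFit-class
setMethod("penaltyLambda", "PrecisionFit", function(x) x@lambda)

setMethod("show", "PrecisionFit", function(object) {
  cat(sprintf(
    "PrecisionFit: %d x %d, lambda = %g, %d sweep(s), converged = %s\n",
    nrow(object@omega), ncol(object@omega), object@lambda,
    object@iterations, object@converged))
  invisible(NULL)
})

#' @rdname SEMParams-class
setMethod("modelGraph", "SEMParams", function(x) x@graph)

#' @rdname SEMParams-class
setMethod("coefficientMatrix", "SEMParams", function(x) {
  g <- x@graph
  labs <- igraph::V(g)$name
  B <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g)
    B[el] <- igraph::E(g)$weight
  }
  B
})

#' @rdname SEMParams-class
setMethod("errorSD", "SEMParams", function(x) x@sigma)

setMethod("show", "SEMParams", function(object) {
  cat(sprintf("SEMParams: %d nodes, %d edges, sigma = %s\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph),
              paste(format(unique(object@sigma)), collapse = ", ")))
  invisible(NULL)
})

#' @rdname DAGFit-class
setMethod("estimatedDAG", "DAGFit", function(x) x@dag)

#' @rdname DAGFit-class
setMethod("novelEdges", "DAGFit", function(x) x@dagNew)

#' @rdname DAGFit-class
setMethod("retainedEdges", "DAGFit", function(x) x@dagOld)

#' @rdname DAGFit-class
setMethod("fitOrdering", "DAGFit", function(x) x@ordering)

#' @rdname DAGFit-class
setMethod("coefficientMatrix", "DAGFit", function(x) {
  g <- x@dag
  labs <- igraph::V(g)$name
  B <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g)
    B[el] <- igraph::E(g)$weight
  }
  B
})

setMethod("show", "DAGFit", function(object) {
  cat(sprintf(
    "DAGFit: %d nodes, %d edges (%d new, %d preserved), %s ordering, %d regressions\n",
    igraph::vcount(object@dag), igraph::ecount(object@dag),
    igraph::ecount(object@dagNew), igraph::ecount(object@dagOld),
    object@ordering@granularity, object@nFits))
  invisible(NULL)
})

#' @rdname PathCoefficients-class
setMethod("pathMatrix", "PathCoefficients", function(x) x@B)

#' @rdname PathCoefficients-class
setMethod("trainMeans", "PathCoefficients", function(x) x@means)

setMethod("show", "PathCoefficients", function(object) {
  cat(sprintf("PathCoefficients: %d nodes, %d nonzero paths\n",
              nrow(object@B), sum(object@B != 0)))
  invisible(NULL)
})
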
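#' @import methods
#' @importFrom stats coef cor cov2cor predict qnorm rbinom rnorm runif sd var
#' @importFrom utils head read.csv write.csv
NULL

setOldClass("igraph")

#' Vertex or layer ordering of a set of nodes
#'
#' A `DAGOrdering` holds the output of stage one of the two-stage DAG
#' search: either a full permutation of the node labels (vertex
#' granularity) or the unique topological layer partition
#' \eqn{L_0, \ldots, L_d} (layer granularity).  In both cases
#' [orderedNodes()] returns a flat label vector in which every candidate
#' parent precedes its children; for layer orderings the flat vector
#' concatenates the layers top-down with labels sorted inside each layer.
#'
#' @slot order character vector: node labels in topological position order.
#' @slot layers list of character vectors, the layer partition (empty list
#'   for vertex orderings).
#' @slot granularity `"vertex"` or `"layer"`.
#'
#' @seealso [topologicalSort()], [layerDecomposition()], [bottomUpOrder()],
#'   [knowledgeOrder()], [candidateAncestors()]
#' @export
setClass("DAGOrdering",
  slots = c(order = "character", layers = "list", granularity = "character"))

setValidity("DAGOrdering", function(object) {
  msg <- character(0)
  if (!object@granularity %in% c("vertex", "layer"))
    msg <- c(msg, "granularity must be 'vertex' or 'layer'")
  if (anyDuplicated(object@order))
    msg <- c(msg, "node labels in the ordering must be unique")
  if (length(object@order) == 0L)
    msg <- c(msg, "ordering must contain at least one node")
  if (identical(object@granularity, "layer")) {
    flat <- unlist(object@layers, use.names = FALSE)
    if (length(object@layers) == 0L)
      msg <- c(msg, "layer ordering must carry a non-empty layer list")
    if (any(vapply(object@layers, length, 1L) == 0L))
      msg <- c(msg, "layers must be non-empty")
    if (!setequal(flat, object@order) || length(flat) != length(object@order))
      msg <- c(msg, "layers must partition the ordered node set")
  } else if (length(object@layers) != 0L) {
    msg <- c(msg, "vertex ordering must not carry layers")
  }
  if (length(msg)) msg else TRUE
})

.vertexOrdering <- function(labels) {
  new("DAGOrdering", order = as.character(labels), layers = list(),
      granularity = "vertex")
}

.layerOrdering <- function(layers) {
  layers <- lapply(layers, function(x) sort(as.character(x)))
  new("DAGOrdering", order = unlist(layers, use.names = FALSE),
      layers = layers, granularity = "layer")
}

#' Penalized precision matrix estimate
#'
#' Result of the graphical lasso ([glassoPrecision()]): the estimated
#' inverse covariance matrix \eqn{\hat\Omega}, the penalty used, and
#' convergence bookkeeping.  The diagonal entries
#' \eqn{\hat\omega_{jj} = 1/\mathrm{var}(Y_j \mid Y_{-j})} drive the
#' bottom-up terminal-vertex selection.
#'
#' @slot omega symmetric positive-definite numeric matrix with node labels.
#' @slot lambda the off-diagonal L1 penalty used.
#' @slot iterations outer block-coordinate sweeps performed.
#' @slot converged logical.
#'
#' @export
setClass("PrecisionFit",
  slots = c(omega = "matrix", lambda = "numeric", iterations = "integer",
            converged = "logical"))

setValidity("PrecisionFit", function(object) {
  msg <- character(0)
  om <- object@omega
  if (nrow(om) != ncol(om)) msg <- c(msg, "omega must be square")
  if (max(abs(om - t(om))) > 1e-8 * (1 + max(abs(om))))
    msg <- c(msg, "omega must be symmetric")
  if (any(diag(om) <= 0)) msg <- c(msg, "omega diagonal must be positive")
  if (object@lambda < 0) msg <- c(msg, "lambda must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Parameters of a linear Gaussian SEM with equal error variances
#'
#' Encodes the generative model \eqn{Y_j = \sum_{k \in pa(j)} \beta_{jk}
#' Y_k + U_j} with independent Gaussian errors.  The DAG is an igraph
#' object whose edge attribute `weight` carries \eqn{\beta_{jk}} for edge
#' \eqn{k \to j}; `sigma` is the common error standard deviation (a
#' per-node vector is accepted only to demonstrate violation of the
#' equal-variance assumption).
#'
#' @slot graph directed acyclic igraph with a `weight` edge attribute.
#' @slot sigma numeric; length 1 (equal variances) or one value per node.
#'
#' @seealso [randomDAG()], [drawWeights()], [simulateSEM()],
#'   [populationCovariance()]
#' @export
setClass("SEMParams", slots = c(graph = "igraph", sigma = "numeric"))

setValidity("SEMParams", function(object) {
  msg <- character(0)
  g <- object@graph
  if (!igraph::is_directed(g)) msg <- c(msg, "graph must be directed")
  else if (!igraph::is_dag(g)) msg <- c(msg, "graph must be acyclic")
  if (igraph::ecount(g) > 0 && is.null(igraph::E(g)$weight))
    msg <- c(msg, "edges must carry a 'weight' coefficient attribute")
  if (any(object@sigma <= 0)) msg <- c(msg, "sigma must be positive")
  if (!length(object@sigma) %in% c(1L, igraph::vcount(g)))
    msg <- c(msg, "sigma must have length 1 or one value per node")
  if (length(msg)) msg else TRUE
})

#' Maximum-likelihood path coefficients of a fitted DAG
#'
#' Holds the matrix \eqn{\hat B} with entry \eqn{(k, j)} equal to the OLS
#' (Gaussian MLE) coefficient \eqn{\hat\beta_{jk}} of child \eqn{j} on
#' parent \eqn{k}; entries off the DAG's edge support are exactly zero.
#' The training column means are stored so that [predictScores()] centers
#' new data without leakage.
#'
#' @slot B numeric p x p matrix, rows = parents, columns = children.
#' @slot means named numeric vector of training column means.
#'
#' @seealso [fitPathCoefficients()], [predictScores()]
#' @export
setClass("PathCoefficients", slots = c(B = "matrix", means = "numeric"))

setValidity("PathCoefficients", function(object) {
  msg <- character(0)
  if (nrow(object@B) != ncol(object@B)) msg <- c(msg, "B must be square")
  if (is.null(rownames(object@B)) ||
      !identical(rownames(object@B), colnames(object@B)))
    msg <- c(msg, "B must carry identical row and column labels")
  if (!identical(sort(names(object@means)), sort(rownames(object@B))))
    msg <- c(msg, "means must be named by the node labels")
  if (length(msg)) msg else TRUE
})

#' Rule for choosing the per-node LASSO penalty
#'
#' @slot mode one of `"auto"` (cross-validation when p <= 100, BIC
#'   otherwise), `"cv"`, `"bic"`, `"tf"` (tuning-free normal-quantile
#'   formula), or `"fixed"` (select per node from a supplied vector).
#' @slot alpha significance level of the tuning-free formula.
#' @slot values candidate penalty values for `mode = "fixed"`.
#'
#' @seealso [lambdaRule()], [selectLambda()], [tuningFreeLambda()]
#' @export
setClass("LambdaRule",
  slots = c(mode = "character", alpha = "numeric", values = "numeric"))

setValidity("LambdaRule", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("auto", "cv", "bic", "tf", "fixed"))
    msg <- c(msg, "mode must be one of auto/cv/bic/tf/fixed")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (object@mode == "fixed" && length(object@values) == 0L)
    msg <- c(msg, "mode 'fixed' requires a vector of candidate values")
  if (any(object@values < 0)) msg <- c(msg, "values must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a penalty-selection rule
#'
#' @param mode see [LambdaRule-class].
#' @param alpha significance level for the tuning-free scheme.
#' @param values candidate penalties for `mode = "fixed"`; supplying a
#'   numeric vector here (with the default mode) switches to `"fixed"`.
#'
#' @return a [LambdaRule-class] object.
#' @export
lambdaRule <- function(mode = c("auto", "cv", "bic", "tf", "fixed"),
                       alpha = 0.05, values = numeric(0)) {
  mode <- match.arg(mode)
  if (mode == "auto" && length(values) > 0L) mode <- "fixed"
  new("LambdaRule", mode = mode, alpha = alpha, values = as.numeric(values))
}

#' Result of the two-stage DAG search
#'
#' @slot dag estimated weighted DAG (igraph; edge attribute `weight`
#'   carries the retained LASSO coefficients).
#' @slot dagNew subgraph of `dag` with the newly estimated connections,
#'   i.e. edges absent from the input knowledge graph.
#' @slot dagOld subgraph of `dag` with the connections preserved from the
#'   input graph.
#' @slot ordering the [DAGOrdering-class] used in stage two.
#' @slot nFits number of nodewise regressions executed.
#' @slot params list of the effective call parameters.
#'
#' @seealso [SEMdag()], [estimatedDAG()], [novelEdges()], [retainedEdges()]
#' @export
setClass("DAGFit",
  slots = c(dag = "igraph", dagNew = "igraph", dagOld = "igraph",
            ordering = "DAGOrdering", nFits = "integer", params = "list"))

setValidity("DAGFit", function(object) {
  msg <- character(0)
  if (!igraph::is_dag(object@dag))
    msg <- c(msg, "estimated dag must be acyclic")
  e <- .edgeKeys(object@dag)
  eNew <- .edgeKeys(object@dagNew)
  eOld <- .edgeKeys(object@dagOld)
  if (!setequal(e, union(eNew, eOld)) || length(intersect(eNew, eOld)))
    msg <- c(msg, "edges(dag) must be the disjoint union of dagNew and dagOld")
  if (length(msg)) msg else TRUE
})
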
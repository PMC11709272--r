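# Stage 1: vertex or layer ordering, knowledge-based (topological sort /
# layer decomposition of a prior DAG) or data-driven bottom-up via
# iterative graphical-lasso precision estimation.

#' Centered cross-product (covariance/correlation) matrix
#'
#' Computes `S = (Y^T Y) / n` after column centering; with
#' `scale = TRUE` columns are additionally standardized so `S` is the
#' sample correlation matrix with an exactly unit diagonal.
#'
#' The package default for the bottom-up search is the *covariance*
#' (`scale = FALSE`): under the equal-error-variance model the terminal
#' node is the one whose full conditional variance equals the (maximal)
#' error variance, a signal that standardization destroys.
#'
#' @param Y numeric data matrix, rows = samples, named columns.
#' @param scale standardize columns to unit variance?
#' @return symmetric p x p matrix with the column labels.
#' @examples
#' Y <- cbind(a = rnorm(50), b = rnorm(50))
#' diag(correlationMatrix(Y, scale = TRUE))
#' @export
correlationMatrix <- function(Y, scale = FALSE) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 2) stop("need at least two rows")
  if (!all(is.finite(Y))) stop("'Y' must be finite")
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y), "-")
  S <- crossprod(Yc) / n
  if (scale) {
    zv <- diag(S) <= .Machine$double.eps
    if (any(zv))
      stop("zero-variance column(s): ",
           paste(colnames(Y)[zv], collapse = ", "))
    S <- cov2cor(S)
    diag(S) <- 1
  }
  S
}

#' Default graphical-lasso penalty
#'
#' `0.001` in the low-dimensional regime (`n > p`) and the square-root
#' rate `sqrt(log(p) / n)` otherwise.  The flat rate `log(p) / n` is kept
#' available because both renderings circulate in the literature; the
#' square-root reading is the default (it matches the rate the graphical
#' lasso theory prescribes, whereas the flat value is vanishingly small
#' exactly where a strong penalty is needed).
#'
#' @param n sample count.
#' @param p node count.
#' @param highdim `"sqrt"` (default) or `"flat"` rate for `n <= p`.
#' @return a nonnegative scalar penalty.
#' @examples
#' defaultGlassoLambda(200, 100)  # 0.001
#' defaultGlassoLambda(50, 100)   # sqrt(log(100)/50)
#' @export
defaultGlassoLambda <- function(n, p, highdim = c("sqrt", "flat")) {
  stopifnot(n >= 1, p >= 1)
  highdim <- match.arg(highdim)
  if (n > p) return(0.001)
  if (highdim == "sqrt") sqrt(log(p) / n) else log(p) / n
}

#' Data-driven bottom-up ordering
#'
#' Iteratively estimates the precision matrix of the remaining variables
#' with the graphical lasso and peels off the terminal vertex -- the node
#' with the *minimum* precision diagonal, i.e. the *maximum* full
#' conditional variance -- or, in layer mode, the terminal layer
#' `{j : omega_jj <= min(omega) + eta}`.  Selected columns are removed and
#' the loop repeats until a single node (or the top layer) remains; the
#' reverse of the removal order is returned.  Ties are broken by node
#' label.
#'
#' Either a data matrix or a covariance matrix `S` may be supplied; with
#' exact (population) input and `lambda -> 0` the ordering provably ranks
#' every true edge forward under the equal-variance model.
#'
#' @param Y n x p data matrix with named columns, or `NULL` when `S` is
#'   given.
#' @param S optional precomputed covariance/correlation matrix.
#' @param granularity `"vertex"` or `"layer"`.
#' @param eta layer-mode tolerance on the precision diagonal (ignored for
#'   vertex granularity).
#' @param lambda graphical-lasso penalty; default [defaultGlassoLambda()].
#' @param scale standardize columns before estimating? See
#'   [correlationMatrix()].
#' @param n sample count (needed for the default penalty when only `S`
#'   is supplied; defaults to a low-dimensional setting).
#'
#' @return a [DAGOrdering-class].
#' @examples
#' g <- directedGraph(rbind(c("Y1", "Y2"), c("Y2", "Y3")))
#' igraph::E(g)$weight <- 0.8
#' Sig <- populationCovariance(new("SEMParams", graph = g, sigma = 1))
#' orderedNodes(bottomUpOrder(S = Sig, lambda = 1e-8))
#' @export
bottomUpOrder <- function(Y = NULL, S = NULL,
                          granularity = c("vertex", "layer"),
                          eta = 0.05, lambda = NULL, scale = FALSE,
                          n = NULL) {
  granularity <- match.arg(granularity)
  if (is.null(S)) {
    if (is.null(Y)) stop("supply either 'Y' or 'S'")
    if (is.null(colnames(Y))) stop("'Y' must have named columns")
    n <- nrow(Y)
    S <- correlationMatrix(Y, scale = scale)
  }
  if (is.null(rownames(S)))
    stop("'S' must carry node labels as dimnames")
  p <- ncol(S)
  if (p < 2) stop("need at least two variables to order")
  if (is.null(lambda))
    lambda <- defaultGlassoLambda(if (is.null(n)) p + 1L else n, p)
  if (granularity == "layer" && (!is.finite(eta) || eta < 0))
    stop("'eta' must be a nonnegative number in layer mode")

  remaining <- rownames(S)
  peeled <- list()                       # terminal-first
  while (length(remaining) > 1) {
    om <- precisionDiagonal(
      glassoPrecision(S[remaining, remaining, drop = FALSE], lambda))
    if (granularity == "vertex") {
      sel <- sort(remaining[om == min(om)])[1]
    } else {
      sel <- sort(remaining[om <= min(om) + eta])
    }
    peeled[[length(peeled) + 1L]] <- sel
    remaining <- setdiff(remaining, sel)
  }
  if (length(remaining))
    peeled[[length(peeled) + 1L]] <- sort(remaining)
  layers <- rev(peeled)                  # top layer first
  if (granularity == "vertex")
    .vertexOrdering(unlist(layers, use.names = FALSE))
  else
    .layerOrdering(layers)
}

#' Adaptive eta threshold from split-half precision stability
#'
#' Splits the rows into two halves, estimates the precision diagonal on
#' each, and returns the mean absolute half-vs-half difference over
#' nodes: a data-driven scale for "how different two precision diagonals
#' can look by sampling noise alone", used as the layer-mode `eta`.  The
#' split is the deterministic first half / second half unless a `seed`
#' requests a random split, so a design whose two halves are identical
#' (duplicated rows) yields exactly zero.
#'
#' @param Y n x p data matrix with named columns; requires `n > 100`.
#' @param lambda graphical-lasso penalty; default [defaultGlassoLambda()]
#'   at the half-sample size.
#' @param scale standardize columns first?
#' @param seed optional integer; when supplied, rows are assigned to the
#'   two halves by a seeded random permutation.
#'
#' @return a nonnegative scalar.
#' @export
adaptiveEta <- function(Y, lambda = NULL, scale = FALSE, seed = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n <= 100)
    stop("adaptive eta needs n > 100; set 'eta' explicitly instead")
  half <- n %/% 2L
  idx <- seq_len(n)
  if (!is.null(seed)) {
    set.seed(seed)
    idx <- sample(idx)
  }
  i1 <- idx[seq_len(half)]
  i2 <- idx[seq.int(n - half + 1L, n)]
  if (is.null(lambda)) lambda <- defaultGlassoLambda(half, ncol(Y))
  d1 <- precisionDiagonal(
    glassoPrecision(correlationMatrix(Y[i1, , drop = FALSE], scale), lambda))
  d2 <- precisionDiagonal(
    glassoPrecision(correlationMatrix(Y[i2, , drop = FALSE], scale), lambda))
  mean(abs(d1 - d2))
}

#' Knowledge-based ordering of a prior DAG
#'
#' Vertex granularity delegates to [topologicalSort()], layer granularity
#' to [layerDecomposition()].  The input must already be acyclic; apply
#' [graphToDAG()] to raw knowledge graphs first.
#'
#' @param g a directed acyclic igraph object.
#' @param granularity `"vertex"` or `"layer"`.
#' @return a [DAGOrdering-class].
#' @export
knowledgeOrder <- function(g, granularity = c("vertex", "layer")) {
  granularity <- match.arg(granularity)
  if (granularity == "vertex") topologicalSort(g) else layerDecomposition(g)
}
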
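# Synthetic-data generator for the generative model the learner assumes:
# a random DAG plus linear child-on-parent equations with i.i.d. Gaussian
# errors of one common variance.

.nodeLabels <- function(p) sprintf("V%0*d", nchar(p), seq_len(p))

#' Random DAG
#'
#' Draws a uniform node permutation and includes each forward pair
#' (earlier node -> later node in the permutation) independently with
#' probability `edgeProb`; the result is acyclic by construction and
#' bit-reproducible per seed.
#'
#' @param p number of nodes.
#' @param edgeProb inclusion probability of each of the `p(p-1)/2`
#'   forward pairs.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param labels optional node labels (default `V01, V02, ...`).
#'
#' @return a directed acyclic igraph object with `p` nodes.
#' @examples
#' g <- randomDAG(6, 0.3, seed = 1)
#' isAcyclic(g)
#' @export
randomDAG <- function(p, edgeProb, seed = NULL, labels = NULL) {
  stopifnot(p >= 1, edgeProb >= 0, edgeProb <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) labels <- .nodeLabels(p)
  stopifnot(length(labels) == p)
  perm <- sample.int(p)
  from <- integer(0); to <- integer(0)
  if (p >= 2) {
    idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
    keep <- runif(nrow(idx)) < edgeProb
    from <- perm[idx[keep, 1]]
    to <- perm[idx[keep, 2]]
  }
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(as.character(labels))
  if (length(from)) g <- igraph::add_edges(g, rbind(labels[from], labels[to]))
  g
}

#' Attach random path coefficients to a DAG
#'
#' Each edge `k -> j` receives a coefficient drawn uniformly from
#' `[lo, hi]` in magnitude with a fair random sign; sign balance keeps
#' variances from blowing up along long paths.  The common error standard
#' deviation defaults to 1 (the equal-variance regime the learner
#' assumes); a per-node `sigma` vector is accepted only to study
#' violations of that assumption.
#'
#' @param dag a directed acyclic igraph object.
#' @param magRange numeric `c(lo, hi)` with `0 < lo <= hi`.
#' @param sigma error standard deviation(s), default 1.
#' @param seed integer seed, or `NULL`.
#'
#' @return a [SEMParams-class] object.
#' @examples
#' pars <- drawWeights(randomDAG(5, 0.4, seed = 1), seed = 2)
#' coefficientMatrix(pars)
#' @export
drawWeights <- function(dag, magRange = c(0.5, 1), sigma = 1, seed = NULL) {
  .checkGraph(dag)
  stopifnot(length(magRange) == 2, magRange[1] > 0,
            magRange[1] <= magRange[2])
  if (!is.null(seed)) set.seed(seed)
  m <- igraph::ecount(dag)
  if (m > 0) {
    mag <- runif(m, magRange[1], magRange[2])
    sgn <- ifelse(runif(m) < 0.5, -1, 1)
    igraph::E(dag)$weight <- sgn * mag
  }
  new("SEMParams", graph = dag, sigma = sigma)
}

.sigmaVector <- function(params) {
  p <- igraph::vcount(params@graph)
  if (length(params@sigma) == 1L) rep(params@sigma, p) else params@sigma
}

#' Closed-form population covariance of a linear SEM
#'
#' Solves the structural system `Y = B^T Y + U` (with `B[k, j]` the
#' coefficient on edge `k -> j`): `Sigma = (I - B^T)^{-1} D (I - B^T)^{-T}`
#' where `D = diag(sigma^2)`.  Because `I - B^T` is unit-triangular under
#' a topological order it is always invertible and the result is positive
#' definite.  Used as the exact-input oracle for the bottom-up ordering.
#'
#' @param params a [SEMParams-class] object.
#' @return symmetric positive-definite p x p matrix with node labels.
#' @examples
#' g <- directedGraph(cbind("Y1", "Y2"))
#' igraph::E(g)$weight <- 0.8
#' populationCovariance(new("SEMParams", graph = g, sigma = 1))
#' @export
populationCovariance <- function(params) {
  stopifnot(is(params, "SEMParams"))
  B <- coefficientMatrix(params)
  p <- nrow(B)
  A <- solve(diag(p) - t(B))     # (I - B^T)^{-1}
  D <- diag(.sigmaVector(params)^2, p)
  Sigma <- A %*% D %*% t(A)
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- dimnames(B)
  Sigma
}

#' Simulate observations from a linear Gaussian SEM
#'
#' Generates nodes in topological order: `Y_j = sum_k beta_jk Y_k + U_j`
#' with `U_j` i.i.d. `N(0, sigma_j^2)`.  The error matrix is drawn
#' column-by-column in node-label order so the output is bit-identical
#' per seed regardless of graph topology.
#'
#' @param params a [SEMParams-class] object.
#' @param n number of samples.
#' @param seed integer seed, or `NULL`.
#'
#' @return an `n x p` numeric matrix, columns named by the nodes.
#' @examples
#' pars <- drawWeights(randomDAG(4, 0.5, seed = 1), seed = 1)
#' Y <- simulateSEM(pars, 100, seed = 1)
#' dim(Y)
#' @export
simulateSEM <- function(params, n, seed = NULL) {
  stopifnot(is(params, "SEMParams"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- params@graph
  labs <- igraph::V(g)$name
  p <- length(labs)
  sig <- .sigmaVector(params)
  U <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, labs))
  U <- sweep(U, 2, sig, "*")
  B <- coefficientMatrix(params)
  Y <- U
  for (j in orderedNodes(topologicalSort(g))) {
    pa <- labs[B[, j] != 0]
    if (length(pa))
      Y[, j] <- Y[, pa, drop = FALSE] %*% B[pa, j] + U[, j]
  }
  Y
}
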
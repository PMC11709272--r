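# Evaluation: structural Hamming distance, Matthews correlation, and
# maximum-likelihood path-coefficient fitting with out-of-sample score
# prediction.

.adjacency01 <- function(g) {
  labs <- sort(igraph::V(g)$name)
  A <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  if (igraph::ecount(g) > 0) A[igraph::as_edgelist(g)] <- 1L
  A
}

.sameNodeSet <- function(g1, g2) {
  if (!setequal(igraph::V(g1)$name, igraph::V(g2)$name))
    stop("graphs must share the same node set")
}

#' Structural Hamming distance between two directed graphs
#'
#' The number of directed adjacency entries that differ, i.e. how many
#' single-edge additions/deletions transform one edge set into the other.
#' A reversed edge costs 2 (one deletion plus one addition).  Symmetric
#' in its arguments and a metric on labelled directed graphs.
#'
#' @param g1,g2 directed igraph objects over the same node set.
#' @return a nonnegative integer.
#' @examples
#' shd(directedGraph(cbind("a", "b"), nodes = c("a", "b")),
#'     directedGraph(cbind("b", "a"), nodes = c("a", "b")))  # 2
#' @export
shd <- function(g1, g2) {
  .checkGraph(g1); .checkGraph(g2); .sameNodeSet(g1, g2)
  sum(abs(.adjacency01(g1) - .adjacency01(g2)))
}

#' Size-normalized structural Hamming distance
#'
#' `shd / (p (p - 1))` by default, which is guaranteed to lie in `[0, 1]`
#' since `p (p - 1)` counts all ordered node pairs; division by `p` alone
#' is selectable but can exceed 1 on dense graphs.
#'
#' @inheritParams shd
#' @param divisor `"pairs"` (`p (p - 1)`, default) or `"nodes"` (`p`).
#' @return a nonnegative real (in `[0, 1]` for `"pairs"`).
#' @export
normalizedSHD <- function(g1, g2, divisor = c("pairs", "nodes")) {
  divisor <- match.arg(divisor)
  p <- igraph::vcount(g1)
  if (p < 2) stop("need at least 2 nodes")
  shd(g1, g2) / if (divisor == "pairs") p * (p - 1) else p
}

#' Confusion counts of an estimated edge set against a reference
#'
#' Counts directed ordered node pairs: TP (edge in both), FP (edge only
#' estimated), FN (edge only in the reference), TN (edge in neither,
#' diagonal excluded).
#'
#' @param est,ref directed igraph objects over the same node set
#'   (estimated and ground-truth graphs).
#' @return a named list with `TP`, `FP`, `FN`, `TN`.
#' @export
edgeConfusion <- function(est, ref) {
  .checkGraph(est); .checkGraph(ref); .sameNodeSet(est, ref)
  A <- .adjacency01(est); B <- .adjacency01(ref)
  off <- !diag(nrow(A))
  list(TP = sum(A == 1 & B == 1),
       FP = sum(A == 1 & B == 0),
       FN = sum(A == 0 & B == 1),
       TN = sum(A == 0 & B == 0 & off))
}

#' Matthews correlation coefficient
#'
#' `(TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, a balanced
#' binary-classification score in `[-1, 1]`: 1 is perfect agreement, 0 no
#' better than random, -1 complete disagreement.  When any margin is zero
#' the coefficient is defined as 0 (the usual degenerate convention).
#'
#' @param TP,FP,FN,TN nonnegative confusion counts; alternatively pass a
#'   single list (as from [edgeConfusion()]) as `TP`.
#' @return a real number in `[-1, 1]`.
#' @examples
#' mcc(TP = 50, FP = 0, FN = 0, TN = 50)  # 1
#' @export
mcc <- function(TP, FP = NULL, FN = NULL, TN = NULL) {
  if (is.list(TP)) {
    cc <- TP; TP <- cc$TP; FP <- cc$FP; FN <- cc$FN; TN <- cc$TN
  }
  v <- c(TP, FP, FN, TN)
  if (any(v < 0) || anyNA(v)) stop("confusion counts must be nonnegative")
  if (sum(v) == 0) stop("confusion counts are all zero")
  TP <- as.numeric(TP); FP <- as.numeric(FP)
  FN <- as.numeric(FN); TN <- as.numeric(TN)
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (den == 0) return(0)
  (TP * TN - FP * FN) / sqrt(den)
}

#' Maximum-likelihood path coefficients of a DAG
#'
#' Ordinary least squares of every child on its parents (the Gaussian-SEM
#' MLE) on centered data.  Entries of the returned matrix off the DAG's
#' edge support are exactly zero; source nodes have all-zero columns.
#'
#' @param dag a directed acyclic igraph whose nodes are data columns.
#' @param data training data matrix (rows = samples, named columns).
#' @return a [PathCoefficients-class] object.
#' @export
fitPathCoefficients <- function(dag, data) {
  .checkGraph(dag)
  if (!igraph::is_dag(dag)) stop("'dag' must be acyclic")
  data <- as.matrix(data)
  labs <- igraph::V(dag)$name
  if (!all(labs %in% colnames(data)))
    stop("data is missing columns: ",
         paste(setdiff(labs, colnames(data)), collapse = ", "))
  data <- data[, labs, drop = FALSE]
  mu <- colMeans(data)
  Yc <- sweep(data, 2, mu, "-")
  B <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (j in labs) {
    pa <- names(igraph::neighbors(dag, j, mode = "in"))
    if (length(pa) == 0) next
    if (nrow(data) <= length(pa))
      stop("node ", j, ": more parents than samples")
    fit <- qr(Yc[, pa, drop = FALSE])
    if (fit$rank < length(pa))
      stop("node ", j, ": rank-deficient parent matrix")
    B[pa, j] <- qr.coef(fit, Yc[, j])
  }
  new("PathCoefficients", B = B, means = mu)
}

#' Predicted scores from fitted path coefficients
#'
#' Computes `Yhat = Yc %*% Bhat` where `Yc` is the input centered with
#' the *training* column means stored in the fit (so test rows are
#' transformed without refitting or leakage).  Source-node columns are
#' identically zero.
#'
#' @param data data matrix covering the fit's node set.
#' @param fit a [PathCoefficients-class] object.
#' @return matrix of predicted (centered) scores, same rows as `data`.
#' @export
predictScores <- function(data, fit) {
  stopifnot(is(fit, "PathCoefficients"))
  data <- as.matrix(data)
  labs <- rownames(fit@B)
  if (!all(labs %in% colnames(data)))
    stop("data is missing columns: ",
         paste(setdiff(labs, colnames(data)), collapse = ", "))
  Yc <- sweep(data[, labs, drop = FALSE], 2, fit@means[labs], "-")
  Yc %*% fit@B
}
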
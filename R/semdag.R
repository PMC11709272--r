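# Two-stage DAG search: (1) vertex/layer ordering, knowledge-based or
# bottom-up; (2) nodewise weighted LASSO on candidate ancestors.

.resolveLambdaRule <- function(lambdas, p, alpha = 0.05) {
  rule <-
    if (is.null(lambdas) || (length(lambdas) == 1 && is.na(lambdas)))
      lambdaRule("auto", alpha = alpha)
    else if (is(lambdas, "LambdaRule")) lambdas
    else if (is.character(lambdas)) lambdaRule(lambdas, alpha = alpha)
    else if (is.numeric(lambdas))
      lambdaRule("fixed", alpha = alpha, values = lambdas)
    else stop("'lambdas' must be NULL/NA, a mode string, a numeric vector, ",
              "or a LambdaRule")
  if (rule@mode == "auto")
    rule@mode <- if (p <= 100) "cv" else "bic"
  rule
}

#' Two-stage order-based DAG learning
#'
#' Learns a DAG from an `n x p` data matrix under the linear
#' equal-error-variance SEM.  Stage one fixes a vertex (`LO = "TO"`) or
#' layer (`LO = "TL"`) ordering: from the prior `graph` when it has edges
#' (after [graphToDAG()] conversion), otherwise data-driven bottom-up via
#' iterative graphical-lasso precision estimation ([bottomUpOrder()]).
#' Stage two regresses every node on its candidate ancestors with a
#' weighted LASSO; with `penalty = TRUE`, edges present in the prior
#' graph get penalty factor 0 (no shrinkage, always retained), all other
#' candidates get 1.  Coefficients with `|beta| > beta` become edges.
#'
#' @param graph prior directed igraph whose node names intersect the data
#'   columns; an edgeless graph (or `NULL`) triggers the fully
#'   data-driven mode.
#' @param data `n x p` numeric matrix, rows = samples, named columns.
#' @param LO `"TO"` (vertex) or `"TL"` (layer) ordering.
#' @param beta minimum absolute LASSO coefficient for a link to be
#'   retained (strict inequality; default 0 removes exact zeros only).
#' @param eta layer-mode bottom-up threshold on the precision diagonal;
#'   `NULL` or `"adaptive"` estimates it by split-half stability
#'   ([adaptiveEta()], needs `n > 100`).
#' @param lambdas penalty selection: `NULL`/`NA` for the automatic rule
#'   (CV when `p <= 100`, BIC above), a mode string (`"cv"`, `"bic"`,
#'   `"tf"`), a numeric vector of candidate penalties, or a
#'   [LambdaRule-class].
#' @param penalty protect prior-graph edges from shrinkage?
#' @param scale standardize columns before the bottom-up precision
#'   estimation? (The covariance default is deliberate; see
#'   [correlationMatrix()].)
#' @param alpha significance level of the tuning-free rule.
#' @param seed integer seed controlling the CV fold assignments.
#'
#' @return a [DAGFit-class]: the estimated weighted DAG, its split into
#'   newly estimated (`dagNew`) and preserved (`dagOld`) connections, and
#'   the ordering used.
#' @examples
#' pars <- drawWeights(randomDAG(6, 0.3, seed = 1), seed = 1)
#' Y <- simulateSEM(pars, 400, seed = 1)
#' fit <- SEMdag(NULL, Y, LO = "TO", seed = 1)
#' fit
#' @export
SEMdag <- function(graph = NULL, data, LO = c("TO", "TL"), beta = 0,
                   eta = 0.05, lambdas = NULL, penalty = TRUE,
                   scale = FALSE, alpha = 0.05, seed = 0L) {
  LO <- match.arg(LO)
  data <- as.matrix(data)
  if (is.null(colnames(data))) stop("'data' must have named columns")
  if (!all(is.finite(data))) stop("'data' must be finite")
  if (beta < 0) stop("'beta' must be nonnegative")

  if (is.null(graph)) graph <- directedGraph(NULL, nodes = colnames(data))
  .checkGraph(graph, allowLoops = TRUE)
  gNodes <- igraph::V(graph)$name
  shared <- intersect(colnames(data), gNodes)
  if (length(shared) < 2)
    stop("fewer than 2 shared nodes between the graph and the data columns")
  if (length(shared) < length(gNodes) || length(shared) < ncol(data))
    warning(sprintf(
      "node mismatch: using the %d shared node(s); dropped %d graph node(s), %d data column(s)",
      length(shared), length(gNodes) - length(shared),
      ncol(data) - length(shared)))
  data <- data[, shared, drop = FALSE]
  graph <- igraph::induced_subgraph(graph, shared)
  p <- ncol(data)
  n <- nrow(data)
  gran <- if (LO == "TO") "vertex" else "layer"

  knowledge <- igraph::ecount(graph) > 0
  if (knowledge) {
    ord <- knowledgeOrder(graphToDAG(graph), gran)
    etaUsed <- NA_real_
  } else {
    etaUsed <- if (gran == "layer") {
      if (is.null(eta) || identical(eta, "adaptive"))
        adaptiveEta(data, scale = scale)
      else eta
    } else NA_real_
    ord <- bottomUpOrder(data, granularity = gran,
                         eta = if (is.na(etaUsed)) 0 else etaUsed,
                         scale = scale)
  }

  rule <- .resolveLambdaRule(lambdas, p, alpha = alpha)
  inputKeys <- .edgeKeys(graph)
  dataC <- sweep(data, 2, colMeans(data), "-")

  coefs <- list()
  nFits <- 0L
  nodes <- orderedNodes(ord)
  for (j in seq_along(nodes)) {
    node <- nodes[j]
    anc <- candidateAncestors(ord, node)
    if (length(anc) == 0) next
    w <- ifelse(penalty & paste(anc, node, sep = "\r") %in% inputKeys, 0, 1)
    X <- dataC[, anc, drop = FALSE]
    y <- dataC[, node]
    lam <- if (rule@mode == "tf")
      tuningFreeLambda(rule@alpha, p = p, jPos = length(anc) + 1L, n = n)
    else
      selectLambda(y, X, rule, weights = w, seed = seed + j)
    coefs[[node]] <- fitNodeLasso(y, X, lam, weights = w)
    nFits <- nFits + 1L
  }

  dag <- assembleDAG(coefs, nodes = nodes, betaThreshold = beta)
  keys <- .edgeKeys(dag)
  oldKeys <- intersect(keys, inputKeys)
  newKeys <- setdiff(keys, inputKeys)
  wAll <- structure(if (igraph::ecount(dag) > 0) igraph::E(dag)$weight
                    else numeric(0),
                    names = .edgeKeysUnsorted(dag))
  mkSub <- function(kk) {
    el <- .keysToEdgelist(kk)
    directedGraph(
      if (nrow(el)) data.frame(el[, 1], el[, 2], weight = wAll[kk]) else NULL,
      nodes = nodes)
  }
  new("DAGFit", dag = dag, dagNew = mkSub(newKeys), dagOld = mkSub(oldKeys),
      ordering = ord, nFits = nFits,
      params = list(LO = LO, beta = beta, eta = etaUsed,
                    lambdaMode = rule@mode, alpha = rule@alpha,
                    penalty = penalty, scale = scale, seed = seed,
                    knowledge = knowledge, n = n, p = p))
}

.edgeKeysUnsorted <- function(g) {
  if (igraph::ecount(g) == 0) return(character(0))
  el <- igraph::as_edgelist(g)
  paste(el[, 1], el[, 2], sep = "\r")
}
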
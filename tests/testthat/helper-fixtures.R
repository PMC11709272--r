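# Shared fixtures and independent oracles. Oracles work on the dense
# adjacency matrix so they share no code path with the igraph-based
# implementation they check.

chainGraph <- function(labels = c("a", "b", "c")) {
  directedGraph(cbind(labels[-length(labels)], labels[-1]))
}

diamondGraph <- function() {
  directedGraph(rbind(c("a", "b"), c("a", "c"), c("b", "d"), c("c", "d")))
}

colliderGraph <- function() {
  directedGraph(rbind(c("i", "j"), c("k", "j")))
}

adjacencyOf <- function(g) {
  labs <- sort(igraph::V(g)$name)
  A <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  if (igraph::ecount(g) > 0) A[igraph::as_edgelist(g)] <- 1
  A
}

# acyclicity oracle: a digraph is cyclic iff some power of A has a
# positive diagonal entry
oracleAcyclic <- function(g) {
  A <- adjacencyOf(g)
  p <- nrow(A)
  if (p == 0) return(TRUE)
  M <- A
  for (i in seq_len(p)) {
    if (any(diag(M) > 0)) return(FALSE)
    M <- (M %*% A > 0) + 0
  }
  TRUE
}

# layer oracle: iterated source peeling straight off the recursive
# definition (L0 = zero in-degree, then repeat on the submatrix)
oracleLayers <- function(g) {
  A <- adjacencyOf(g)
  labs <- rownames(A)
  layers <- list()
  while (length(labs)) {
    sub <- A[labs, labs, drop = FALSE]
    src <- labs[colSums(sub) == 0]
    stopifnot(length(src) > 0)
    layers[[length(layers) + 1L]] <- sort(src)
    labs <- setdiff(labs, src)
  }
  layers
}

# random directed graph that may contain cycles (and optional self-loops)
randomDigraph <- function(p, prob, seed, loops = FALSE) {
  set.seed(seed)
  labs <- sprintf("n%02d", seq_len(p))
  pairs <- expand.grid(from = labs, to = labs, stringsAsFactors = FALSE)
  if (!loops) pairs <- pairs[pairs$from != pairs$to, ]
  keep <- runif(nrow(pairs)) < prob
  directedGraph(if (any(keep)) pairs[keep, ] else NULL, nodes = labs)
}

edgeKeysOf <- function(g) {
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0) return(character(0))
  paste(el[, 1], el[, 2], sep = ">")
}

backwardEdgeRate <- function(g, ord) {
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0) return(0)
  mean(match(el[, 1], ord) > match(el[, 2], ord))
}

chainSEM <- function(p = 3, beta = 0.8, sigma = 1,
                     labels = paste0("Y", seq_len(p))) {
  g <- chainGraph(labels)
  igraph::E(g)$weight <- beta
  new("SEMParams", graph = g, sigma = sigma)
}
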
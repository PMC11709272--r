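# Graph data model and topological machinery. Graphs are directed igraph
# objects with unique character vertex names; all tie-breaking is by
# ascending node label so every operation is deterministic.

.checkGraph <- function(g, allowLoops = FALSE) {
  if (!igraph::is_igraph(g)) stop("'g' must be an igraph object")
  if (!igraph::is_directed(g)) stop("'g' must be a directed graph")
  labs <- igraph::V(g)$name
  if (is.null(labs)) stop("graph vertices must be named")
  if (anyDuplicated(labs)) stop("vertex names must be unique")
  if (igraph::any_multiple(g)) stop("duplicate edges are not allowed")
  if (!allowLoops && any(igraph::which_loop(g)))
    stop("self-loops are not allowed here; run graphToDAG() first")
  invisible(g)
}

# canonical "from->to" keys, label-sorted
.edgeKeys <- function(g) {
  if (igraph::ecount(g) == 0) return(character(0))
  el <- igraph::as_edgelist(g)
  sort(paste(el[, 1], el[, 2], sep = "\r"))
}

.keysToEdgelist <- function(keys) {
  if (length(keys) == 0)
    return(matrix(character(0), 0, 2))
  do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
}

#' Build a directed graph from an edge list
#'
#' Convenience constructor used throughout the package and the CLI: a
#' directed igraph from a two-column `from`/`to` edge table plus optional
#' isolated nodes.  An optional third column `weight` is attached as the
#' edge attribute of the same name.
#'
#' @param edges two- or three-column matrix/data.frame (`from`, `to`,
#'   optional `weight`), or `NULL` for an edgeless graph.
#' @param nodes character vector of node labels; defaults to the labels
#'   appearing in `edges`.
#'
#' @return a directed igraph object.
#' @examples
#' g <- directedGraph(cbind(c("a", "a"), c("b", "c")))
#' isAcyclic(g)
#' @export
directedGraph <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || NROW(edges) == 0) {
    if (is.null(nodes)) nodes <- character(0)
    return(igraph::make_empty_graph(directed = TRUE) +
             igraph::vertices(as.character(nodes)))
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  from <- as.character(edges[[1]])
  to <- as.character(edges[[2]])
  labs <- sort(unique(c(from, to, as.character(nodes))))
  g <- igraph::make_empty_graph(directed = TRUE) + igraph::vertices(labs)
  g <- igraph::add_edges(g, rbind(from, to))
  if (ncol(edges) >= 3) igraph::E(g)$weight <- as.numeric(edges[[3]])
  .checkGraph(g, allowLoops = TRUE)
  g
}

#' Test a directed graph for acyclicity
#'
#' @param g a directed igraph object.
#' @return `TRUE` iff `g` contains no directed cycle (a self-loop counts
#'   as a cycle).
#' @examples
#' isAcyclic(directedGraph(cbind("a", "b")))
#' @export
isAcyclic <- function(g) {
  .checkGraph(g, allowLoops = TRUE)
  igraph::is_dag(g)
}

#' Transpose a directed graph
#'
#' Flips the orientation of every edge; nodes (and any edge weights) are
#' kept.  The layer decomposition applies iterative leaf removal to the
#' transpose so that source layers come out top-down.
#'
#' @param g a directed igraph object.
#' @return the transposed igraph.
#' @export
graphTranspose <- function(g) {
  .checkGraph(g, allowLoops = TRUE)
  igraph::reverse_edges(g)
}

# locate one directed cycle for error messages (g known cyclic)
.findCycle <- function(g) {
  labs <- sort(igraph::V(g)$name)
  for (v in labs) {
    for (w in labs) {
      if (v == w) next
      suppressWarnings({
        p1 <- igraph::shortest_paths(g, v, w, mode = "out",
                                     weights = NA)$vpath[[1]]
        p2 <- igraph::shortest_paths(g, w, v, mode = "out",
                                     weights = NA)$vpath[[1]]
      })
      if (length(p1) && length(p2))
        return(c(names(p1), names(p2)[-1]))
    }
    if (igraph::are_adjacent(g, v, v)) return(c(v, v))
  }
  labs[1]
}

#' Topological vertex sort
#'
#' Kahn's algorithm with deterministic tie-breaking: among the nodes of
#' in-degree zero, the smallest label is emitted first.  Every edge of the
#' input then points from an earlier to a later position.
#'
#' @param g a directed acyclic igraph object.
#' @return a [DAGOrdering-class] with vertex granularity.
#' @examples
#' topologicalSort(directedGraph(rbind(c("a", "b"), c("b", "c"))))
#' @export
topologicalSort <- function(g) {
  .checkGraph(g)
  labs <- igraph::V(g)$name
  p <- length(labs)
  if (p == 0) stop("graph has no nodes")
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g), mode = "out"),
                names)
  names(adj) <- labs
  indeg <- igraph::degree(g, mode = "in")
  names(indeg) <- labs
  out <- character(0)
  ready <- sort(labs[indeg == 0])
  while (length(ready)) {
    v <- ready[1]
    ready <- ready[-1]
    out <- c(out, v)
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) ready <- sort(c(ready, w))
    }
  }
  if (length(out) < p) {
    cyc <- .findCycle(igraph::induced_subgraph(g, setdiff(labs, out)))
    stop("graph is cyclic; one cycle: ", paste(cyc, collapse = " -> "))
  }
  .vertexOrdering(out)
}

#' Topological layer decomposition via iterative leaf removal
#'
#' Assigns every node of a DAG to a unique layer: the transpose of the
#' graph is formed and leaves (nodes without outgoing edges, i.e. the
#' sources of the original graph) are stripped iteratively; reversing the
#' roles in this way yields the layers top-down, so `L0` is exactly the
#' source set and each `Lj` is the source set of the subgraph remaining
#' after removing `L0, ..., L(j-1)`.  Unlike a topological vertex sort,
#' this partition is unique; parents of a node always lie in strictly
#' upper layers.
#'
#' @param g a directed acyclic igraph object.
#' @return a [DAGOrdering-class] with layer granularity.
#' @examples
#' diamond <- directedGraph(rbind(c("a", "b"), c("a", "c"),
#'                                c("b", "d"), c("c", "d")))
#' nodeLayers(layerDecomposition(diamond))
#' @export
layerDecomposition <- function(g) {
  .checkGraph(g)
  if (igraph::vcount(g) == 0) stop("graph has no nodes")
  tg <- graphTranspose(g)
  layers <- list()
  while (igraph::vcount(tg) > 0) {
    leaves <- sort(names(which(igraph::degree(tg, mode = "out") == 0)))
    if (length(leaves) == 0) {
      cyc <- .findCycle(graphTranspose(tg))
      stop("graph is cyclic; one cycle: ", paste(cyc, collapse = " -> "))
    }
    layers[[length(layers) + 1L]] <- leaves
    tg <- igraph::delete_vertices(tg, leaves)
  }
  .layerOrdering(layers)
}

#' Convert an arbitrary directed graph to a DAG
#'
#' Prior knowledge graphs (e.g. signalling pathways) often contain cycles
#' and self-loops, while the ordering stage requires a DAG.  The rule is
#' deterministic and documented: self-loops are removed first, then a
#' depth-first traversal is started from each node in ascending label
#' order (neighbours also visited in label order) and every back edge --
#' an edge closing a directed cycle into a vertex on the current DFS
#' stack -- is deleted.  An already acyclic graph is returned unchanged.
#'
#' @param g a directed igraph object, possibly cyclic, possibly with
#'   self-loops.
#' @return an acyclic subgraph of `g`.
#' @export
graphToDAG <- function(g) {
  .checkGraph(g, allowLoops = TRUE)
  g <- igraph::delete_edges(g, igraph::E(g)[igraph::which_loop(g)])
  if (igraph::is_dag(g)) return(g)
  labs <- igraph::V(g)$name
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g), mode = "out"),
                function(v) sort(names(v)))
  names(adj) <- labs
  color <- structure(rep(0L, length(labs)), names = labs) # 0 new 1 stack 2 done
  drop <- character(0)
  for (root in sort(labs)) {
    if (color[root] != 0L) next
    # iterative DFS; stack holds (node, index of next neighbour to try)
    stack <- list(list(v = root, i = 1L))
    color[root] <- 1L
    while (length(stack)) {
      top <- stack[[length(stack)]]
      nbrs <- adj[[top$v]]
      if (top$i <= length(nbrs)) {
        w <- nbrs[top$i]
        stack[[length(stack)]]$i <- top$i + 1L
        if (color[w] == 1L) {
          drop <- c(drop, paste(top$v, w, sep = "|"))
        } else if (color[w] == 0L) {
          color[w] <- 1L
          stack[[length(stack) + 1L]] <- list(v = w, i = 1L)
        }
      } else {
        color[top$v] <- 2L
        stack[[length(stack)]] <- NULL
      }
    }
  }
  if (length(drop)) {
    pairs <- do.call(rbind, strsplit(drop, "|", fixed = TRUE))
    eids <- igraph::get_edge_ids(g, t(pairs))
    g <- igraph::delete_edges(g, eids[eids > 0])
  }
  stopifnot(igraph::is_dag(g))
  g
}

#' Descriptive summary of a directed graph
#'
#' Counts vertices, edges, sources (no incoming edges) and sinks (no
#' outgoing edges), and reports the mean total degree (in + out, i.e.
#' `2 E / V`) and the mean directed unnormalized shortest-path
#' betweenness.
#'
#' @param g a directed igraph object.
#' @return a one-row `data.frame` with columns `nVertices`, `nEdges`,
#'   `nSources`, `nSinks`, `meanDegree`, `meanBetweenness`.
#' @examples
#' graphSummary(directedGraph(rbind(c("a", "b"), c("b", "c"))))
#' @export
graphSummary <- function(g) {
  .checkGraph(g)
  p <- igraph::vcount(g)
  data.frame(
    nVertices = p,
    nEdges = igraph::ecount(g),
    nSources = sum(igraph::degree(g, mode = "in") == 0),
    nSinks = sum(igraph::degree(g, mode = "out") == 0),
    meanDegree = if (p) mean(igraph::degree(g, mode = "all")) else 0,
    meanBetweenness = if (p)
      mean(igraph::betweenness(g, directed = TRUE, weights = NA,
                               normalized = FALSE))
    else 0)
}
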
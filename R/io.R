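# File formats: TSV edge lists, GraphML (via igraph), dense labelled
# adjacency CSV, and numeric data matrices (CSV/TSV).

.sniffFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         graphml = "graphml",
         csv = "adjacency_csv",
         "edge_tsv")
}

#' Read a directed graph from a file
#'
#' Supported formats: `edge_tsv` (header `from<TAB>to`, optional third
#' column `weight`), `graphml` (directed edges only), and
#' `adjacency_csv` (square labelled matrix; a nonzero entry `(k, j)`
#' means the edge `k -> j`, and the value becomes the edge weight when it
#' is not 1).  All formats round-trip with [writeGraph()].
#'
#' @param path input file.
#' @param format one of `"edge_tsv"`, `"graphml"`, `"adjacency_csv"`;
#'   guessed from the extension by default.
#' @return a directed igraph object.
#' @export
readGraph <- function(path,
                      format = c("auto", "edge_tsv", "graphml",
                                 "adjacency_csv")) {
  format <- match.arg(format)
  if (format == "auto") format <- .sniffFormat(path)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (!igraph::is_directed(g))
      stop("GraphML graph is undirected; only directed edges are supported")
    if (is.null(igraph::V(g)$name)) igraph::V(g)$name <- as.character(
      seq_len(igraph::vcount(g)))
    return(.checkGraph(g, allowLoops = TRUE))
  }
  if (format == "adjacency_csv") {
    A <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
    if (nrow(A) != ncol(A) || !identical(rownames(A), colnames(A)))
      stop("adjacency CSV must be square with identical row/column labels")
    idx <- which(A != 0, arr.ind = TRUE)
    el <- if (nrow(idx)) data.frame(rownames(A)[idx[, 1]],
                                    colnames(A)[idx[, 2]],
                                    weight = A[idx])
          else NULL
    g <- directedGraph(el, nodes = rownames(A))
    if (!is.null(el) && all(igraph::E(g)$weight == 1))
      g <- igraph::delete_edge_attr(g, "weight")
    return(g)
  }
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty edge file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- parts[[1]]
  if (length(hdr) < 2 || hdr[1] != "from" || hdr[2] != "to")
    stop("edge TSV needs a 'from<TAB>to' header (line 1)")
  hasW <- length(hdr) >= 3 && hdr[3] == "weight"
  from <- character(0); to <- character(0); w <- numeric(0)
  seen <- character(0)
  for (i in seq_along(parts)[-1]) {
    row <- parts[[i]]
    if (length(row) == 1 && row == "") next
    if (length(row) < 2)
      stop(sprintf("malformed edge row at line %d of %s", i, path))
    key <- paste(row[1], row[2], sep = "\r")
    if (key %in% seen)
      stop(sprintf("duplicate edge at line %d of %s", i, path))
    seen <- c(seen, key)
    from <- c(from, row[1]); to <- c(to, row[2])
    if (hasW) {
      wi <- suppressWarnings(as.numeric(row[3]))
      if (is.na(wi))
        stop(sprintf("non-numeric weight at line %d of %s", i, path))
      w <- c(w, wi)
    }
  }
  el <- if (length(from)) {
    if (hasW) data.frame(from, to, weight = w) else data.frame(from, to)
  } else NULL
  directedGraph(el)
}

#' Write a directed graph to a file
#'
#' Rows are emitted in label-sorted (from, to) order so output is stable
#' across runs; edge weights (e.g. the LASSO coefficients of an estimated
#' DAG) are written at full precision.
#'
#' @param g a directed igraph object (optionally with a `weight` edge
#'   attribute) or a [DAGFit-class] (its estimated DAG is written).
#' @param path output file.
#' @param format as in [readGraph()].
#' @return `path`, invisibly.
#' @export
writeGraph <- function(g, path,
                       format = c("auto", "edge_tsv", "graphml",
                                  "adjacency_csv")) {
  if (is(g, "DAGFit")) g <- estimatedDAG(g)
  .checkGraph(g, allowLoops = TRUE)
  format <- match.arg(format)
  if (format == "auto") format <- .sniffFormat(path)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  labs <- sort(igraph::V(g)$name)
  hasW <- !is.null(igraph::E(g)$weight)
  if (format == "adjacency_csv") {
    A <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
    if (igraph::ecount(g) > 0)
      A[igraph::as_edgelist(g)] <- if (hasW) igraph::E(g)$weight else 1
    write.csv(A, path, quote = FALSE)
    return(invisible(path))
  }
  el <- igraph::as_edgelist(g)
  o <- order(el[, 1], el[, 2])
  body <- if (nrow(el)) {
    if (hasW)
      paste(el[o, 1], el[o, 2],
            format(igraph::E(g)$weight[o], digits = 17), sep = "\t")
    else paste(el[o, 1], el[o, 2], sep = "\t")
  } else character(0)
  hdr <- if (hasW) "from\tto\tweight" else "from\tto"
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a numeric data matrix
#'
#' CSV or TSV with a header row of unique column labels and a purely
#' numeric, complete body; parse problems are reported with their
#' row/column coordinates.
#'
#' @param path input file (delimiter guessed from the first line).
#' @return numeric matrix with named columns.
#' @export
readMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\t", readLines(path, n = 1))) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 colClasses = NA, stringsAsFactors = FALSE)
  if (anyDuplicated(colnames(df)))
    stop("duplicate column labels in ", path)
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric or missing value at row %d, column '%s' of %s",
                   bad[1], colnames(df)[j], path))
    df[[j]] <- v
  }
  as.matrix(df)
}

#' Write a numeric data matrix as CSV
#'
#' @param Y numeric matrix with named columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMatrix <- function(Y, path) {
  write.csv(as.data.frame(Y), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
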
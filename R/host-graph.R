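#' Host networks for graphette sampling
#'
#' A host graph is a large simple undirected network whose k-node induced
#' subgraphs are sampled and identified against the canonical tables.
#' External node labels (arbitrary strings) are mapped to contiguous
#' 0-based indices in order of first appearance in the edge list, read
#' row-wise (first endpoint before second).  Self-loops are rejected;
#' duplicate edges are silently collapsed.
#'
#' @param edges a two-column matrix or data frame of node labels (character
#'   or coercible), one row per edge; `NULL` for an edgeless graph.
#' @param isolated additional node labels with no edges (the edge-list
#'   format cannot express these; programmatic construction can).
#' @return an object of class `"host_graph"`: a list with `n` (node count),
#'   `labels` (character vector, index i+1 holds the label of node i),
#'   `edges` (m x 2 integer matrix of 0-based pairs, first column >
#'   second), and `adj` (per-node integer vectors of 0-based neighbours).
#' @examples
#' host_graph(rbind(c("a", "b"), c("b", "c")))   # the path a-b-c
#' host_graph(NULL, isolated = letters[1:10])    # 10 isolated nodes
#' @export
host_graph <- function(edges = NULL, isolated = NULL) {
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(0), 0L, 2L)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("edges must have two columns", call. = FALSE)
    edges <- matrix(as.character(edges), ncol = 2L)
  }
  if (any(edges[, 1L] == edges[, 2L]))
    stop("self-loop in edge list", call. = FALSE)
  labels <- unique(c(as.vector(t(edges)), as.character(isolated)))  # first-appearance
  if (!length(labels)) stop("host graph needs at least one node", call. = FALSE)
  u <- match(edges[, 1L], labels) - 1L
  v <- match(edges[, 2L], labels) - 1L
  e <- cbind(pmax(u, v), pmin(u, v))
  e <- unique(e)
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  n <- length(labels)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (r in seq_len(nrow(e))) {
    a <- e[r, 1L]; b <- e[r, 2L]
    adj[[a + 1L]] <- c(adj[[a + 1L]], b)
    adj[[b + 1L]] <- c(adj[[b + 1L]], a)
  }
  adj <- lapply(adj, sort)
  structure(list(n = n, labels = labels, edges = e, adj = adj),
            class = "host_graph")
}

#' Read a host graph from a plain-text edge list
#'
#' Format: one edge per line, two whitespace-separated labels; lines
#' starting with `#` and blank lines are ignored.
#'
#' @param path path to the edge-list file.
#' @return a [host_graph()].
#' @export
read_host_graph <- function(path) {
  if (!file.exists(path)) stop(gettextf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("edge list is empty", call. = FALSE)
  toks <- strsplit(lines, "[[:space:]]+")
  bad <- lengths(toks) != 2L
  if (any(bad))
    stop(gettextf("malformed edge-list line: '%s'", lines[which(bad)[1L]]), call. = FALSE)
  host_graph(do.call(rbind, toks))
}

#' @export
print.host_graph <- function(x, ...) {
  cat(sprintf("<host_graph> %d nodes, %d edges\n", x$n, nrow(x$edges)))
  invisible(x)
}
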
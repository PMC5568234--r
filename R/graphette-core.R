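#' Graphettes: small graphs as adjacency bit vectors
#'
#' A graphette is a k-node undirected graph (k <= 8), connected or not,
#' stored as the node count `k` together with an integer whose bits are the
#' lower triangle of the adjacency matrix: the unordered pair (i, j) with
#' 0 <= j < i < k occupies bit position p(i, j) = i(i-1)/2 + j, so a graph
#' on k nodes is one of the 2^b(k) integers in [0, 2^b(k)) with
#' b(k) = k(k-1)/2.  Node positions are 0-based throughout, matching the
#' bit-position formula.
#'
#' @param k node count, an integer in 1..8.
#' @param bits non-negative integer below `2^gbits(k)`.
#' @return `graphette()` returns an object of class `"graphette"`, a list
#'   with elements `k` and `bits`.
#' @examples
#' graphette(3, 7)          # the triangle
#' graphette(4)             # the empty graph on 4 nodes
#' @export
graphette <- function(k, bits = 0L) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > 8L)
    stop("k must be a single integer in 1..8", call. = FALSE)
  bits <- as.integer(bits)
  b <- gbits(k)
  if (length(bits) != 1L || is.na(bits) || bits < 0L || (b < 31L && bits >= bitwShiftL(1L, b)))
    stop(gettextf("bits must lie in [0, 2^%d) for k = %d", b, k), call. = FALSE)
  structure(list(k = k, bits = bits), class = "graphette")
}

#' @export
print.graphette <- function(x, ...) {
  e <- graphette_edges(x)
  cat(sprintf("<graphette> k = %d, bits = %d, %d edge%s\n",
              x$k, x$bits, nrow(e), if (nrow(e) == 1L) "" else "s"))
  if (nrow(e)) cat("  edges:", paste0("(", e[, 1L], ",", e[, 2L], ")", collapse = " "), "\n")
  invisible(x)
}

#' Number of bits in the lower-triangle encoding
#'
#' @param k node count.
#' @return `k(k-1)/2` as an integer.
#' @export
gbits <- function(k) as.integer(k * (k - 1L) / 2L)

# 0-based bit position of pair (i, j), i > j >= 0
pair_bit <- function(i, j) as.integer(i * (i - 1L) / 2L + j)

# b(k) x 2 matrix of (i, j) pairs in bit-position order p = 0 .. b-1
pair_table <- function(k) {
  if (k < 2L) return(matrix(integer(0), 0L, 2L))
  i <- rep.int(seq_len(k - 1L), seq_len(k - 1L))
  j <- sequence(seq_len(k - 1L)) - 1L
  cbind(i = i, j = j)
}

#' Encode an edge set as a bit vector
#'
#' Each edge (i, j) with `0 <= j < i < k` contributes `2^(i(i-1)/2 + j)` to
#' the integer.  Edges may be given in either node order; they are
#' normalised to i > j.
#'
#' @param k node count (1..8).
#' @param edges a two-column matrix (or coercible) of 0-based node pairs;
#'   `NULL` or a zero-row matrix means the edgeless graph.
#' @return the bit-vector integer.
#' @examples
#' graphette_encode(3, NULL)                          # 0
#' graphette_encode(3, rbind(c(1,0), c(2,0), c(2,1))) # 7, the triangle
#' graphette_encode(3, rbind(c(2,1)))                 # 4
#' @export
graphette_encode <- function(k, edges = NULL) {
  k <- as.integer(k)
  if (is.null(edges) || NROW(edges) == 0L) return(graphette(k, 0L)$bits)
  edges <- matrix(as.integer(as.matrix(edges)), ncol = 2L)
  hi <- pmax(edges[, 1L], edges[, 2L])
  lo <- pmin(edges[, 1L], edges[, 2L])
  if (any(hi == lo)) stop("self-loops are not valid graphette edges", call. = FALSE)
  if (any(lo < 0L) || any(hi >= k)) stop("edge endpoint out of range 0..k-1", call. = FALSE)
  p <- unique(pair_bit(hi, lo))
  sum(bitwShiftL(1L, p))
}

#' Decode a bit vector into a graphette with an explicit edge set
#'
#' Inverse of [graphette_encode()]: `graphette_encode(k, graphette_edges(g))`
#' reproduces `bits`.
#'
#' @param bits bit-vector integer in `[0, 2^gbits(k))`.
#' @param k node count.
#' @return a `"graphette"` object.
#' @export
graphette_decode <- function(bits, k) graphette(k, bits)

#' Edge set of a graphette
#'
#' @param g a `"graphette"` object.
#' @return a two-column integer matrix of 0-based pairs with column 1 > column 2.
#' @export
graphette_edges <- function(g) {
  pt <- pair_table(g$k)
  if (nrow(pt) == 0L) return(pt)
  set <- bitwAnd(g$bits, bitwShiftL(1L, seq_len(nrow(pt)) - 1L)) != 0L
  pt[set, , drop = FALSE]
}

# bits -> 0/1 integer vector of length b (LSB first)
bits_to_vec <- function(bits, b) {
  if (b == 0L) return(integer(0))
  as.integer(bitwAnd(bits, bitwShiftL(1L, 0:(b - 1L))) != 0L)
}

#' Induced-subgraph bit vector
#'
#' Extracts the subgraph of a host network induced on an ordered k-set of
#' nodes and encodes it: bit p(i, j) is set iff the host has an edge
#' between `nodes[i]` and `nodes[j]` (0-based positions within the set).
#' The order of `nodes` determines the bit vector; reordering gives an
#' isomorphic but generally different integer.
#'
#' @param host a [host_graph()].
#' @param nodes ordered vector of k distinct 0-based host node indices.
#' @return the bit-vector integer of the induced graphette.
#' @export
induced_bits <- function(host, nodes) {
  stopifnot(inherits(host, "host_graph"))
  nodes <- as.integer(nodes)
  k <- length(nodes)
  if (k < 1L || k > 8L) stop("need 1..8 nodes", call. = FALSE)
  if (anyDuplicated(nodes)) stop("nodes in a k-set must be distinct", call. = FALSE)
  if (any(nodes < 0L) || any(nodes >= host$n)) stop("node index out of range", call. = FALSE)
  bits <- 0L
  for (i in seq_len(k - 1L)) {           # position i (0-based) = i here
    hit <- nodes[seq_len(i)] %in% host$adj[[nodes[i + 1L] + 1L]]
    if (any(hit))
      bits <- bits + sum(bitwShiftL(1L, pair_bit(i, which(hit) - 1L)))
  }
  bits
}

#' Relabel a graphette by a permutation
#'
#' `pi` is an image vector: position i maps to node `pi[i+1]` (0-based
#' values).  The result has edge (pi(u), pi(v)) exactly when `g` has edge
#' (u, v).
#'
#' @param g a `"graphette"`.
#' @param pi integer vector of length `g$k`, a permutation of `0:(k-1)`.
#' @return the relabelled `"graphette"`.
#' @export
apply_permutation <- function(g, pi) {
  pi <- as.integer(pi)
  k <- g$k
  if (length(pi) != k || !setequal(pi, 0:(k - 1L)))
    stop("pi must be a permutation of 0:(k-1) with length k", call. = FALSE)
  e <- graphette_edges(g)
  if (nrow(e) == 0L) return(graphette(k, 0L))
  graphette(k, graphette_encode(k, cbind(pi[e[, 1L] + 1L], pi[e[, 2L] + 1L])))
}

#' Complement graphette
#'
#' Flips every bit: `bits` becomes `(2^b(k) - 1) - bits`.  Automorphisms
#' are shared between a graphette and its complement, which the
#' automorphism generator exploits on dense inputs.
#'
#' @param g a `"graphette"`.
#' @return the complement `"graphette"`.
#' @export
graphette_complement <- function(g) {
  b <- gbits(g$k)
  mask <- if (b == 0L) 0L else bitwShiftL(1L, b) - 1L
  graphette(g$k, bitwXor(g$bits, mask))
}

#' Sorted degree sequence
#'
#' @param g a `"graphette"`.
#' @return non-decreasing integer vector of the k node degrees.
#' @export
degree_sequence <- function(g) sort(node_degrees(g))

# per-position (unsorted) degrees, 0-based position order
node_degrees <- function(g) {
  d <- integer(g$k)
  e <- graphette_edges(g)
  if (nrow(e)) for (col in 1:2) {
    t <- tabulate(e[, col] + 1L, nbins = g$k)
    d <- d + t
  }
  d
}

# k x k logical adjacency matrix
adjacency_matrix <- function(g) {
  A <- matrix(FALSE, g$k, g$k)
  e <- graphette_edges(g)
  if (nrow(e)) {
    A[e + 1L] <- TRUE
    A[e[, 2:1, drop = FALSE] + 1L] <- TRUE
  }
  A
}

#' Is a graphette connected (i.e. also a graphlet)?
#'
#' Breadth-first traversal from node 0; a 1-node graphette is connected.
#'
#' @param g a `"graphette"`.
#' @return `TRUE` iff all k nodes lie in one component.
#' @export
is_connected <- function(g) {
  k <- g$k
  if (k == 1L) return(TRUE)
  A <- adjacency_matrix(g)
  seen <- logical(k)
  seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(!seen & rowSums(A[, frontier, drop = FALSE]) > 0L)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}
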
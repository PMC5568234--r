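# Shared fixtures: named graphette constructors, host generators, cached
# table builds, and independent oracles (igraph isomorphism, exhaustive
# subset enumeration, traversal-based connectivity).

g_path <- function(k) {           # 0-1-2-...-(k-1)
  graphette(k, graphette_encode(k, cbind(seq_len(k - 1L), seq_len(k - 1L) - 1L)))
}

g_cycle <- function(k) {
  e <- rbind(cbind(seq_len(k - 1L), seq_len(k - 1L) - 1L), c(k - 1L, 0L))
  graphette(k, graphette_encode(k, e))
}

g_star <- function(k) {           # node 0 is the centre
  graphette(k, graphette_encode(k, cbind(seq_len(k - 1L), 0L)))
}

g_clique <- function(k) graphette(k, bitwShiftL(1L, gbits(k)) - 1L)

random_bits <- function(k) as.integer(floor(stats::runif(1) * 2^gbits(k)))

random_perm <- function(k) sample.int(k) - 1L

# cached table builds shared across test files (k = 6 takes a few seconds)
.tables_cache <- new.env(parent = emptyenv())
get_tables <- function(k) {
  key <- as.character(k)
  if (is.null(.tables_cache[[key]])) .tables_cache[[key]] <- graphette_tables(k)
  .tables_cache[[key]]
}

# Erdos-Renyi G(n, p) host with labels v1..vn (isolated nodes kept)
er_host <- function(n, p, seed) {
  set.seed(seed)
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  labs <- paste0("v", seq_len(n))
  host_graph(if (any(keep)) cbind(labs[pairs[keep, 1]], labs[pairs[keep, 2]]) else NULL,
             isolated = labs)
}

ig_from_graphette <- function(g) {
  ig <- igraph::make_empty_graph(n = g$k, directed = FALSE)
  e <- graphette_edges(g)
  if (nrow(e)) ig <- igraph::add_edges(ig, as.vector(t(e)) + 1L)
  ig
}

# exact graphette distribution by exhaustive enumeration of all k-subsets
exhaustive_counts <- function(host, k, tables) {
  subsets <- utils::combn(host$n, k) - 1L
  counts <- integer(length(tables$map$canonicals))
  for (j in seq_len(ncol(subsets))) {
    ci <- tables$map$canon_of[induced_bits(host, subsets[, j]) + 1L]
    counts[ci + 1L] <- counts[ci + 1L] + 1L
  }
  counts
}

# independent connectivity oracle: union of reachable sets by repeated
# adjacency-matrix multiplication (no shared code with is_connected's BFS)
connected_oracle <- function(g) {
  k <- g$k
  if (k == 1L) return(TRUE)
  e <- graphette_edges(g)
  A <- diag(k)
  if (nrow(e)) { A[e + 1L] <- 1; A[e[, 2:1, drop = FALSE] + 1L] <- 1 }
  R <- A
  for (i in seq_len(k)) R <- (R %*% A > 0) * 1
  all(R[1L, ] > 0)
}

# independent permutation enumerator (insertion-based, unlike the
# package's prefix-recursive one); rows cover all k! image vectors
all_perms <- function(k) {
  P <- matrix(0L, 1L, 1L)
  for (m in 2:k) {
    out <- matrix(0L, nrow(P) * m, m)
    r <- 0L
    for (i in seq_len(nrow(P))) for (pos in seq_len(m)) {
      r <- r + 1L
      out[r, ] <- append(P[i, ], m - 1L, after = pos - 1L)
    }
    P <- out
  }
  if (k == 1L) matrix(0L, 1L, 1L) else P
}

# brute-force automorphism count: filter every permutation
perms_count_brute <- function(g) {
  P <- all_perms(g$k)
  sum(vapply(seq_len(nrow(P)), function(j)
    apply_permutation(g, P[j, ])$bits == g$bits, logical(1)))
}
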
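#' Isomorphism, automorphisms and orbits of graphettes
#'
#' Two k-node graphs are isomorphic when some node permutation carries the
#' edge set of one exactly onto the other.  An automorphism is an
#' isomorphism of a graph with itself; the automorphism group partitions
#' the nodes into orbits — classes of topologically interchangeable
#' nodes.  Orbits are what make graphette statistics meaningful per node:
#' a node's structural role in a sampled graphette is its orbit.
#'
#' @name iso_orbits
NULL

# all k! permutations of 0:(k-1) in lexicographic order of image vectors,
# as a k! x k integer matrix (identity first)
perms_lex <- function(k) {
  if (k == 1L) return(matrix(0L, 1L, 1L))
  sub <- perms_lex(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 0L
  for (first in 0:(k - 1L)) {
    rest <- setdiff(0:(k - 1L), first)
    blk <- matrix(rest[sub + 1L], nrow(sub), k - 1L)
    idx <- row + seq_len(nrow(sub))
    out[idx, 1L] <- first
    out[idx, -1L] <- blk
    row <- row + nrow(sub)
  }
  out
}

# pack an image vector (0-based) into one integer, 3 bits per image,
# LSB-first: sum image[i] * 8^(i-1).  Max k=8 -> fits in 24 bits.
perm_pack <- function(pi) as.integer(sum(as.integer(pi) * 8^(seq_along(pi) - 1L)))

perm_unpack <- function(code, k) as.integer((code %/% 8^(0:(k - 1L))) %% 8L)

perm_identity <- function(k) 0:(k - 1L)

# sigma o pi : apply pi first, then sigma (image vectors, 0-based)
perm_compose <- function(sigma, pi) sigma[pi + 1L]

perm_inverse <- function(pi) order(pi) - 1L

#' Cycle decomposition of a permutation
#'
#' Splits an image vector into its disjoint cycles; within a cycle,
#' successive elements are images under the permutation, and each cycle
#' starts at its smallest unvisited element.  For example the image vector
#' `c(2,0,1,3,5,4)` splits into cycles (0 2 1), (3), (4 5).
#'
#' @param pi integer image vector, a permutation of `0:(k-1)`.
#' @return a list of integer vectors partitioning `0:(k-1)`.
#' @export
cycles_of <- function(pi) {
  pi <- as.integer(pi)
  k <- length(pi)
  if (!setequal(pi, 0:(k - 1L))) stop("not a permutation of 0:(k-1)", call. = FALSE)
  seen <- logical(k)
  cycles <- list()
  for (start in 0:(k - 1L)) {
    if (seen[start + 1L]) next
    cyc <- integer(0)
    u <- start
    repeat {
      cyc <- c(cyc, u)
      seen[u + 1L] <- TRUE
      u <- pi[u + 1L]
      if (u == start) break
    }
    cycles[[length(cycles) + 1L]] <- cyc
  }
  cycles
}

# backtracking search for permutations mapping g onto h.
# Candidate images are restricted to nodes of equal degree, and partial
# maps are pruned by adjacency consistency with all previously placed
# nodes.  Images are tried in ascending order, so the first hit is the
# lexicographically smallest witness.  all = TRUE collects every hit
# (used for Aut(g) with h = g).
iso_search <- function(Ag, Ah, dg, dh, all = FALSE) {
  k <- nrow(Ag)
  found <- vector("list", 0L)
  img <- integer(k)
  used <- logical(k)
  recurse <- function(i) {
    if (i > k) {
      if (all) found[[length(found) + 1L]] <<- img - 1L
      return(!all)
    }
    for (cand in seq_len(k)) {
      if (used[cand] || dh[cand] != dg[i]) next
      ok <- TRUE
      for (j in seq_len(i - 1L)) {
        if (Ag[i, j] != Ah[cand, img[j]]) { ok <- FALSE; break }
      }
      if (!ok) next
      img[i] <<- cand
      used[cand] <<- TRUE
      if (recurse(i + 1L)) return(TRUE)
      used[cand] <<- FALSE
    }
    FALSE
  }
  hit <- recurse(1L)
  if (all) found else if (hit) img - 1L else NULL
}

#' Test two graphettes for isomorphism
#'
#' Short-circuits to `FALSE` when the sorted degree sequences differ;
#' otherwise backtracks over degree-compatible permutations.  On success
#' the witness is the lexicographically smallest permutation `pi` with
#' `apply_permutation(g, pi)$bits == h$bits`.
#'
#' @param g,h `"graphette"` objects with equal `k`.
#' @return a list with `isomorphic` (logical) and `witness` (image vector,
#'   or `NULL` when not isomorphic).
#' @export
are_isomorphic <- function(g, h) {
  if (g$k != h$k) stop("graphettes differ in size", call. = FALSE)
  dg <- node_degrees(g); dh <- node_degrees(h)
  if (!identical(sort(dg), sort(dh)))
    return(list(isomorphic = FALSE, witness = NULL))
  w <- iso_search(adjacency_matrix(g), adjacency_matrix(h), dg, dh)
  list(isomorphic = !is.null(w), witness = w)
}

#' Generate the automorphism group of a graphette
#'
#' Backtracks over degree classes: a node may only map to a node of equal
#' degree, and partial maps inconsistent with the adjacency matrix are cut
#' immediately — same output as filtering all k! permutations, far
#' cheaper.  Dense graphettes (more than half the possible edges) are
#' handled through their complement, which has the same automorphism
#' group.
#'
#' @param g a `"graphette"`, k <= 8.
#' @return a list of image vectors (each a permutation of `0:(k-1)`),
#'   lexicographically ordered, always containing the identity.
#' @export
generate_automorphisms <- function(g) {
  b <- gbits(g$k)
  e <- nrow(graphette_edges(g))
  if (b > 0L && e > b / 2) g <- graphette_complement(g)   # Aut(g) == Aut(g')
  A <- adjacency_matrix(g)
  d <- node_degrees(g)
  iso_search(A, A, d, d, all = TRUE)
}

#' Enumerate the automorphism orbits of a graphette
#'
#' Every node starts with its own index as colour; for each cycle of each
#' automorphism, all member nodes are recoloured with the minimum colour
#' in the cycle, and the pass over cycles repeats until no colour changes.
#' At the fixed point, two nodes share a colour exactly when some
#' automorphism (possibly a composition) maps one to the other, and each
#' node's colour is the smallest node index in its orbit.
#'
#' @param g a `"graphette"`, k <= 8.
#' @return a list with `colors` (integer vector, `colors[u+1]` is the
#'   orbit colour of node u) and `n_orbits` (number of distinct orbits).
#' @export
enumerate_orbits <- function(g) {
  k <- g$k
  auts <- generate_automorphisms(g)
  cycles <- unlist(lapply(auts, cycles_of), recursive = FALSE)
  color <- 0:(k - 1L)
  repeat {
    changed <- FALSE
    for (cyc in cycles) {
      cmin <- min(color[cyc + 1L])
      if (any(color[cyc + 1L] != cmin)) {
        color[color %in% color[cyc + 1L]] <- cmin
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(colors = color, n_orbits = length(unique(color)))
}
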
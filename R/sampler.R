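#' Statistical graphette sampling
#'
#' Exhaustively enumerating all k-node induced subgraphs of a large
#' network is exponential in k and n; sampling N k-sets and identifying
#' each in constant time through the canonical tables approximates the
#' graphette distribution and the per-node orbit degree vectors at a cost
#' linear in N.  Three k-set selection strategies are provided:
#'
#' * `"uniform"` — a uniformly random k-subset of the nodes;
#' * `"local"` — a uniformly random seed node, grown by repeatedly adding
#'   a uniformly chosen neighbour of the current set (falling back to a
#'   uniform non-member when the neighbourhood is exhausted, so
#'   disconnected hosts never stall);
#' * `"edge"` — a uniformly random edge's endpoints, grown as in
#'   `"local"`.
#'
#' @name sampler
NULL

sample_methods <- c("uniform", "local", "edge")

# uniform choice from an integer vector (sample() treats length-1 x as 1:x)
pick1 <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

#' Sample one k-set of host nodes
#'
#' Uses R's global RNG stream; callers wanting reproducibility seed it
#' (the higher-level drivers take an explicit `seed`).
#'
#' @param host a [host_graph()].
#' @param k set size, 1..8 and at most `host$n`.
#' @param method one of `"uniform"`, `"local"`, `"edge"`.
#' @return integer vector of k distinct 0-based node indices, in the
#'   order they were selected.
#' @export
sample_kset <- function(host, k, method = c("uniform", "local", "edge")) {
  method <- match.arg(method)
  k <- as.integer(k)
  n <- host$n
  if (k < 1L || k > 8L) stop("k must be in 1..8", call. = FALSE)
  if (k > n) stop("k exceeds the number of host nodes", call. = FALSE)
  if (method == "uniform")
    return(sample.int(n, k) - 1L)
  if (method == "edge") {
    if (nrow(host$edges) == 0L)
      stop("edge-based sampling needs at least one edge", call. = FALSE)
    e <- host$edges[sample.int(nrow(host$edges), 1L), ]
    set <- as.integer(e)
    if (k == 1L) return(set[1L])
  } else {
    set <- sample.int(n, 1L) - 1L
  }
  while (length(set) < k) {
    nbr <- setdiff(unique(unlist(host$adj[set + 1L])), set)
    if (length(nbr)) {
      set <- c(set, pick1(nbr))
    } else {
      set <- c(set, pick1(setdiff(0:(n - 1L), set)))
    }
  }
  set
}

sample_run <- function(host, k, N, method, seed, tables) {
  stopifnot(inherits(host, "host_graph"))
  map <- tables$map; orbits <- tables$orbits
  if (map$k != k) stop("tables were built for a different k", call. = FALSE)
  N <- as.integer(N)
  if (N < 1L) stop("N must be positive", call. = FALSE)
  set.seed(seed)
  counts <- integer(length(map$canonicals))
  odv <- matrix(0L, host$n, orbits$num_orbits)
  for (s in seq_len(N)) {
    nodes <- sample_kset(host, k, method)
    bits <- induced_bits(host, nodes)
    ci <- map$canon_of[bits + 1L]
    counts[ci + 1L] <- counts[ci + 1L] + 1L
    w <- perm_unpack(map$perm[bits + 1L], k)
    ids <- orbits$orbit_id[ci + 1L, w + 1L]      # orbit of original position u
    odv[cbind(nodes + 1L, ids + 1L)] <- odv[cbind(nodes + 1L, ids + 1L)] + 1L
  }
  list(counts = counts, odv = odv)
}

#' Estimate the graphette distribution of a host network
#'
#' Draws N k-sets (with replacement across draws), identifies each via
#' [induced_bits()] and the canonical map, and accumulates per-canonical
#' counts.  A fixed seed gives bit-identical output.
#'
#' @param host a [host_graph()].
#' @param k graphette size, 1..8.
#' @param N number of samples.
#' @param method k-set selection strategy, see [sample_kset()].
#' @param seed RNG seed.
#' @param tables `"graphette_tables"` for this k.
#' @return an object of class `"graphette_distribution"`: `k`, `N`,
#'   `method`, `seed`, `counts` (per canonical index), `freq`
#'   (`counts/N`), `canonicals`, `connected`.
#' @export
estimate_distribution <- function(host, k, N, method = "uniform", seed = 1L, tables) {
  run <- sample_run(host, k, N, method, seed, tables)
  structure(list(k = as.integer(k), N = as.integer(N), method = method,
                 seed = as.integer(seed), counts = run$counts,
                 freq = run$counts / N,
                 canonicals = tables$map$canonicals,
                 connected = tables$map$connected),
            class = "graphette_distribution")
}

#' @export
print.graphette_distribution <- function(x, ...) {
  cat(sprintf("<graphette_distribution> k = %d, N = %d (%s sampling)\n",
              x$k, x$N, x$method))
  seen <- which(x$counts > 0L)
  for (ci in seen)
    cat(sprintf("  canonical %3d (bits %7d%s): %8d  (%.4f)\n",
                ci - 1L, x$canonicals[ci], if (x$connected[ci]) ", graphlet" else "",
                x$counts[ci], x$freq[ci]))
  invisible(x)
}

#' Sampled orbit degree vectors
#'
#' For every sample, each member node at original position u scores one
#' hit at the global orbit ID of canonical position `witness(u)`; over N
#' samples the per-node hit counts form the orbit degree vector, the
#' orbit-level analogue of the graphlet degree vector.  Entries sum to
#' `N * k` over all nodes and orbits.
#'
#' @inheritParams estimate_distribution
#' @return an object of class `"orbit_degree_vectors"`: `k`, `N`,
#'   `method`, `seed`, `counts` (n x num_orbits integer matrix, rows in
#'   host node order), `labels`.
#' @export
orbit_degree_vectors <- function(host, k, N, method = "uniform", seed = 1L, tables) {
  run <- sample_run(host, k, N, method, seed, tables)
  structure(list(k = as.integer(k), N = as.integer(N), method = method,
                 seed = as.integer(seed), counts = run$odv,
                 labels = host$labels),
            class = "orbit_degree_vectors")
}

#' @export
print.orbit_degree_vectors <- function(x, ...) {
  cat(sprintf("<orbit_degree_vectors> %d nodes x %d orbits, N = %d\n",
              nrow(x$counts), ncol(x$counts), x$N))
  invisible(x)
}

#' Write a graphette distribution as TSV
#'
#' Columns: canonical index, canonical bit vector, connected flag, count,
#' frequency.  Counts are the source of truth; frequencies are derived.
#'
#' @param dist a `"graphette_distribution"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(dist, path) {
  df <- data.frame(canon_index = seq_along(dist$counts) - 1L,
                   canon_bits = dist$canonicals,
                   connected = as.integer(dist$connected),
                   count = dist$counts,
                   frequency = dist$freq)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write orbit degree vectors as TSV
#'
#' One row per host node: node label, then one count column per global
#' orbit ID.
#'
#' @param odv an `"orbit_degree_vectors"` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_odv <- function(odv, path) {
  df <- data.frame(node = odv$labels, odv$counts, check.names = FALSE)
  names(df) <- c("node", paste0("orbit", seq_len(ncol(odv$counts)) - 1L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
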
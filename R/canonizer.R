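#' Canonical graphette lookup tables
#'
#' Among all 2^b(k) bit vectors on k nodes, the canonical representative
#' of an isomorphism class is its numerically smallest member.  The
#' canonical map stores, for every bit vector B, the index of its
#' canonical, a witness permutation carrying B onto that canonical, and a
#' per-canonical connectivity flag — after which identifying any k-set of
#' nodes in a host network is a constant-time array lookup.
#'
#' @name canonizer
NULL

# For every B in lo..(hi-1) compute the minimum of its isomorphism orbit
# restricted to [min_lo, min_hi), plus the first (lexicographic)
# permutation attaining it.  The permutation action is vectorised: one
# 0/1 bit matrix times a b x k! power matrix gives every permuted value of
# every B in a chunk at once.
canon_scan <- function(k, lo, hi, min_lo = 0, min_hi = NULL) {
  b <- gbits(k)
  if (is.null(min_hi)) min_hi <- 2^b
  P <- perms_lex(k)
  np <- nrow(P)
  if (b == 0L) {               # k = 1: the single empty graph
    return(list(canon = 0L, perm = perm_pack(0L)))
  }
  pt <- pair_table(k)
  # PW[p+1, j] = 2^(position of pair (perm_j(i), perm_j(j')))
  PW <- matrix(0, b, np)
  for (j in seq_len(np)) {
    pi <- P[j, ]
    a <- pi[pt[, 1L] + 1L]; c <- pi[pt[, 2L] + 1L]
    PW[, j] <- 2^pair_bit(pmax(a, c), pmin(a, c))
  }
  n <- hi - lo
  canon <- integer(n)
  perm <- integer(n)
  chunk <- max(1L, floor(2^21 / np))
  pow <- 2^(0:(b - 1L))
  for (start in seq(lo, hi - 1, by = chunk)) {
    Bs <- start:min(start + chunk - 1, hi - 1)
    M <- matrix(0, length(Bs), b)
    for (p in seq_len(b)) M[, p] <- (Bs %/% pow[p]) %% 2
    vals <- M %*% PW
    if (min_lo > 0 || min_hi < 2^b)
      vals[vals < min_lo | vals >= min_hi] <- Inf
    wit <- max.col(-vals, ties.method = "first")
    idx <- (start - lo) + seq_along(Bs)
    canon[idx] <- as.integer(vals[cbind(seq_along(Bs), wit)])
    perm[idx] <- apply(P[wit, , drop = FALSE], 1L, perm_pack)
  }
  list(canon = canon, perm = perm)
}

new_canonical_map <- function(k, canon, perm) {
  canonicals <- sort(unique(canon))
  structure(list(
    k = k, b = gbits(k),
    canon_of = match(canon, canonicals) - 1L,      # 0-based canonical index
    perm = perm,                                   # packed witness per B
    canonicals = canonicals,
    connected = vapply(canonicals, function(bits) is_connected(graphette(k, bits)),
                       logical(1))
  ), class = "canonical_map")
}

#' Build the full canonical map for k-node graphettes
#'
#' Scans all 2^b(k) bit vectors; each class's canonical is its numeric
#' minimum, and the stored witness is the lexicographically first
#' permutation carrying the bit vector onto it (so every canonical's own
#' witness is the identity).
#'
#' @param k node count, 1..8.  k = 7 takes on the order of an hour on one
#'   core; k = 8 is only realistic partitioned across many machines (see
#'   [build_partition()]).
#' @return an object of class `"canonical_map"`: `k`, `b`, `canon_of`
#'   (0-based canonical index per bit vector), `perm` (packed witness
#'   permutation per bit vector), `canonicals` (ascending bit vectors of
#'   the NC(k) class representatives), `connected` (per-canonical flag).
#' @examples
#' m <- build_canonical_map(4)
#' length(m$canonicals)   # 11 isomorphism classes on 4 nodes
#' @export
build_canonical_map <- function(k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > 8L)
    stop("k must be in 1..8", call. = FALSE)
  res <- canon_scan(k, 0, 2^gbits(k))
  new_canonical_map(k, res$canon, res$perm)
}

#' @export
print.canonical_map <- function(x, ...) {
  cat(sprintf("<canonical_map> k = %d: %d bit vectors -> %d canonicals (%d connected)\n",
              x$k, 2^x$b, length(x$canonicals), sum(x$connected)))
  invisible(x)
}

#' Build one partition of the canonical scan
#'
#' Splits the bit-vector range [0, 2^b(k)) into `m` near-equal parts and
#' evaluates part `part`: every B in the part is mapped to its
#' lowest-numbered isomorph *within the part* (its temporary canonical),
#' with a witness permutation.  Parts are merged by [sift_canonicals()].
#'
#' @param k node count.
#' @param part 0-based part index.
#' @param m number of parts.
#' @return an object of class `"partition_result"`: `k`, `part`, `m`,
#'   `lo`, `hi` (range covered, hi exclusive), `canon` (temporary
#'   canonical bit vector per B in the range), `perm` (packed witnesses).
#' @export
build_partition <- function(k, part, m) {
  k <- as.integer(k); part <- as.integer(part); m <- as.integer(m)
  if (m < 1L || part < 0L || part >= m) stop("need 0 <= part < m", call. = FALSE)
  n <- 2^gbits(k)
  lo <- as.integer(floor(part * n / m)); hi <- as.integer(floor((part + 1) * n / m))
  if (hi <= lo) stop("empty partition: m exceeds the number of bit vectors", call. = FALSE)
  res <- canon_scan(k, lo, hi, min_lo = lo, min_hi = hi)
  structure(list(k = k, part = part, m = m, lo = lo, hi = hi,
                 canon = res$canon, perm = res$perm),
            class = "partition_result")
}

#' Merge partition results into the full canonical map ("sifting")
#'
#' The parts' temporary canonicals are merged into a global list: scanning
#' temporaries in ascending order, each is either isomorphic to an
#' already-accepted global canonical (and is re-pointed to it, composing
#' witnesses) or becomes a new global canonical.  The pass repeats until
#' no temporary is re-pointed.  The result is bit-for-bit identical to
#' [build_canonical_map()] run serially.
#'
#' @param parts list of `"partition_result"` objects covering
#'   [0, 2^b(k)) disjointly.
#' @return a `"canonical_map"`.
#' @export
sift_canonicals <- function(parts) {
  if (!length(parts) || !all(vapply(parts, inherits, logical(1), "partition_result")))
    stop("parts must be a list of partition_result objects", call. = FALSE)
  k <- parts[[1L]]$k
  if (!all(vapply(parts, `[[`, integer(1), "k") == k))
    stop("parts disagree on k", call. = FALSE)
  ord <- order(vapply(parts, `[[`, numeric(1), "lo"))
  parts <- parts[ord]
  n <- 2^gbits(k)
  los <- vapply(parts, `[[`, numeric(1), "lo")
  his <- vapply(parts, `[[`, numeric(1), "hi")
  if (los[1L] != 0 || his[length(his)] != n || any(los[-1L] != his[-length(his)]))
    stop(errorCondition("parts do not tile [0, 2^b(k)) disjointly",
                        class = c("graphette_partition_error", "error", "condition")))
  canon <- unlist(lapply(parts, `[[`, "canon"))
  perm <- unlist(lapply(parts, `[[`, "perm"))

  # point each temporary canonical at the global minimum of its class
  temps <- sort(unique(canon))
  target <- temps                       # current global canonical per temp
  tperm <- vapply(temps, function(t) perm_pack(perm_identity(k)), integer(1))
  dkey <- vapply(temps, function(t) paste(degree_sequence(graphette(k, t)), collapse = ","),
                 character(1))
  repeat {
    repointed <- FALSE
    globals <- list()                   # degree-key -> accepted canonicals
    for (i in seq_along(temps)) {
      cur <- target[i]
      key <- dkey[i]
      hit <- NA
      for (cand in globals[[key]]) {
        iso <- are_isomorphic(graphette(k, temps[i]), graphette(k, cand))
        if (iso$isomorphic) { hit <- cand; hitw <- iso$witness; break }
      }
      if (!is.na(hit)) {
        if (hit != cur) {
          target[i] <- hit
          tperm[i] <- perm_pack(hitw)
          repointed <- TRUE
        }
      } else {
        globals[[key]] <- c(globals[[key]], temps[i])
      }
    }
    if (!repointed) break
  }

  idx <- match(canon, temps)
  out_canon <- target[idx]
  # The composed witness (temp witness after part witness) carries B onto
  # its global canonical, but the serial builder stores the
  # lexicographically smallest such permutation; normalise so the sifted
  # map is bit-identical to the serial one.
  out_perm <- integer(n)
  canon_cache <- list()
  for (i in seq_len(n)) {
    B <- i - 1L
    if (B == out_canon[i]) { out_perm[i] <- perm_pack(perm_identity(k)); next }
    p1 <- perm_unpack(perm[i], k)
    p2 <- perm_unpack(tperm[idx[i]], k)
    composed <- perm_compose(p2, p1)
    g <- graphette(k, B)
    key <- as.character(out_canon[i])
    h <- canon_cache[[key]]
    if (is.null(h)) {
      h <- list(A = adjacency_matrix(graphette(k, out_canon[i])),
                d = node_degrees(graphette(k, out_canon[i])))
      canon_cache[[key]] <- h
    }
    w <- iso_search(adjacency_matrix(g), h$A, node_degrees(g), h$d)
    if (is.null(w)) w <- composed       # unreachable if the merge is correct
    out_perm[i] <- perm_pack(w)
  }
  new_canonical_map(k, out_canon, out_perm)
}

#' Assign global orbit IDs across all canonicals
#'
#' Canonicals are processed in ascending bit-vector order; within each,
#' orbits are numbered by increasing minimal node index; IDs are
#' consecutive integers from 0 across the whole table.  The total equals
#' the summed orbit counts of all canonical graphettes.
#'
#' @param map a `"canonical_map"`.
#' @return an object of class `"orbit_table"`: `k`, `orbit_id` (NC(k) x k
#'   integer matrix whose entry at row c, column u+1 is the global ID of
#'   node position u in canonical c), `num_orbits`.
#' @export
assign_global_orbits <- function(map) {
  stopifnot(inherits(map, "canonical_map"))
  k <- map$k
  nc <- length(map$canonicals)
  ids <- matrix(0L, nc, k)
  nxt <- 0L
  for (ci in seq_len(nc)) {
    orb <- enumerate_orbits(graphette(k, map$canonicals[ci]))
    local <- match(orb$colors, sort(unique(orb$colors))) - 1L
    ids[ci, ] <- nxt + local
    nxt <- nxt + orb$n_orbits
  }
  structure(list(k = k, orbit_id = ids, num_orbits = nxt), class = "orbit_table")
}

#' @export
print.orbit_table <- function(x, ...) {
  cat(sprintf("<orbit_table> k = %d: %d canonicals, %d global orbits\n",
              x$k, nrow(x$orbit_id), x$num_orbits))
  invisible(x)
}

#' Build the canonical map and orbit table together
#'
#' @param k node count, 1..8.
#' @return a list of class `"graphette_tables"` with elements `map` and
#'   `orbits`.
#' @export
graphette_tables <- function(k) {
  map <- build_canonical_map(k)
  structure(list(map = map, orbits = assign_global_orbits(map)),
            class = "graphette_tables")
}

#' Constant-time graphette and orbit lookup
#'
#' Given the bit vector of k nodes taken in some order, returns which
#' canonical graphette it is, the witness permutation onto the canonical,
#' and the global orbit ID of each of the k original positions: the
#' original position u inherits the ID of canonical position
#' `witness[u+1]`.
#'
#' @param tables a `"graphette_tables"` object (or list with `map` and
#'   `orbits`).
#' @param bits bit-vector integer in `[0, 2^b(k))`.
#' @return a list: `canon_index` (0-based), `canon_bits`, `witness`
#'   (image vector), `orbit_ids` (length-k integer vector, per original
#'   position), `connected` (logical).
#' @export
graphette_lookup <- function(tables, bits) {
  map <- tables$map; orbits <- tables$orbits
  k <- map$k
  bits <- as.integer(bits)
  if (length(bits) != 1L || is.na(bits) || bits < 0L || bits >= 2^map$b)
    stop("bits out of range for these tables", call. = FALSE)
  ci <- map$canon_of[bits + 1L]
  w <- perm_unpack(map$perm[bits + 1L], k)
  list(canon_index = ci,
       canon_bits = map$canonicals[ci + 1L],
       witness = w,
       orbit_ids = orbits$orbit_id[ci + 1L, w + 1L],
       connected = map$connected[ci + 1L])
}
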
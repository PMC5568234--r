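#' Table persistence
#'
#' Tables are stored as little-endian 32-bit words under a common path
#' prefix, one header per indexed file, so a k = 8 map (2^28 entries)
#' stays within the 4-bytes-per-entry budget that makes the whole table
#' practical to ship:
#'
#' * `<prefix>_map.bin` — header, then 2^b(k) words: canonical index in
#'   bits 0-13, connected flag in bit 14.
#' * `<prefix>_perm.bin` — 2^b(k) words: the witness permutation, k
#'   3-bit images packed LSB-first.
#' * `<prefix>_orbit.bin` — header, then NC(k) x k words of global orbit
#'   IDs, row-major by canonical.
#' * `<prefix>_canon.txt` — human-readable listing: one line per
#'   canonical with index, bit vector, connectedness and orbit colours.
#'
#' Header layout: 8-byte magic `"GRFTABLE"`, then five words — format
#' version (1), k, b(k), NC(k), num_orbits.
#'
#' @name table_store
NULL

TABLE_MAGIC <- "GRFTABLE"
PART_MAGIC <- "GRFPARTS"
TABLE_VERSION <- 1L

store_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "graphette_store_error", "error", "condition")))
}

write_header <- function(con, k, nc, num_orbits) {
  writeChar(TABLE_MAGIC, con, nchars = 8L, eos = NULL)
  writeBin(as.integer(c(TABLE_VERSION, k, gbits(k), nc, num_orbits)),
           con, size = 4L, endian = "little")
}

read_header <- function(con, path) {
  magic <- readChar(con, 8L, useBytes = TRUE)
  if (!identical(magic, TABLE_MAGIC))
    store_error(gettextf("bad magic in %s", path), "graphette_bad_magic")
  h <- readBin(con, integer(), n = 5L, size = 4L, endian = "little")
  if (length(h) < 5L)
    store_error(gettextf("truncated header in %s", path), "graphette_truncated")
  if (h[1L] != TABLE_VERSION)
    store_error(gettextf("unsupported format version %d in %s", h[1L], path),
                "graphette_bad_version")
  if (h[3L] != gbits(h[2L]))
    store_error(gettextf("inconsistent header (b != k(k-1)/2) in %s", path),
                "graphette_header_mismatch")
  list(k = h[2L], b = h[3L], nc = h[4L], num_orbits = h[5L])
}

read_words <- function(con, n, path) {
  w <- readBin(con, integer(), n = n, size = 4L, endian = "little")
  if (length(w) != n)
    store_error(gettextf("truncated payload in %s (expected %d words, got %d)",
                         path, n, length(w)), "graphette_truncated")
  w
}

#' Write canonical and orbit tables to disk
#'
#' @param tables a `"graphette_tables"` object (or list with `map`,
#'   `orbits`).
#' @param prefix path prefix; four files `<prefix>_{map,perm,orbit}.bin`
#'   and `<prefix>_canon.txt` are written.
#' @return `prefix`, invisibly.
#' @export
write_tables <- function(tables, prefix) {
  map <- tables$map; orbits <- tables$orbits
  stopifnot(inherits(map, "canonical_map"))
  k <- map$k
  nc <- length(map$canonicals)

  con <- file(paste0(prefix, "_map.bin"), "wb"); on.exit(close(con))
  write_header(con, k, nc, orbits$num_orbits)
  writeBin(map$canon_of + bitwShiftL(as.integer(map$connected[map$canon_of + 1L]), 14L),
           con, size = 4L, endian = "little")
  close(con); on.exit()

  con <- file(paste0(prefix, "_perm.bin"), "wb"); on.exit(close(con))
  writeBin(map$perm, con, size = 4L, endian = "little")
  close(con); on.exit()

  con <- file(paste0(prefix, "_orbit.bin"), "wb"); on.exit(close(con))
  write_header(con, k, nc, orbits$num_orbits)
  writeBin(as.integer(t(orbits$orbit_id)), con, size = 4L, endian = "little")
  close(con); on.exit()

  lines <- vapply(seq_len(nc), function(ci) {
    orb <- orbits$orbit_id[ci, ]
    paste(ci - 1L, map$canonicals[ci], as.integer(map$connected[ci]),
          paste(orb - min(orb), collapse = " "), sep = "\t")
  }, character(1))
  writeLines(c("#index\tbits\tconnected\torbit_colors", lines),
             paste0(prefix, "_canon.txt"))
  invisible(prefix)
}

#' Read tables written by [write_tables()]
#'
#' Headers are validated against `k` and against each other; a missing
#' file, magic/version/k mismatch or truncated payload raises a classed
#' error (`graphette_file_missing`, `graphette_bad_magic`,
#' `graphette_bad_version`, `graphette_header_mismatch`,
#' `graphette_truncated`) and no partial table is returned.
#'
#' @param prefix path prefix used at write time.
#' @param k expected node count.
#' @return a `"graphette_tables"` object.
#' @export
read_tables <- function(prefix, k) {
  k <- as.integer(k)
  paths <- paste0(prefix, c("_map.bin", "_perm.bin", "_orbit.bin"))
  missing <- !file.exists(paths)
  if (any(missing))
    store_error(gettextf("missing table file: %s", paths[which(missing)[1L]]),
                "graphette_file_missing")
  n <- 2^gbits(k)

  con <- file(paths[1L], "rb"); on.exit(close(con))
  h <- read_header(con, paths[1L])
  if (h$k != k)
    store_error(gettextf("%s holds k = %d, not k = %d", paths[1L], h$k, k),
                "graphette_header_mismatch")
  words <- read_words(con, n, paths[1L])
  close(con); on.exit()
  canon_idx <- bitwAnd(words, bitwShiftL(1L, 14L) - 1L)
  conn_bit <- bitwAnd(bitwShiftR(words, 14L), 1L) == 1L

  con <- file(paths[2L], "rb"); on.exit(close(con))
  perm <- read_words(con, n, paths[2L])
  close(con); on.exit()

  con <- file(paths[3L], "rb"); on.exit(close(con))
  ho <- read_header(con, paths[3L])
  if (ho$k != k || ho$nc != h$nc || ho$num_orbits != h$num_orbits)
    store_error(gettextf("orbit file header disagrees with map header under %s", prefix),
                "graphette_header_mismatch")
  ids <- read_words(con, h$nc * k, paths[3L])
  close(con); on.exit()

  # reconstruct canonical bit vectors: the first bit vector pointing at a
  # canonical index is the class minimum, i.e. the canonical itself
  first <- !duplicated(canon_idx)
  canonicals <- integer(h$nc)
  canonicals[canon_idx[first] + 1L] <- (seq_len(n) - 1L)[first]
  if (length(canonicals) != h$nc || is.unsorted(canonicals, strictly = TRUE))
    store_error(gettextf("canonical set reconstructed from %s violates invariants",
                         paths[1L]), "graphette_header_mismatch")
  map <- structure(list(k = k, b = gbits(k), canon_of = canon_idx, perm = perm,
                        canonicals = canonicals,
                        connected = conn_bit[canonicals + 1L]),
                   class = "canonical_map")
  orbits <- structure(list(k = k,
                           orbit_id = matrix(ids, h$nc, k, byrow = TRUE),
                           num_orbits = h$num_orbits),
                      class = "orbit_table")
  structure(list(map = map, orbits = orbits), class = "graphette_tables")
}

#' Write one partition result for a later sift
#'
#' @param part a `"partition_result"` from [build_partition()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_partition <- function(part, path) {
  stopifnot(inherits(part, "partition_result"))
  con <- file(path, "wb"); on.exit(close(con))
  writeChar(PART_MAGIC, con, nchars = 8L, eos = NULL)
  writeBin(as.integer(c(TABLE_VERSION, part$k, part$m, part$part, part$lo, part$hi)),
           con, size = 4L, endian = "little")
  writeBin(as.integer(part$canon), con, size = 4L, endian = "little")
  writeBin(as.integer(part$perm), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a partition result written by [write_partition()]
#'
#' @param path partition file.
#' @return a `"partition_result"`.
#' @export
read_partition <- function(path) {
  if (!file.exists(path))
    store_error(gettextf("missing partition file: %s", path), "graphette_file_missing")
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readChar(con, 8L, useBytes = TRUE)
  if (!identical(magic, PART_MAGIC))
    store_error(gettextf("bad magic in %s", path), "graphette_bad_magic")
  h <- readBin(con, integer(), n = 6L, size = 4L, endian = "little")
  if (length(h) < 6L || h[1L] != TABLE_VERSION)
    store_error(gettextf("bad partition header in %s", path), "graphette_bad_version")
  n <- h[6L] - h[5L]
  canon <- read_words(con, n, path)
  perm <- read_words(con, n, path)
  structure(list(k = h[2L], part = h[4L], m = h[3L], lo = h[5L], hi = h[6L],
                 canon = canon, perm = perm),
            class = "partition_result")
}
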
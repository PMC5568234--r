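test_that("isomorphism testing with degree pruning and a valid witness", {
  # the three one-edge 3-graphettes are pairwise isomorphic
  e10 <- graphette(3, 1); e21 <- graphette(3, 4)
  r <- are_isomorphic(e10, e21)
  expect_true(r$isomorphic)
  expect_identical(apply_permutation(e10, r$witness)$bits, e21$bits)
  # degree mismatch short-circuits
  expect_false(are_isomorphic(g_path(3), graphette(3, 4))$isomorphic)
  expect_error(are_isomorphic(g_path(3), g_path(4)), "differ in size")
  set.seed(31)
  for (k in 3:7) {
    for (rep in 1:20) {
      g <- graphette(k, random_bits(k))
      h <- apply_permutation(g, random_perm(k))
      r <- are_isomorphic(g, h)
      expect_true(r$isomorphic)
      expect_identical(apply_permutation(g, r$witness)$bits, h$bits)
    }
  }
})

test_that("are_isomorphic agrees with the igraph oracle", {
  set.seed(17)
  for (k in 4:6) {
    for (rep in 1:500) {
      g <- graphette(k, random_bits(k))
      h <- graphette(k, random_bits(k))
      mine <- are_isomorphic(g, h)$isomorphic
      oracle <- igraph::isomorphic(ig_from_graphette(g), ig_from_graphette(h))
      if (mine != oracle)
        fail(sprintf("disagreement at k=%d: %d vs %d", k, g$bits, h$bits))
    }
  }
  succeed()
})

test_that("automorphism groups are exact", {
  expect_length(generate_automorphisms(g_clique(3)), 6L)
  # 3-path 0-1-2: identity and the endpoint swap
  p3 <- g_path(3)
  auts <- generate_automorphisms(p3)
  expect_length(auts, 2L)
  expect_true(all(vapply(auts, function(pi)
    apply_permutation(p3, pi)$bits == p3$bits, logical(1))))
  # 5-cycle: dihedral group of order 10, frozen from the brute-force count
  c5 <- g_cycle(5)
  expect_length(generate_automorphisms(c5), 10L)
  # independent route: filter all 120 permutations directly
  brute <- perms_count_brute(c5)
  expect_identical(length(generate_automorphisms(c5)), brute)
})

test_that("Aut(g) properties: identity, Lagrange, closure, complement equality", {
  set.seed(23)
  for (k in 3:6) {
    for (rep in 1:10) {
      g <- graphette(k, random_bits(k))
      auts <- generate_automorphisms(g)
      packed <- vapply(auts, function(p) sum(p * 8^(0:(k - 1))), numeric(1))
      expect_true(sum(0:(k - 1) * 8^(0:(k - 1))) %in% packed)  # identity
      expect_identical(factorial(k) %% length(auts), 0)        # Lagrange
      # sampled closure: sigma o pi stays in Aut(g)
      for (s in 1:5) {
        pi <- auts[[sample.int(length(auts), 1)]]
        sigma <- auts[[sample.int(length(auts), 1)]]
        expect_true(sum(sigma[pi + 1] * 8^(0:(k - 1))) %in% packed)
      }
    }
  }
  # Aut(g) == Aut(complement(g)) as sets, for every canonical at k <= 6
  for (k in 3:6) {
    for (bits in get_tables(k)$map$canonicals) {
      g <- graphette(k, bits)
      a1 <- generate_automorphisms(g)
      a2 <- generate_automorphisms(graphette_complement(g))
      expect_identical(a1, a2)
    }
  }
})

test_that("cycle decomposition matches the worked example", {
  expect_identical(cycles_of(c(2L, 0L, 1L, 3L, 5L, 4L)),
                   list(c(0L, 2L, 1L), 3L, c(4L, 5L)))
  expect_identical(cycles_of(0:4), as.list(0:4))
  expect_identical(cycles_of(c(1L, 0L)), list(c(0L, 1L)))
  expect_error(cycles_of(c(0L, 0L)), "not a permutation")
  # successive elements are images; cycles partition the node set
  set.seed(41)
  for (rep in 1:50) {
    k <- sample(2:8, 1)
    pi <- random_perm(k)
    cyc <- cycles_of(pi)
    expect_identical(sort(unlist(cyc)), 0:(k - 1))
    for (c in cyc)
      for (i in seq_along(c))
        expect_identical(pi[c[i] + 1L], c[if (i == length(c)) 1L else i + 1L])
  }
})

test_that("orbit enumeration colours nodes by minimal orbit member", {
  o <- enumerate_orbits(graphette(3, 1))      # edge (1,0) + isolated node 2
  expect_identical(o$n_orbits, 2L)
  expect_identical(o$colors, c(0L, 0L, 2L))
  o <- enumerate_orbits(g_path(3))            # path 0-1-2, centre node 1
  expect_identical(o$n_orbits, 2L)
  expect_identical(o$colors[2], 1L)
  expect_identical(o$colors[c(1, 3)], c(0L, 0L))
  # 5-cycle is vertex-transitive: one orbit
  expect_identical(enumerate_orbits(g_cycle(5))$n_orbits, 1L)
})

test_that("orbits refine degree classes and are complement-symmetric", {
  set.seed(53)
  for (k in 3:6) {
    for (rep in 1:15) {
      g <- graphette(k, random_bits(k))
      o <- enumerate_orbits(g)
      d <- degree_sequence(g)  # not positional; recompute positionally
      dpos <- vapply(0:(k - 1), function(u)
        sum(graphette_edges(g) == u), integer(1))
      for (col in unique(o$colors))
        expect_length(unique(dpos[o$colors == col]), 1L)
      expect_identical(enumerate_orbits(graphette_complement(g))$n_orbits, o$n_orbits)
    }
  }
})

test_that("same final colour implies a connecting automorphism (all k<=5 canonicals)", {
  for (k in 2:5) {
    P <- all_perms(k)
    for (bits in get_tables(k)$map$canonicals) {
      g <- graphette(k, bits)
      colors <- enumerate_orbits(g)$colors
      for (u in 0:(k - 2)) for (v in (u + 1):(k - 1)) {
        if (colors[u + 1] != colors[v + 1]) next
        hit <- FALSE
        for (j in seq_len(nrow(P))) {        # brute force over all k! perms
          pi <- P[j, ]
          if (pi[u + 1] == v && apply_permutation(g, pi)$bits == g$bits) {
            hit <- TRUE; break
          }
        }
        if (!hit) fail(sprintf("no automorphism maps %d to %d in k=%d bits=%d",
                               u, v, k, bits))
      }
    }
  }
  succeed()
})
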
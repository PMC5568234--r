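test_that("k-set sampling honours method preconditions and set validity", {
  tri <- host_graph(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  set.seed(1)
  for (method in c("uniform", "local", "edge"))
    expect_setequal(sample_kset(tri, 3, method), 0:2)
  empty <- host_graph(NULL, isolated = paste0("n", 1:10))
  for (rep in 1:20) {
    s <- sample_kset(empty, 3, "local")     # neighbourhood always exhausted
    expect_length(s, 3L)
    expect_identical(anyDuplicated(s), 0L)
  }
  expect_error(sample_kset(empty, 3, "edge"), "at least one edge")
  expect_error(sample_kset(tri, 4), "exceeds")
})

test_that("edge-based samples from a star always contain the centre", {
  star <- host_graph(cbind("c", paste0("l", 1:5)))
  set.seed(2)
  for (rep in 1:200) expect_true(0L %in% sample_kset(star, 3, "edge"))
})

test_that("clique and edgeless hosts give point-mass distributions", {
  tab3 <- get_tables(3)
  k5 <- host_graph(t(utils::combn(paste0("n", 1:5), 2)))
  d <- estimate_distribution(k5, 3, 100, "uniform", 11, tab3)
  expect_identical(d$counts[d$canonicals == 7L], 100L)
  expect_identical(sum(d$counts), 100L)

  tab4 <- get_tables(4)
  empty <- host_graph(NULL, isolated = paste0("n", 1:10))
  d0 <- estimate_distribution(empty, 4, 50, "local", 11, tab4)
  expect_identical(d0$counts[1L], 50L)
})

test_that("uniform frequencies on a 4-path converge to the exhaustive distribution", {
  tab3 <- get_tables(3)
  host <- host_graph(rbind(c("a", "b"), c("b", "c"), c("c", "d")))
  exact <- exhaustive_counts(host, 3, tab3) / choose(4, 3)
  # 2 of 4 subsets are 3-paths, 2 are edge-plus-isolate
  expect_identical(sort(exact[exact > 0]), c(0.5, 0.5))
  N <- 10000L
  d <- estimate_distribution(host, 3, N, "uniform", 13, tab3)
  tol <- 3 * sqrt(exact * (1 - exact) / N)
  expect_true(all(abs(d$freq - exact) <= tol + 1e-12))
})

test_that("sampling is deterministic under a fixed seed", {
  host <- er_host(30, 0.15, seed = 8)
  tab4 <- get_tables(4)
  for (method in c("uniform", "local", "edge")) {
    d1 <- estimate_distribution(host, 4, 500, method, 99, tab4)
    d2 <- estimate_distribution(host, 4, 500, method, 99, tab4)
    expect_identical(d1$counts, d2$counts)
    o1 <- orbit_degree_vectors(host, 4, 500, method, 99, tab4)
    o2 <- orbit_degree_vectors(host, 4, 500, method, 99, tab4)
    expect_identical(o1$counts, o2$counts)
    expect_false(identical(
      estimate_distribution(host, 4, 500, method, 100, tab4)$counts, d1$counts))
  }
})

test_that("orbit degree vectors conserve N * k and respect orbit structure", {
  tab3 <- get_tables(3)
  k3 <- host_graph(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  odv <- orbit_degree_vectors(k3, 3, 10, "uniform", 5, tab3)
  tri_orbit <- graphette_lookup(tab3, 7)$orbit_ids[1] + 1L
  expect_identical(odv$counts[, tri_orbit], rep(10L, 3))
  expect_identical(sum(odv$counts), 30L)

  host <- er_host(25, 0.2, seed = 12)
  for (method in c("uniform", "edge")) {
    o <- orbit_degree_vectors(host, 5, 300, method, 21, get_tables(5))
    expect_identical(sum(o$counts), 300L * 5L)
    expect_true(all(o$counts >= 0L))
  }
})

test_that("star centre never scores endpoint-orbit hits at k = 3", {
  tab3 <- get_tables(3)
  star <- host_graph(cbind("c", paste0("l", 1:3)))
  # of the four 3-subsets, three contain the centre and induce a 3-path
  # centred on c; the leaves-only subset is edgeless (leaves are pairwise
  # non-adjacent), so c can never occupy a path-endpoint orbit
  path_lookup <- graphette_lookup(tab3, 3L)   # path 0-1-2 with centre 0
  centre_orbit <- path_lookup$orbit_ids[1]
  endpoint_orbit <- path_lookup$orbit_ids[2]
  odv <- orbit_degree_vectors(star, 3, 2000, "uniform", 31, tab3)
  expect_identical(odv$counts[1, endpoint_orbit + 1L], 0L)
  expect_true(odv$counts[1, centre_orbit + 1L] > 0L)
  # leaves never sit in the path-centre orbit
  expect_identical(sum(odv$counts[2:4, centre_orbit + 1L]), 0L)
})

test_that("nodes sharing a global orbit ID within a sample share a degree there", {
  host <- er_host(20, 0.25, seed = 44)
  tab4 <- get_tables(4)
  set.seed(77)
  for (rep in 1:100) {
    nodes <- sample_kset(host, 4, "local")
    bits <- induced_bits(host, nodes)
    r <- graphette_lookup(tab4, bits)
    g <- graphette(4, bits)
    dpos <- vapply(0:3, function(u) sum(graphette_edges(g) == u), integer(1))
    for (id in unique(r$orbit_ids))
      expect_length(unique(dpos[r$orbit_ids == id]), 1L)
  }
})

test_that("distribution and ODV TSV outputs are faithful", {
  dir <- withr::local_tempdir()
  host <- host_graph(rbind(c("a", "b"), c("b", "c"), c("c", "d")))
  tab3 <- get_tables(3)
  d <- estimate_distribution(host, 3, 200, "uniform", 3, tab3)
  write_distribution(d, file.path(dir, "dist.tsv"))
  f <- read.delim(file.path(dir, "dist.tsv"))
  expect_identical(f$count, d$counts)
  expect_identical(sum(f$count), 200L)
  expect_equal(sum(f$frequency), 1)
  odv <- orbit_degree_vectors(host, 3, 200, "uniform", 3, tab3)
  write_odv(odv, file.path(dir, "odv.tsv"))
  fo <- read.delim(file.path(dir, "odv.tsv"))
  expect_identical(fo$node, host$labels)
  expect_identical(sum(as.matrix(fo[, -1])), 600L)
})
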
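Package: graphette
Title: Canonical Graphettes, Automorphism Orbits and Graphlet Sampling
Version: 0.1.0
Authors@R: person("Graphette", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Canonizes every induced k-node subgraph (k <= 8) of an
    undirected network, connected or not ("graphettes"), via precomputed
    lookup tables from lower-triangular adjacency bit vectors to canonical
    representatives, enumerates the automorphism orbits of every canonical
    graphette, and uses the tables for constant-time graphette and orbit
    identification when statistically sampling k-node sets from a large
    host network. Includes a partitioned ("sifting") table builder for
    large k, a compact binary table format, samplers for uniform, local
    and edge-based k-set selection, and per-node orbit degree vectors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    utils
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
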
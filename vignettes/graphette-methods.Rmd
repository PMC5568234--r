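---
title: "Canonical graphettes and orbit sampling: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canonical graphettes and orbit sampling: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphette)
```

## The model

A *graphette* is any induced subgraph on k nodes of an undirected simple
graph — the generalisation of a graphlet that drops the connectedness
requirement, which is unavoidable once k-sets are drawn by sampling
rather than by enumeration. With k fixed and small (k ≤ 8 here), a
graphette is fully described by b(k) = k(k−1)/2 bits: the lower triangle
of its adjacency matrix, pair (i, j) with i > j at bit position
i(i−1)/2 + j, least significant bit first. Every graph on k labelled
nodes is thus an integer in [0, 2^b(k)), and isomorphism is the orbit
relation of the permutation group S_k acting on these integers.

Three structures are precomputed per k:

* the **canonical map**: every bit vector B points to K(B), the
  numerically smallest integer in its isomorphism class, along with a
  witness permutation carrying B onto K(B);
* the **orbit table**: for every canonical graphette, the partition of
  its k node positions into automorphism orbits, with a single global ID
  space across all canonicals (consecutive integers from 0, canonicals in
  ascending order, orbits within a canonical ordered by smallest member);
* a per-canonical **connectivity flag**.

Together these make the identification of any sampled k-set O(1): encode
the induced adjacency (b(k) pair checks), index two arrays, and push the
witness through the orbit row.

## Numbering conventions

The encoding fixes lower-triangle, row-major, LSB-first. This is a
convention, not a finding: *counts* (numbers of canonicals, numbers of
orbits, class sizes) are invariant under any re-encoding, while the
specific integer value of a canonical representative is not. Published
implementations of the same idea have used the upper triangle; their
canonical integers differ from ours, their counts do not. All tests and
acceptance targets therefore compare counts and structural properties,
never specific canonical integers against external sources.

Node positions are 0-based everywhere (matching the bit formula), and
permutations are image vectors: `pi[i + 1]` is the image of position i.
The witness stored for B is the *lexicographically smallest* permutation
carrying B onto K(B); this makes the table a pure function of the input
(no dependence on scan order or tie-breaking accidents), and gives every
canonical the identity as witness.

## Canonization

The builder must map all 2^b(k) bit vectors. The reference procedure —
ascending scan, testing each B against previously found canonicals by
degree-pruned permutation search — is faithful but interpreter-hostile.
Because the canonical is the class *minimum*, the same result is obtained
by computing, for each B, the minimum over all k! permuted values. That
inner loop vectorises completely: a chunk of bit vectors becomes a 0/1
matrix (rows = graphettes, columns = bit positions), each permutation
becomes a column of powers of two (the permuted position of every bit),
and one matrix product yields every permuted value of every graphette in
the chunk. Row minima are the canonicals; the first column attaining the
minimum is the lex-smallest witness. k = 6 (32768 × 720) takes about a
second; k = 7 stays feasible on one core in about an hour (it is excluded
from the default test suite for time, not correctness — the CLI runs it);
k = 8 needs the partitioned route below.

### Partitioned builds ("sifting")

For large k the range [0, 2^b(k)) is split into m parts, each evaluated
independently: within part i, every B maps to the smallest member of its
class *that lies in the part* (its temporary canonical), with a witness.
Merging scans the union of temporary canonicals in ascending order
against the accepted global list using the degree-pruned backtracking
isomorphism test, re-pointing temporaries until a pass makes no change.
One pass already suffices in this in-memory setting — the global minimum
of a class is necessarily some part's temporary canonical — but the loop
runs to a fixed point regardless, since a distributed merge may see
partial lists. Composed witnesses (part witness, then merge witness) are
valid but not necessarily lex-minimal, so the merge recomputes each
non-canonical's witness with the backtracking search; this is what makes
the sifted map bit-identical to the serial one, which the tests assert
for m ∈ {2, 4, 8} and for uneven hand-made ranges.

This also keeps two genuinely independent routes to the same table — the
vectorised minimum-of-orbit scan and backtracking permutation search —
checking each other.

## Automorphisms and orbits

`generate_automorphisms()` backtracks over images restricted to
equal-degree nodes, pruning on adjacency consistency with all previously
placed nodes; this returns exactly the permutations fixing the graph,
ordered lexicographically, without touching most of S_k. Graphettes with
more than b(k)/2 edges are processed through their complement, which has
the same automorphism group.

`enumerate_orbits()` colours each node with its own index, then merges:
for each cycle of each automorphism, all nodes carrying any colour found
in the cycle are recoloured to the cycle's minimum, repeating the pass
over cycles until stable. A single pass over cycles in an unfavourable
order can under-merge (two cycles that share an orbit only through a
third), hence the fixed-point iteration; the recolouring step propagates
whole colour classes, so convergence is fast. At the fixed point each
node's colour is the smallest index in its orbit, colours refine degree
classes, and a graphette and its complement have identical colourings.

Two conservation laws double-check the tables and are tested at every
k ≤ 6: orbit–stabilizer (Σ over canonicals of k!/|Aut| = 2^b(k), e.g.
1 + 3 + 3 + 1 = 8 at k = 3) and the complement involution on canonical
indices (complementation permutes the canonical list, and doing it twice
is the identity).

## Sampling

Three k-set strategies are provided. Only the first is defined by a
single sentence; the expansion rule of the other two was an open design
choice, fixed as follows:

* **uniform** — a uniformly random k-subset;
* **local** — uniform seed node; then repeatedly pick uniformly among the
  *distinct* nodes adjacent to the current set and not in it; if that
  neighbourhood is empty (disconnected hosts, small components), pick a
  uniform non-member instead;
* **edge** — uniform seed edge (both endpoints), then expand as in local.

Uniform-over-distinct-neighbours (rather than over edge endpoints, which
would weight candidates by their connectivity to the set) was chosen as
the simplest rule that is well-defined on every host; the fallback
guarantees termination on any host with at least k nodes. Draws are with
replacement across samples: the estimator targets the distribution over
k-sets, and deduplication would bias it on small hosts. All randomness
flows through R's global generator, seeded once per run, so a fixed seed
reproduces counts bit-for-bit across platforms.

Counts are the source of truth; frequencies are derived. The orbit
degree vector of node u accumulates, over samples containing u, one hit
at the global orbit ID of u's position — so entries over all nodes and
orbits total N·k exactly, a conservation the tests check on every run.

## Tunable parameters

| parameter | meaning | default / range | notes |
|---|---|---|---|
| `k` | graphette size, nodes | 1..8 | tables: seconds to k = 6; k = 7 ~1 h; k = 8 partitioned only |
| `N` | number of sampled k-sets | caller-set | binomial error of a class at frequency p is √(p(1−p)/N) |
| `method` | k-set selection | `"uniform"` | `"local"`/`"edge"` bias toward connected graphettes |
| `seed` | RNG seed | caller-set | identical output for identical inputs |
| `m`, `part` | partition count / index | build-time | any m ≥ 1; parts need not be equal |

## What the synthetic data emulates — and what it does not

Test fixtures are constructed, not collected: named structures (paths,
stars, cycles, cliques) whose automorphism groups are known closed-form;
Erdős–Rényi G(n, p) hosts at sparse p for sampling tests; and the
shipped 30-node example network (`inst/extdata/synthetic_network.txt`),
which is a G(30, 0.12) draw and is labelled synthetic. These exercise
every code path — including disconnected graphettes, exhausted
neighbourhoods and isolated nodes — and the exhaustive-enumeration
oracle on ≤ 8-node hosts verifies the sampler against ground truth.

They do not emulate the degree heterogeneity, clustering or community
structure of real biological networks. A green sampling test therefore
establishes correctness of identification and counting, not that any
particular sampling strategy estimates a real network's graphlet
spectrum efficiently; variance on heavy-tailed hosts is out of scope, as
are error bars beyond raw counts.

## Numerical and degenerate-input choices

* Bit vectors stay within 2^28 < 2^31, so everything is exact in R
  integers; the vectorised scan uses doubles (exact far beyond 2^28).
* k = 1 has b(1) = 0: one empty graphette, one orbit, bit vector 0; all
  operations accept it.
* Ties in canonization cannot occur (the minimum is unique); ties among
  witnesses are broken lexicographically.
* Self-loops in edge lists are an error, never silently dropped;
  duplicate edges collapse silently. Hosts may contain isolated nodes
  only via programmatic construction — the two-column edge-list format
  cannot express them.
* Table files are little-endian 32-bit words; headers are validated
  against recomputed b(k) and payload lengths, and truncation or
  mismatch raises a classed error with no partial table returned.

## Known limitations

* k = 8 tables are computable with the partitioned builder but take
  hundreds of CPU-weeks; nothing in the test suite exercises k = 8, and
  k ≥ 9 encodings are rejected outright.
* The canonical integers are convention-bound (see above); tables
  produced by upper-triangle implementations are not interchangeable
  with ours at the file level.
* No NAUTY-class canonical labelling: brute-force-with-pruning is the
  point at these sizes, and the k ≤ 8 lookup table makes per-sample cost
  independent of it.
* Sampling estimates carry only binomial error; no variance reduction or
  weighting schemes are implemented.
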
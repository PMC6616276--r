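---
title: "Metapath features and unsupervised rank aggregation on biomedical concept graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metapath features and unsupervised rank aggregation on biomedical concept graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbdgraph)
```

## The model

`lbdgraph` treats the biomedical literature as a heterogeneous information
network. The raw material is a table of semantic predications — triples such
as `Nicotine AFFECTS Memory`, each attributed to an article (PMID) — whose
endpoints are UMLS concepts labeled with semantic-type codes and whose
predicates come from a fixed vocabulary. The network model is deliberately
simple and faithful to how such extractions are distributed:

* one node per CUI. A concept extracted under several semantic types keeps
  a per-type observation count; only the **primary type** — the most
  commonly observed one, ties broken by first observation — participates in
  type-level computations. All observed types are retained for bookkeeping
  and round-tripping.
* one directed edge per unique (subject, predicate, object) triple. The
  number of records merged into an edge is its **weight**, and the set of
  contributing PMIDs is an edge property. Weights count records (the same
  PMID extracted twice counts twice); PMIDs are a set.

Note what this model is *not*: it is a model of the literature, not of
biology. Degree reflects how heavily a concept is studied, which is exactly
the bias the feature set below is designed to confront.

## Metapath features

Analysis is organized around **metapaths**: type-level patterns such as
`aapp-AFFECTS>menp`, where each step records a node type, a predicate, and a
traversal orientation (`<` marks a step taken against edge direction).
Between a source `s` and a target `t` the package enumerates every
node-simple path of at most `max_len` edges (default 2), groups the instances
by metapath, and computes three features per (source, target, metapath) cell:

* **count** — the raw number of path instances. Cheap and interpretable, but
  dominated by heavily studied concepts.
* **DWPC** (degree-weighted path count) — each path contributes the product
  over its `2k` node–metaedge incidences of the metaedge-specific degree
  raised to `-w`. `w = 0` recovers the count exactly; larger `w` punishes
  paths through hubs harder. The default `w = 0.4` follows the established
  hetnet-analysis convention for this statistic; it is exposed in the
  configuration because no single damping suits every corpus.
* **HeteSim** — a normalized pairwise recursion: strip the first relation on
  the source side (out-neighbor set `O`) and the last on the target side
  (in-neighbor set `I`), average the recursion over all `|O|·|I|` pairs. The
  empty path is the Kronecker delta. Odd-length paths bottom out at a single
  relation whose intermediate objects are the edge instances, so a length-1
  metapath scores `[edge exists] / (out-degree × in-degree)`. Values are in
  `[0, 1]` and, for length-2 metapaths, reduce to the closed form
  `|O∩I| / (|O|·|I|)` — an identity the test suite verifies against the
  generic recursion.

  Two variants of HeteSim exist in the literature: the arithmetic-mean
  recursion implemented here, and a cosine-normalized variant. We implement
  the arithmetic-mean form because it is the one whose recursion and delta
  base case define this package's contract; its values are probability-like
  (the chance that two walkers meet) rather than cosine-like.

Features are computed on *unweighted structure*: an edge contributes one
traversal regardless of its extraction weight. The features are defined in
terms of neighbor sets and path instances; extraction weights and PMIDs are
carried as reporting metadata. Both orientations are traversable during
enumeration (source discovery uses undirected neighborhoods, so reverse steps
must be representable); a forward-only mode is available. Paths are
node-simple, with endpoint coincidence permitted only when `source == target`
— this admits declared self-connection analyses while excluding the
out-and-back inflation that unrestricted revisiting would cause.

Metapaths of length greater than 2 are supported by the engine (the tests
exercise length 3) but the default bound is 2: on a realistic corpus the
number of paths explodes combinatorially beyond that, and 2 steps already
capture the A→B→C inference pattern classical literature-based discovery is
built on.

## Source discovery

Targets are user-chosen CUIs. Sources default to the targets' graph
neighborhood, specified as a boolean rule over undirected 1-hop
neighborhoods, e.g. `"(C0023185 OR C0025260) AND (C0028040 OR C0039663)"` —
union for `OR`, intersection for `AND`, parentheses for grouping (without
parentheses `AND` binds tighter). Target CUIs landing in the evaluated set
are kept, which permits self-connections when targets neighbor one another.

## Rank aggregation (ULARA)

Each (target, metapath, feature) column of the tensor is converted to a dense
ranking of the sources (ties share a rank; the next distinct value takes the
next integer; higher feature = better rank). Columns that are all zero carry
no ordering information and are dropped; zero-valued items within a kept
column receive that column's worst dense rank, so every ranker is a total
ranking. Multi-target runs concatenate rankers along the metapath dimension.

ULARA learns non-negative ranker weights summing to one, guided by agreement
with the pool. The update we fix (the gradient `∇ᵢ = (rᵢ − μ)²` admits
several schedules):

1. initialize `w = (1/N, …, 1/N)`;
2. weighted consensus per item: `μ(x) = Σᵢ wᵢ rᵢ(x)`;
3. disagreement per ranker: `Dᵢ = Σₓ (rᵢ(x) − μ(x))²`;
4. additive step `wᵢ ← wᵢ − η·Dᵢ/Σⱼ Dⱼ`, then clip at zero and renormalize;
5. stop when `max |Δw| < tol` or after `max_iters`.

Defaults: `η = 0.01`, `max_iters = 500`, `tol = 1e-8`. The procedure is
deterministic and has two useful exact properties: identical rankers are a
uniform fixed point (all `Dᵢ = 0`; the implementation stops immediately
rather than dividing by zero), and a lone dissenter among agreeing rankers is
monotonically down-weighted until clipped. We chose batch updates with a
weighted consensus (rather than an online per-query schedule with an
unweighted mean) for determinism and because the weighted mean is the
quantity the final scores use; with uniform initialization the first
iteration is identical under both conventions. Final ordering sorts by
aggregate score with lexicographic CUI tie-breaks, so output files are
reproducible byte for byte.

## Comparative analytics

* **Clustering**: cosine similarity of per-source metapath feature vectors
  (all-zero vectors are defined to have similarity 0 to everything, 1 to
  themselves), then average-linkage agglomerative clustering on
  `1 − similarity`; the dendrogram leaf order is the presentation order.
  Count features are the default input — counts are larger and sparser than
  the normalized features and separate source families more cleanly.
* **Ranking correlations**: Kendall τ-b (tie-adjusted, as dense ranks always
  carry ties), computed by Knight's O(n log n) merge-sort algorithm. The
  test suite requires exact agreement with an O(n²) pair-counting oracle and
  with `stats::cor(method = "kendall")`.
* **Metapath diversity**: per (source, target) counts of metapaths with
  non-zero support, plus the Pearson correlation between targets' per-source
  count vectors; zero-variance vectors yield `NA` rather than a warning.
* **High-residual comparison**: for two rankings sharing items, the residual
  is `rank_A − rank_B`. The report lists the top-k most negative residuals
  (better in A), most positive (better in B), and — excluding those — the
  top-k shared items by mean rank, mirroring how such comparisons are read
  off a Venn diagram. "Significantly different" has no canonical threshold
  in this setting; top-k by |residual| (default k = 10) is our
  operationalization, and the three lists are disjoint by construction.

## Synthetic data: what it emulates and what it does not

The generator (`synth_config()`, `generate_graph()`) emulates the coarse
statistics of a predication corpus at desk scale: a node-type census, a
predicate vocabulary with per-metaedge edge budgets, heavy-tailed endpoint
propensities (Pareto draws with tail exponent α, default 2.5) so that a few
concepts become hubs the way heavily cited concepts do, optional multi-typed
nodes (a strict minority of a node's mentions relabeled to a secondary type,
so the primary type is stable by construction), an article-identifier pool,
and an optional record duplication rate that produces weight-2 edges.
Generation is a pure function of the configuration, seed included; roster
nodes never sampled into an edge are kept as isolated nodes so the census
holds.

`plant_association()` adds node-disjoint instances of a length-2 metapath
between a chosen source and target, choosing intermediates whose step edges
do not yet exist, so the planted cell's count rises by exactly the requested
number and the ground truth is recorded on the graph.

What the generator does *not* emulate: extraction noise and negation,
citation dynamics over time, realistic predicate co-occurrence structure, or
the sheer scale (3 × 10⁵ nodes, 2 × 10⁷ edges) of the real corpus. Passing
tests on synthetic graphs therefore demonstrate the correctness and the
qualitative behavior of the machinery — not that any particular biomedical
finding would replicate.

### Study conditions used by the benchmark

The planted-recovery benchmark (`simulate_planted_recovery()`) uses 100
source-type nodes, 80 intermediates, 20 targets and 2000 edges (1200
source→intermediate, 500 intermediate→target, 200 source→target) under the
heavy-tailed model, plants 5 paths from one random source, ranks all sources
by ULARA over the HeteSim rankers, and scores success when the planted
source beats the median unplanted source. The shape was chosen once as a
sparse, realistic desk-scale profile with spare intermediates available for
planting. Recovery runs at about 90% of seeded trials; the failures are
almost always trials whose randomly chosen planted source is a hub — HeteSim
normalizes by neighbor-set sizes, so five planted intermediates move a
hub's score much less than a peripheral node's. That behavior is the
intended character of the measure (it resists count bias), not an artifact.

The oracle-equivalence suite checks `enumerate_paths`, the count, DWPC and
HeteSim against brute-force implementations that work directly off the flat
edge table, on 200 random graphs of up to 30 nodes and 120 edges with 3–5
node types, at tolerance 1e-12.

## Numerical and design notes

* Dense ranks are integers; all feature arithmetic is double precision. The
  feature TSV serializes values with `%.17g`, so write→read round-trips are
  exact on non-zero support (zero cells are implicit; the axis labels ride
  along as comment headers).
* The graph store is an environment-backed in-memory structure with
  reference semantics (mutating loaders return the graph invisibly) and a
  lazily rebuilt flat index for neighbor/degree queries. The exported query
  surface — `node_neighbors()`, `metaedge_degree()`, `graph_nodes()`,
  `graph_edges()` — is the store contract; a service-backed store could
  implement the same surface.
* Degenerate inputs fail loudly with classed conditions: all-tied rankings
  (undefined τ), single-item aggregation, rank matrices with no informative
  columns, capacity-exceeding synthetic configurations, malformed CUIs or
  rule syntax (with position). The pipeline names its failing stage.
* `HeteSim` returns 0 when either end's neighbor set along the metapath is
  empty; a zero metaedge degree on a realized path incidence is impossible
  by construction and raises an internal-consistency error if ever observed.
* Ties everywhere are broken lexicographically by CUI, which together with
  seeded generation makes every output byte-reproducible.

## Known limitations

* Path enumeration is exact DFS; it is meant for desk-scale graphs
  (thousands of edges). No sampling or approximate counting is provided.
* Edge extraction weights do not enter the features; whether they should is
  an open modeling question documented above.
* ULARA here is the additive-update variant only; exponential updates and
  supervised aggregation are out of scope.
* The high-residual threshold is top-k, not a significance test.
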
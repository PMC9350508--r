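---
title: "The circuitgraph data model: redundant aggregates for connectome queries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The circuitgraph data model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitgraph)
```

## The problem

An electron-microscopy connectome is, at its core, a directed multigraph:
reconstructed bodies (segments) carry presynaptic T-bars and postsynaptic
densities, and each T-bar drives one or more densities on other bodies —
fly synapses are *polyadic*. Automatic segmentation plus partial
proofreading leaves this graph in a characteristic state: a few thousand
large, named, typed bodies that are real neurons, and orders of magnitude
more tiny anonymous fragments carrying a handful of stray synapses.
Scientists ask a small set of recurring questions of such data — who are a
neuron's strongest partners, which neurons project from region A to
region B, how complete is the reconstruction around my cell — and they
ask them often enough that the representation, not the query engine, is
what determines whether answers arrive in milliseconds or minutes.

`circuitgraph` implements the property-graph representation that makes
these queries cheap, as an ordinary in-memory R object with plain-text
on-disk exchange formats. The package is deliberately storage-engine
agnostic: everything lives in `data.table`s inside a `graph_store` value,
and the design invariant is *redundancy with proof* — every derived
aggregate can be recomputed from the primary state, and the test suite
holds the package to exact agreement with brute-force recomputation.

## The data model

A `graph_store` holds, as primary state:

* **segments** — one row per body: `body_id` (mandatory, unique),
  optional `instance`, `type`, `status` (free-form; "Traced" by
  convention marks proofread bodies), and `size` in voxels;
* **sites** — one row per synaptic element: kind (`pre`/`post`), integer
  voxel coordinates, and a prediction `confidence` in [0, 1];
* **links** — the pre→post pairings. Each post site has at most one
  presynaptic partner; a pre site may drive many post sites;
* **rois** — a forest of named brain regions, where leaf regions may
  carry half-open axis-aligned boxes for geometric membership.

And, derived from it, the redundant layer that queries actually touch:

* **connections** — one row per ordered body pair with ≥ 1 link. The
  `weight` of A→B is defined as the *number of links* from A's pre
  sites to B's post sites. Because each post site has at most one pre
  partner, this equals the number of B's postsynaptic densities driven
  by A, which makes a conservation law exact: summed over leaf ROIs,
  the connection's post-site tallies (plus post sites outside every
  leaf) equal the weight. The alternative convention — counting
  distinct T-bars — would break this law under polyadic fan-out, which
  is why the link count is the default here.
* **per-ROI tallies** (`roiInfo`) at both segment and connection level:
  pre/post site counts per region, *including ancestor regions*, so a
  query against a coarse region needs no hierarchy walk. On a
  connection, post sites are tallied by their own location and pre
  tallies count distinct participating pre sites.
* **synapse sets** — per directed connection, the grouping of each
  endpoint's participating sites. These are derived on demand
  (`synapse_sets()`); the outgoing set of A towards B and the incoming
  set of B from A jointly cover exactly the links between the pair.
* **meta totals** and a uniform **spatial grid** (cell edge 128 voxels)
  over site coordinates backing box queries.

Autapses (A→A) are stored like any other connection. ROI membership is
closed under the hierarchy: a site inside a leaf box belongs to the leaf
and all its ancestors. Overlapping leaf boxes are allowed; a site in the
overlap belongs to both. When an explicit membership table and box
geometry are both supplied, the table wins, with a warning.

## Neurons versus segments

Most of the store's bodies are fragments nobody wants in their query
results, so bodies are *designated* as neurons by a monotone promotion
predicate — a disjunction over size, pre-site count, post-site count,
and (optionally) the mere presence of a reconstruction status. The
default, `size ≥ 1e7` voxels or `pre ≥ 2` or `post ≥ 10` or any status,
splits the bimodal population cleanly; all thresholds are configurable
through `promotion_predicate()`. Every query defaults to neuron scope
with segment scope as an explicit opt-in, and the two scopes are held
equal by construction: the neuron-scope result of a region query must
equal the segment-scope result filtered to designated neurons.

## The query suite

`partners()` serves partner tables straight from the stored aggregates;
with a confidence threshold it instead recounts links whose pre *and*
post confidences pass, because the stored weight deliberately ignores
confidence. `find_paths()`/`find_shortest_paths()` enumerate simple
directed paths under a per-connection weight floor, counting length in
hops. Path search carries a deterministic *node-expansion budget*
(default `1e5` expansions) instead of a wall-clock timeout: a reproducible
run either completes or raises a budget error — never a silent partial
answer. For a source equal to the target, the only admissible path is a
direct autapse hop; longer cycles would revisit the source and are not
simple paths.

Three operations needed formulas the interactive tools they mirror do
not publish, so the choices are the package's own and are flagged as
such:

* `similar_by_roi_profile()` ranks neurons by cosine similarity of
  L2-normalized leaf-ROI profile vectors (pre tallies concatenated with
  post tallies). Cosine makes the ranking scale-invariant — a neuron
  twice the size with the same regional footprint scores 1.
* `cell_type_summary()` scores members of a type by cosine similarity
  of connectivity fingerprints indexed by *partner type* (outgoing and
  incoming halves concatenated); typing partners rather than
  identifying them makes fingerprints comparable across members that
  hit different individual cells of the same class.
* `roi_connectivity_matrix()` in weighted mode credits each neuron with
  its input share `post(from)/total_post` times its output tally
  `pre(to)`, normalizing by input only — one defensible reading of
  "neurons that go from one region to another"; count mode is simply
  the projection-neuron count.

Regular expressions (type and instance searches) use R's PCRE dialect
and match the whole string unless the pattern is explicitly anchored;
status comparisons are case-insensitive throughout.

## Quality metrics

Two different completeness questions get two different predicates, and
both are configurable. `partner_completeness()` asks what share of a
body's links lead to a *designated neuron* (any status) — fragmentation
of a neighbourhood. `roi_completeness()` asks what share of a region's
sites belong to *traced* bodies — proofreading progress. Because the
interactive tooling this mirrors is phrased over segments while the
underlying metric is phrased over synapses, `roi_completeness()` reports
both the site-weighted fraction (primary) and the per-segment fraction.
Empty denominators raise an undefined-value condition rather than
reporting 0. `coverage_curve()` ranks bodies by their site count in a
region (ties broken by ascending body id) and accumulates: the curve is
non-decreasing and its last entry is exactly 1 because the final
cumulative sum is the total divided by itself — no floating-point
tolerance is needed.

## Incremental updates

Proofreading emits merge, split, and annotation events. `apply_merge()`,
`apply_split()`, and `apply_edit_log()` (JSON-lines, strictly increasing
sequence numbers) apply them *incrementally*: only the aggregate rows
touching the affected bodies are recomputed. The module's defining
property, enforced by test, is that the incremental result is
field-for-field identical to a full rebuild from correspondingly edited
raw data. Three design points deserve mention:

* Split events carry an explicit `moved_site_ids` list and an optional
  `new_size` (voxels transferred to the new body, default 0). Raw site
  records carry no volume, so the size transfer must be stated by the
  producer of the event; with it, a split can exactly invert a merge.
* Neuron designation is re-evaluated under the store's recorded
  predicate once per applied *batch*, not per event — the store the
  caller sees is always a snapshot-consistent state.
* Already-applied sequence numbers are skipped with a warning
  (idempotence guard); a mid-log failure raises a classed error
  carrying the store as of the last successful event and its sequence
  number.

Stores are immutable R values: every operation returns the updated
store, so concurrent readers of an old value always see a consistent
snapshot (single-writer semantics). On-disk snapshots
(`write_store_archive()`) persist the exported bundle plus a
`meta.json` with the dataset name, version, totals, predicate, and last
applied sequence.

## What the synthetic generator emulates — and what it does not

`generate_world()` builds worlds with the statistical shape the model is
designed for: bimodal body sizes (neurons ≥ 2×10⁷ voxels, fragments
≤ 10⁵, straddling the default promotion threshold), polyadic fan-out
drawn from a truncated geometric distribution (default parameter 0.6,
cap 5, mean ≈ 1.7 densities per T-bar), post sites jittered within two
voxels of their T-bar, a grid of leaf ROIs under a single root, a
negative-binomial total synapse count (default mean 30 per neuron),
synapse confidences from a Beta(6, 2), and a type-preference matrix
steering which cell types connect.

The key statistical decision is how reconstruction incompleteness is
planted. Each site — pre and post independently — belongs to a traced,
designated neuron with probability `traced_fraction`, and otherwise to a
fragment. Site-level independence makes both completeness metrics
*exactly binomial* in the number of sites or links measured, so the
recovery tests can use closed-form standard errors. Fragments are
allocated by capacity slots (at most 1 pre and 9 post sites each),
keeping every fragment strictly under the default promotion predicate,
so the planted neuron set is exactly recoverable after ingestion. A
fully proofread world (`n_fragments = 0`) requires `traced_fraction = 1`;
anything else is rejected as infeasible rather than silently rescaled.

What the generator does **not** emulate: spatially clustered synapse
placement (real neuropil synapses follow arbors, not uniform volume),
body-level correlation of tracing status (real proofreading traces
whole neurons, so real completeness estimates have larger variance than
the binomial ideal), degree distributions with heavy tails, and
production-scale cardinalities — worlds are desk-scale, at most on the
order of 10⁴ sites. Passing recovery tests therefore demonstrates
correctness of the *metrics*, not calibrated uncertainty for real
reconstructions.

## Numerical and degenerate-input choices

* Coordinates are 0-based integer voxels; all boxes are half-open, so
  boxes tile space without double counting, and a degenerate box (equal
  corners) is empty rather than an error.
* Deterministic ordering everywhere: body id ascending for record
  lists, weight descending then partner id for partner tables, (hop
  count, lexicographic body sequence) for paths, rank ties by body id
  in coverage curves. No result depends on insertion order.
* Cosine similarity against an all-zero vector is reported as 0 between
  distinct bodies; a *query* body with no synapses is an
  undefined-profile error, not a zero.
* Body ids are stored as doubles (production reconstruction ids exceed
  32-bit integers); all internal keys format them deterministically.
* Aggregate tallies with both counts zero are absent, not stored as
  zero rows; empty bundles build valid empty stores.

## Problem sizes used by the test suite

The shipped tests exercise: 100 random worlds (≈ 300–2,000 sites each)
for the aggregate-versus-brute-force and redundant-route equivalences;
1,000 path-search cases on digraphs of ≤ 12 bodies checked against
independent `igraph` enumeration; 50 random edit logs checked against
full rebuilds; 100 export/ingest and 100 SWC round trips; and 150
completeness-recovery worlds (50 seeds at each planted fraction 0.5,
0.8, 0.95) asserting standard-normal behaviour of the binomial
z-scores. These sizes keep the default suite comfortably fast on one
CPU while covering the store's state space well.

## Known limitations

* Single dataset per store; multiple datasets are separate archives
  selected by path, not label prefixes inside one store.
* No query language: the API surface *is* the query set. Arbitrary
  graph-pattern queries are out of scope by design.
* Skeletons (SWC) are carried and round-tripped but not analysed; no
  geometric QC (synapse-to-skeleton distance) is performed.
* The extensibility hook (`extra_nodes`) accepts additional node kinds
  keyed by a label string without involving them in any aggregate —
  sub-cellular structures such as mitochondria can ride along, but no
  semantics are implemented for them.
* `update_log` assumes a single writer; there is no conflict
  resolution, streaming transport, or transaction log.
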
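# circuitgraph

Property-graph storage and analysis for synapse-level EM connectomes, in R.

Modern electron-microscopy reconstructions describe neural circuits as
tens of thousands of reconstructed bodies connected by millions of
chemical synapses. Automatic segmentation plus partial proofreading
leaves that graph in a characteristic state: a handful of large, named,
typed **neurons** and a vastly larger population of tiny anonymous
**fragments**. The recurring scientific questions — who are a neuron's
strongest partners, which neurons project from brain region A to region
B, how complete is the reconstruction around a cell of interest — are
graph queries whose cost is dominated by representation, not by the
query engine.

`circuitgraph` is for connectomics researchers and tool builders who
need those queries as ordinary R calls over plain-text data. It
implements:

* an in-memory **property-graph store** (`graph_store`) holding bodies,
  pre/post synaptic sites, the polyadic pre→post links between them, a
  hierarchical ROI forest, and the *redundant aggregates* that make
  queries fast — per-pair connection weights and per-ROI synapse
  tallies (`roiInfo`) at both segment and connection level;
* **ingestion and lossless export** of CSV bundles, JSON ROI
  hierarchies, and SWC neuron skeletons;
* the canonical **query suite**: partner tables, bounded simple-path and
  shortest-path search with a deterministic expansion budget, common
  partners, reciprocity, region projections, ROI-profile and cell-type
  similarity, region-to-region connectivity matrices, regex type
  search, and spatial box queries;
* **reconstruction-quality metrics**: partner completeness, region
  completeness, and segment coverage curves;
* **incremental maintenance** from merge/split/annotation edit logs
  (JSON lines), provably equal to a full rebuild from edited raw data;
* a deterministic **synthetic-connectome generator** with planted
  ground truth, and a **command-line interface** over on-disk store
  archives.

## The model in brief

For bodies $A$ and $B$, the stored connection weight is

$$w(A \to B) = \#\{(s_{\text{pre}}, s_{\text{post}}) \in \text{links} :
\text{owner}(s_{\text{pre}}) = A,\ \text{owner}(s_{\text{post}}) = B\},$$

the number of $B$'s postsynaptic densities driven by $A$ (each post
site has at most one presynaptic partner). Per-ROI tallies are stored
redundantly on segments and connections, ancestor regions included, so
that over leaf ROIs the connection's post tallies conserve the weight
exactly. Bodies are designated neurons by a monotone promotion
predicate (default: size ≥ 10⁷ voxels, or ≥ 2 pre sites, or ≥ 10 post
sites, or any reconstruction status), and every query defaults to
neuron scope. Completeness of a body's neighbourhood is the fraction of
its links whose partner is a designated neuron; completeness of a
region is the fraction of its sites owned by traced bodies. The methods
vignette (`vignettes/connectome-store.Rmd`) derives and justifies each
of these choices.

## Worked example

The package ships a hand-checkable micro-connectome: three bodies
(Kenyon cell 100, projection neuron 200, fragment 300), nine synaptic
sites in two leaf ROIs (`alpha`, `beta`) under the root `brain`, and
five pre→post links.

```r
library(circuitgraph)
store <- toy_store()
store
#> <graph_store 'toy' v1.0>
#>   3 segments (2 designated neurons)
#>   9 synaptic sites (4 pre, 5 post), 5 links
#>   3 connections, 3 ROIs

partners(store, 100, "outgoing", scope = "segments")
#>    partner_body weight partner_type partner_instance partner_status direction
#> 1:          200      3          PN1            PN1-1         Traced  outgoing
#> 2:          300      1         <NA>             <NA>           <NA>  outgoing
```

Body 100 drives 200 through three links and the fragment 300 through
one, so three quarters of its outputs land on a designated neuron:

```r
pc <- partner_completeness(store, 100, "outgoing")
pc$fraction_complete
#> [1] 0.75
pc$status_breakdown
#> (none) Traced
#>      1      3

coverage_curve(store, "beta", "post")
#>    rank body_id n_sites cumulative_fraction
#> 1:     1     200       2                0.50
#> 2:     2     100       1                0.75
#> 3:     3     300       1                1.00
```

The coverage curve says: the top body (200) accounts for half of
`beta`'s postsynaptic sites, and three bodies are needed to account for
all of them.

The same operations are available from the shell via the installed
`exec/circuitgraph` script:

```sh
circuitgraph ingest --bundle toy_dir --store toy_store
circuitgraph query partners --store toy_store --body 100 --direction out --scope segments
circuitgraph qc roi-completeness --store toy_store --roi beta
```

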
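Package: circuitgraph
Title: Property-Graph Storage and Analysis of Electron-Microscopy Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An in-memory property-graph data model for synapse-level
    connectome reconstructions: segments and designated neurons, polyadic
    synaptic sites and their pre-to-post links, hierarchical brain regions
    (ROIs), and the redundant connection-level aggregates (weights and
    per-ROI synapse tallies) that make circuit queries fast. Includes
    CSV/JSON/SWC ingestion and lossless export, the canonical connectivity
    query suite (partner tables, bounded path search, region projection and
    connectivity matrices, similarity rankings), reconstruction-quality
    metrics (partner and region completeness, segment coverage curves),
    incremental maintenance of all aggregates from merge/split edit logs,
    a deterministic synthetic-connectome generator for testing, and a
    command-line interface over on-disk store archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
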
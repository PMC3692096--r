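Package: circlemapr
Title: CircleMap Visualization of Multi-Omics Matrices on Pathway Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Renders coordinated CircleMap glyphs - nested rings of
    per-sample spokes, one ring per omics platform - around the genes of a
    typed pathway graph, and serializes the scene to deterministic SVG.
    Reads tab-separated gene-by-sample score matrices, sample annotations,
    gene sets, SIF networks and a typed-node pathway dialect; supports
    background-network filtering by gene set, multi-track interaction
    overlay with per-source edge colors, multi-key spoke sorting with
    propagation across all glyphs, and aggregation of samples into
    group-mean segments. Includes seeded synthetic-data generators
    emulating anti-correlated methylation/expression pairs and a
    hypermutated tumor cohort, a command-line front end, and a minimal
    HTTP GET rendering service.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
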
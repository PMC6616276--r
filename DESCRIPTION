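Package: lbdgraph
Title: Literature-Based Discovery on Biomedical Concept Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds typed, directed, weighted biomedical concept graphs from
    semantic predication tables (SemMedDB-style subject-predicate-object
    triples with UMLS concept identifiers), computes metapath-based features
    (path count, degree-weighted path count, HeteSim) between source and
    target concepts, aggregates feature-wise rankings with an unsupervised
    rank-aggregation algorithm (ULARA), and provides comparative analytics:
    source-similarity clustering, Kendall tau-b ranking correlations, and
    high-residual comparison of aggregate rankings. Includes a synthetic
    heterogeneous-graph generator with planted source-target associations for
    benchmarking, plus TSV and GraphML interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
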
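Package: heterosisTx
Title: Expression-Pattern Classification and Mid-Parent Heterosis Analysis for
    Hybrid-Parent Trio Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting heterosis (hybrid vigor) in crop
    transcriptomes from hybrid-parent trios. Calls differentially expressed
    genes between female parent, male parent and F1 hybrid, classifies each
    trio DEG into one of twelve expression patterns grouped as additive,
    dominant or over-dominant, computes mid-parent heterosis values and
    strong/middle/weak hybrid groups, intersects group-common DEGs,
    performs hypergeometric term enrichment, and detects weighted
    coexpression modules (soft-threshold adjacency, topological overlap,
    eigengenes) correlated with a trait such as plant gross weight. Includes
    a seeded negative-binomial trio simulator with planted pattern, trait
    and module truth so every stage is testable without external data, and
    bundles the printed summary tables of a 4x4 diallel Chinese cabbage
    heterosis trial as worked-example input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    mclust,
    withr
Config/testthat/edition: 3
biocViews: Transcriptomics, DifferentialExpression, GeneExpression,
    Network, Pathways
RoxygenNote: 7.3.3
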
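Package: cytoDriver
Title: Network-Based Cytokine Driver Inference for Post-Traumatic Osteoarthritis Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers upstream cytokine drivers of age-specific transcriptomic
    responses to joint trauma by combining selection of age-specific
    stress-response gene sets from time-course differential-expression tables,
    random-walk-with-restart propagation on weighted tissue-specific gene
    networks seeded at a receptor, ridge-regression cytokine activity inference
    with permutation significance, single-sample gene set enrichment with
    leading-edge extraction, DerSimonian-Laird random-effects meta-analysis of
    standardized mean differences, topological-overlap co-expression module
    detection, connectivity-map tau scoring for signature-reversing compounds,
    and 2x2 enrichment statistics. Ships a synthetic-data generator with
    planted ground truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    jsonlite,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
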
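Package: tfwire
Title: Transcription Factor Differential Wiring Networks from Two-Condition Expression Data
Version: 0.1.0
Authors@R: person("Open", "Contributor", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs condition-specific gene co-expression networks from a
    two-condition expression matrix and ranks transcription factors by their
    regulatory impact. The pipeline normalizes counts to transcripts-per-million,
    filters lowly expressed genes by a half-of-means rule, log-transforms,
    scores differential expression with a gene-wise standardized contrast,
    computes Regulatory Impact Factors (RIF1/RIF2) for every transcription
    factor against the differentially expressed gene set, and prunes pairwise
    correlations with the Partial Correlation and Information Theory (PCIT)
    trio algorithm. Includes a seeded synthetic-data generator with planted
    differential wiring for validation, tabular/SIF/GraphML exports, and a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
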
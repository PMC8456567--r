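Package: omicwalk
Title: Multi-Omics Integration and Network Propagation for Cancer Gene Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of paired tumor/normal multi-omics cohorts:
    paired differential testing of expression, gene-level copy number and
    promoter methylation with Benjamini-Hochberg false discovery control,
    mutation-frequency screening, combination of the layers into
    direction-consistent dysregulation groups and 0-3 source scores, random
    walk with restart over a merged interaction network with node-label
    permutation significance, and downstream survival and association
    statistics (Kaplan-Meier, log-rank, univariate Cox, chi-squared tables).
    Ships a seeded synthetic-cohort generator so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    survival,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
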
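Package: driverscan
Title: Network Propagation and Meta-Analytic Validation of Shared Disease Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Nominates candidate "key driver" genes shared by two diseases and
    validates them by field-synopsis meta-analysis. The network stage expands
    two seed-gene sets over a confidence-filtered protein-protein interaction
    network by random walk with restart, cuts each ranked expansion at the peak
    of a GSEA-style running sum, intersects the expansions, and scores every
    network gene for hypergeometric enrichment of the common genes among its
    interaction neighbors (Benjamini-Hochberg corrected). The meta-analysis
    stage pools case-control genotype 2x2 tables into odds ratios with
    DerSimonian-Laird random effects or Mantel-Haenszel fixed effects,
    Cochran's Q and I-squared heterogeneity with confidence intervals,
    leave-one-out sensitivity, Harbord's small-study-effects test, power and
    false-positive report probability, and Venice-criteria credibility grading.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
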
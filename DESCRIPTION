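Package: scprofib
Title: Single-Cell Pathway Activity Scoring and Profibrotic Phenotype Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores per-cell activity of a gene pathway with the
    Mann-Whitney-Wilcoxon gene-set test (MWW-GST) after within-cluster
    standardization, calls pathway-active (profibrotic) cell populations,
    extracts cell-type-specific differential expression signatures, builds
    co-active pathway networks from Fisher exact association tests, validates
    signature activity across experimental conditions, projects signatures
    into bulk expression samples as non-negative least-squares phenotype
    scores, and stratifies survival by score quartiles. Includes
    negative-binomial single-cell, bulk-mixture and survival simulators with
    planted structure so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    pracma,
    survival,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
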
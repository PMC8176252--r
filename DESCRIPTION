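Package: escchet
Title: Multi-Omics Heterogeneity Analysis for Esophageal Squamous Cell
    Carcinoma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies inter-sample tumor heterogeneity across mutation,
    expression and proteome data in esophageal squamous cell carcinoma
    (ESCC)-style cohorts. Builds Boolean mutation profiles from MAF-lite
    somatic variant tables and compares samples by matching dissimilarity;
    compares transcriptomes (TPM) by correlation distance; catalogues
    per-gene variant spectra (e.g. TP53 hotspots); partitions multi-dataset
    gene overlaps and resolves trans-species protein ambiguity in
    patient-derived xenograft proteomes; and performs gene-set
    over-representation with the EASE score (jackknifed one-sided Fisher
    exact test). A synthetic-cohort generator emulates sparse patient-like
    and dense cell-line-like cohorts so every stage is testable at desk
    scale without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    pheatmap,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
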
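Package: oncoclade
Title: Tumor Cladistics from Array-CGH Copy-Number Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of colorectal-tumor cohorts profiled by
    array comparative genomic hybridization (aCGH), microsatellite-instability
    (MSI) marker panels and methylation-specific PCR. Calls gene-level
    copy-number gains and losses from interval reports with fold-change
    thresholds, classifies MSI status from the five-marker mononucleotide
    panel, tabulates candidate-gene methylation frequencies with stratified
    association tests, builds a binary shared-aberration ("polarity") matrix
    across specimens, and infers maximum-parsimony cladograms of tumors with
    exact (exhaustive, branch-and-bound) and heuristic searches, rooting at
    the aberration-free normal genome and reporting per-node synapomorphies.
    Includes a seeded synthetic-cohort generator so every pipeline stage is
    testable without external data, and SPSS-convention (type-6 quantile)
    cohort summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
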
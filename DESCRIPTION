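Package: bcancestry
Title: Ancestry-Stratified Clinical and Genomic Analysis of Breast Cancer Cohorts
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end, testable implementation of an ancestry-stratified
    breast-cancer cohort analysis: genetic-ancestry assignment from
    superpopulation proportions by threshold, a clinical regression battery
    (linear, logistic and negative-binomial models with a European-ancestry
    reference), ancestry-matched tumour-mutational-burden estimation with a
    population-frequency retain/discard filter, dual-route differential
    somatic mutation calling (per-feature logistic regression with
    false-discovery-rate control, plus a strict 2 percent presence threshold
    with intersection sets), germline pathogenicity filtering over a clinical
    gene panel with enrichment modelling, percentile-based screening-window
    derivation, and Monte-Carlo power analysis for the per-feature logistic
    design. A seeded synthetic-cohort generator with a truth ledger stands in
    for the controlled-access study data, so every stage is exercised by
    parameter-recovery tests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
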
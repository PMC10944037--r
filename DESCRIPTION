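Package: proteomr
Title: Proteome-Wide Survival Screening, Mendelian Randomization, and
    Colocalization for Heart Failure Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for proteome-wide outcome analysis
    in established heart failure: Cox proportional-hazards screening of
    standardized plasma protein levels against death and the composite of
    death or heart-failure hospitalization, principal-component based
    multiple-testing correction, index-event (collider) bias correction of
    case-only outcome GWAS via a cluster-then-slope mixture model,
    two-sample Mendelian randomization with correlated cis-pQTL instruments
    (Wald ratio, generalized inverse-variance weighting, MR-Egger, weighted
    median), and Bayesian colocalization with approximate Bayes factors and
    conditional posteriors. Includes a synthetic-data generator producing
    LD-structured genotypes, cis-regulated proteins, survival cohorts, and
    liability-selected case-only GWAS with controllable collider bias, so
    the full pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
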
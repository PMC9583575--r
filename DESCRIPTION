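Package: ssdriver
Title: Sample-Specific Driver Modules from Network Perturbation and
    Multi-Omics Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constructs per-sample differential co-expression networks
    (sample-specific networks, SSNs) by testing the change in Pearson
    correlation when a single case sample is added to a reference cohort,
    builds per-sample somatic-mutation and methylation-aberration
    profiles (Hampel filter on consolidated promoter beta values), and
    extracts sample-specific driver modules around mutated or aberrantly
    methylated seed genes under 2-order neighborhood and hub-gene
    constraints. Includes cohort- and subtype-level driver-module
    aggregation with a Monte Carlo edge-frequency null, module
    analytics (centralities, Jaccard similarity, rank tests), and a
    fully deterministic synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
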
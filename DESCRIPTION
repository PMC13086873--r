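Package: genotoxvar
Title: Variability and Uncertainty Analysis of Genotoxicity Test-Guideline Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the variability of categorical genotoxicity
    results from OECD test-guideline (TG) conform studies. Reads study-level
    assay records in the EFSA genotoxicity-database dialect, harmonizes
    per-compound overall calls across database conventions, computes pairwise
    inter-database concordance, estimates per-compound pseudo-replicate
    similarity (the probability of an identical result upon replication) with
    binning and majority calls, screens protocol variables that discriminate
    conflicting results with a per-compound random forest, and tests whether
    protocol options shift study sensitivity using paired Wilcoxon signed-rank
    comparisons of per-compound positive fractions. A synthetic-data generator
    with known ground truth (latent compound genotoxicity, option-level
    sensitivity effects, ambiguity and acceptability noise) makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
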
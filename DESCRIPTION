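Package: atgscan
Title: Genome-Wide Analysis of Translation Initiation Fidelity Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how eukaryotic transcripts encode translation
    initiation fidelity. Builds frame-resolved profiles of ATG (and arbitrary
    codon) occurrences around the START codon, scores start-codon contexts with
    a position-specific scoring matrix trained on highly translated genes,
    generates codon-resampled and codon-permuted null genomes, estimates the
    length of the region depleted of alternative ATGs with sliding-window
    Kolmogorov-Smirnov tests and empirical null-genome flags, quantifies the
    metabolic cost of alternative initiation events, runs a folding-energy
    control with pluggable minimum-free-energy engines, and evaluates a staged
    ladder of expression predictors built from initiation rules. A seeded
    synthetic-genome generator reproduces the statistical structure the
    analysis assumes so every stage is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
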
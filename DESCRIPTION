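Package: mirboost
Title: Pre-miRNA Hairpin Classification with Boosted Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies real pre-miRNA hairpins among candidate RNA stem-loops
    and assigns them to species. Extracts a fixed 98-dimensional feature vector
    from each sequence (64 overlapping trinucleotide frequencies, 32 triplet
    structure-sequence codes from the folded secondary structure, the minimum
    free energy, and the G-U wobble pair count) and trains an AdaBoost ensemble
    of small 98-12-1 feedforward neural networks as the classifier. Secondary
    structures come from the ViennaRNA 'RNAfold' program when it is installed,
    with a built-in deterministic base-pair-maximization fallback otherwise.
    Includes stratified V-fold cross-validation with confusion-matrix metrics,
    a one-vs-rest multi-class extension for species assignment, a seeded
    synthetic hairpin generator for fully reproducible experiments, and a
    command-line interface covering simulation, feature extraction, training,
    prediction and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
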
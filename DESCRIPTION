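Package: pinepop
Title: Multilocus Population Genetics and Coalescent Demographic Inference
    for Low-Diversity Conifers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multilocus nuclear-sequence and chloroplast
    microsatellite population analyses of small, range-restricted tree
    populations: sequence diversity (Watterson's theta, nucleotide
    diversity at total, silent and nonsynonymous sites), site-frequency
    neutrality tests (Tajima's D, Fu and Li's D* and F*, Fu's Fs,
    standardized Fay and Wu's H, McDonald-Kreitman) with coalescent
    significance, linkage disequilibrium and its decay with distance,
    AMOVA-based F(ST), G(ST) versus R(ST) comparison and Mantel tests with
    permutation significance, mismatch-distribution sudden-expansion tests
    for chloroplast haplotypes, and approximate Bayesian computation over
    standard-neutral, exponential-growth and bottleneck demographic models
    driven by a built-in coalescent simulator with recombination.  A
    synthetic-data generator produces complete study-shaped datasets with
    known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    geosphere,
    nnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
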
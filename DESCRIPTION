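Package: mtexpand
Title: Haplotype Diversity, Neutrality Tests and Demographic Expansion from
    mtDNA Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-style toolkit for intraspecific mitochondrial DNA
    phylogeography. Reads aligned control-region or cytochrome-b sequences
    (or published haplotype-by-variable-site tables with per-locality
    counts), collapses them into haplotypes, and computes the classical
    summary statistics of molecular diversity (segregating sites, haplotype
    and nucleotide diversity, mean pairwise differences), Tajima's D and
    Fu's Fs neutrality tests with coalescent-simulation p-values, mismatch
    distributions with sudden-expansion model fits (tau, theta0, theta1),
    Harpending's raggedness, and expansion-time dating via tau = 2*mu*t.
    Also builds median-joining haplotype networks with median (Steiner)
    vectors, computes Tamura-Nei (TN93) model distances with gamma rate
    heterogeneity and bootstrap standard errors, and ships a coalescent
    simulator under constant-size and sudden-expansion demographies for
    calibration and power checks. Includes the golden jackal control-region
    and cytochrome-b haplotype tables as worked fixtures and a pipeline
    that reproduces the full analysis from one configuration object.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
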
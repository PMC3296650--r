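Package: invscan
Title: Detection and Genotyping of Polymorphic Inversions from SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects polymorphic chromosomal inversions from population SNP
    data (phased haplotypes or unphased genotypes) using linkage-disequilibrium
    differences across candidate breakpoints. A four-block mixture likelihood
    separating forward and inverted subpopulations is fitted by
    expectation-maximization and compared against a no-inversion null model
    with the Bayesian Information Criterion. A sliding-window scan locates
    candidate inverted segments, overlapping significant windows are merged
    into regions of interest, and each chromosome or subject is assigned an
    inversion status by a majority vote over qualifying windows. Genotype
    input is phased locally around each candidate breakpoint with a
    haplotype-frequency EM, so no genome-wide phasing is required. A
    simplified population simulator with suppressed recombination between
    orientations provides synthetic data for benchmarking.
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
    rlang,
    ggplot2,
    generics,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
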
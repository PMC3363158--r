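Package: pedgwas
Title: Pedigree-Aware QTL Mapping by Mixed Models, Haplotype Clustering
    and Bayesian Variable Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates QTL-MAS-style pedigreed populations (half-sib sire
    families, phased SNP haplotypes on a cM map, eight quantitative trait
    loci including a multi-allelic, an imprinted and an epistatic pair)
    and maps QTL with four complementary association methods: a
    single-SNP linear mixed model with a pedigree polygenic effect, a
    sliding-window random-haplotype model tested by boundary likelihood
    ratio, a genealogy-based haplotype-clustering mixed model built on
    four-gamete perfect phylogenies, and spike-and-slab Bayesian variable
    selection fitted by Gibbs sampling.  An evaluation layer scores calls
    against the simulated truth for power, false positives and mapping
    precision.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
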
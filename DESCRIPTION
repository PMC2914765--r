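Package: ibdphase
Title: Pairwise Identity-by-Descent Detection and IBD-Driven Haplotype Phasing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects chromosome segments shared identical-by-descent (IBD)
    between pairs of samples from biallelic SNP data using hidden Markov
    models: a two-state model with unordered-genotype emissions and a
    five-state model with phased-genotype emissions whose transitions allow
    the shared segment to switch between homologous autosomes at
    heterozygous loci, making detection robust to phase errors. Detected
    IBD segments are in turn used to update the haplotype phase through a
    maximum-satisfiability local search over relative phase coefficients,
    and detection and phasing can be alternated until convergence. Includes
    a two-stage Wright-Fisher family simulator with founder-ancestry
    tracking for ground-truth IBD, and evaluation metrics (switch error
    rate, false-negative/false-positive IBD rates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
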
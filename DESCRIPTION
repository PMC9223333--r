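Package: ascendr
Title: Dating Founder Events from the Decay of Allele-Sharing Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers the age (in generations) and intensity of a founder event
    in a population from the decay of identity-by-state allele-sharing
    correlation across the genome, without requiring phased genotypes. Reads
    EIGENSTRAT genotype triplets, computes within- and cross-population
    allele-sharing correlation profiles over genetic-distance bins with either
    an exact SNP-pair engine or an FFT mesh-autocorrelation engine, supports a
    heterozygosity-weighted covariance mode for pseudo-haploid and sparse data,
    fits an exponential decay by bounded non-linear least squares, quantifies
    uncertainty with a weighted per-chromosome block jackknife, and classifies
    the significance of the inferred event. A companion module simulates
    genotype data under two-population bottleneck and admixture demographies
    for validation.
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
    data.table,
    jsonlite,
    minpack.lm,
    generics,
    ggplot2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
SystemRequirements: Python (>= 3.8) with msprime and numpy for the simulation
    module (shelled out via the bundled inst/python/founder_sim.py).
Config/testthat/edition: 3
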
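Package: regionbvs
Title: Region-Based Bayesian Variable Selection for Case-Control GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Sparse Bayesian variable-selection regression for genome-wide
    association studies of binary traits. Each chromosome is partitioned into
    overlapping fixed-size SNP windows; within every window a spike-and-slab
    probit regression is fitted by Markov chain Monte Carlo, yielding per-SNP
    posterior inclusion probabilities (PIPs). Region-level significance is
    assessed by a phenotype-permutation test with early stopping and
    Bonferroni correction, candidate regions are validated in an independent
    cohort via mean-PIP permutation tests, and cross-dataset agreement is
    summarised by a linkage-disequilibrium consensus analysis. A synthetic
    genotype/phenotype generator with LD-block structure and a liability
    threshold model makes the whole pipeline testable without access-controlled
    data. Readers for BIMBAM mean-genotype and PLINK text formats are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
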
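Package: lemma
Title: Linear Environment Mixed Model Analysis of Gene-Environment Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Bayesian whole-genome regression that jointly models additive SNP
    effects and genome-wide gene-by-environment (GxE) interactions through a
    single learned environmental score (ES), fitted by mean-field variational
    inference with variational-EM hyper-parameter updates and SQUAREM
    acceleration. Includes leave-one-chromosome-out single-SNP GxE tests with
    heteroskedasticity-robust (sandwich) standard errors, F-test and robust
    F-test comparators, squared-environment screening, randomized
    Haseman-Elston estimation of additive and GxE variance components (single
    component and MAF/LD-stratified) with block-jackknife standard errors, and
    a simulation module that generates genotypes, environments and phenotypes
    with known GxE architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    car,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
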
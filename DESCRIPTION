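Package: bayesrqtl
Title: Multi-Breed Genomic Prediction with BayesR and Local-GEBV QTL Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome regression for multi-breed dairy reference
    populations combining bull and cow records with heterogeneous error
    variance. Implements an extended BayesR Gibbs sampler (four-component
    normal-mixture prior on SNP effects, fixed effects, pedigree polygenic
    term, per-record residual weights), a weighted GBLUP counterpart solved
    through the mixed-model equations with SNP effects back-solved from
    genomic breeding values, EM-REML variance-component estimation,
    record-weight construction for daughter trait deviations and repeated
    cow records, and local-GEBV sliding-window QTL mapping with nine-class
    pleiotropy labelling. Includes a synthetic multi-breed data generator
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
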
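Package: phenogp
Title: Phenomic and Genomic Prediction for Multi-Environment Plant Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparing phenomic prediction (near-infrared
    spectroscopy based) with genomic prediction in multi-environment plant
    breeding trials. Covers simulation of genotypes, split-block trial
    designs, traits and plot-level reflectance spectra; outlier flagging,
    REML variance decomposition, broad-sense heritability and
    per-environment genotype BLUEs; chemometric spectral preprocessing and
    per-wavelength genotype BLUPs; VanRaden genomic and hyperspectral
    relationship matrices; single- and multi-environment kernel prediction
    models with genotype-by-environment deviations fitted by Gibbs
    sampling; and a sparse-testing cross-validation engine with
    predictive-ability comparison on Fisher's z scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    lme4,
    Matrix,
    signal,
    emmeans,
    jsonlite,
    yaml,
    vcfR,
    Rcpp,
    stats,
    utils,
    methods,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
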
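Package: mtgp
Title: Multi-Trait Multi-Environment Genomic Prediction for Wheat Yield Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Genomic prediction of genetically correlated yield-component
    traits (grain yield, harvest index, spike fertility, thousand grain
    weight) evaluated across multiple environments. Provides genotype
    quality control for inbred GBS panels (missingness, minor allele
    frequency, heterozygosity and Fisher allelic-independence filters),
    genomic relationship matrices, mixed-model adjusted means (BLUEs) and
    broad-sense heritability, Bayesian whole-genome prediction models
    (multi-environment GBLUP, a matrix-variate multi-trait
    multi-environment Gibbs sampler, and multi-output regressor stacking),
    feed-forward neural network models with a response-surface
    hyperparameter search, population-structure-stratified cross-validation,
    prediction accuracy, and response to selection. A synthetic-data
    generator with known genetic architecture supports parameter-recovery
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    MASS,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
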
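Package: psindex
Title: Penalized and Reduced-Rank Selection Indices for High-Dimensional Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to predict the genetic merit of a target trait (e.g. grain
    yield) from high-dimensional secondary phenotypes such as hyper-spectral
    reflectance. Implements standard, L2- (ridge), L1-/elastic-net- (via
    covariance-form coordinate descent and LARS) and principal-component
    (reduced-rank) selection indices; mixed-model pre-adjustment of field-trial
    records; REML estimation of variance components, heritability and genetic
    covariances through univariate models and the sum-of-traits identity;
    trial-blocked training/testing evaluation of indirect-selection accuracy
    and relative efficiency; vegetation-index and penalized phenotypic
    prediction baselines; and a synthetic-data generator with known genetic
    architecture providing closed-form accuracy oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    graphics,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
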
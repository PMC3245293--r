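Package: bmix
Title: Bayesian Joint Ancestry and Association Testing in Admixed Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint Bayesian testing of local-ancestry (admixture) and
    genotype (association) effects at single markers in admixed cohorts.
    Implements chi-square Bayes-factor calibration with noncentral
    alternative densities, autocorrelation-based effective-test (testing
    burden) estimation via autoregressive spectral density at frequency
    zero, generalized-linear-model admixture scans, local-ancestry
    stratified association scans pooled by inverse-variance fixed effects,
    posterior chaining of the two stages, power and sample-size trade-off
    analysis, and a Balding-Nichols simulator of admixed case-control and
    quantitative-trait cohorts used for validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
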
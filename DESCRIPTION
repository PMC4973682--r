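Package: promperf
Title: Provider Performance Profiling from Patient-Reported Outcomes
    with Missing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Missing-data-aware assessment of hospital provider performance
    from patient-reported outcome measures (PROMs). Implements multilevel
    multiple imputation of ordinal Oxford Hip Score items via a latent-normal
    (ordered probit) model with provider random effects fitted by MCMC,
    case-mix adjustment with indirect standardisation, funnel-plot
    classification of providers into alert/alarm states with a best-practice
    tariff eligibility rule, and a delta-reweighting sensitivity analysis for
    data that are missing not at random. Includes a synthetic cohort
    generator that emulates the structure of the English PROM hip-replacement
    survey (patients nested in providers, threshold-model item responses,
    logistic selection-model missingness) so the whole pipeline can be
    exercised and validated without confidential patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
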
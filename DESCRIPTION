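Package: ribart
Title: Random-Intercept BART Accelerated Failure Time Models for Clustered
    Survival Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a random-intercept accelerated failure time model whose
    regression function is a Bayesian sum of trees (BART), for causal
    inference about multiple treatments on clustered, right-censored
    survival outcomes. Implements a Metropolis-within-Gibbs sampler with
    truncated-normal censoring augmentation and parameter-expanded
    variance-component updates; posterior treatment-effect estimation on
    the log-time, survival-probability and restricted-mean-survival-time
    scales; a confounding-function sensitivity analysis for unmeasured
    confounding using nested multiple imputation; and a clustered-survival
    simulation engine with Weibull outcomes and calibrated random-intercept
    multinomial treatment assignment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    survival,
    nnet,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
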
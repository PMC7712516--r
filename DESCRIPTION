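Package: sf6dbayes
Title: Bayesian Beta and Linear Regression Models for SF-6D Health State Valuations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Bayesian beta and linear regression models, with optional
    respondent random effects and sociodemographic covariates, to SF-6D
    standard-gamble health-state utility data. Provides the SF-6D descriptive
    system (18,000 states, dummy-variable design matrices, adjacency),
    standard-gamble preprocessing (pits-anchored adjustment, bounding,
    constant-respondent exclusion), a Metropolis-within-Gibbs MCMC sampler
    with Gelman-Rubin diagnostics, model comparison by mean prediction error,
    root-mean-square error and the deviance information criterion, a
    monotonicity audit over adjacent state pairs, leave-one-out predictive
    validation, and a synthetic valuation-study generator for parameter
    recovery experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
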
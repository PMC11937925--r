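Package: rwvalence
Title: Valenced Rescorla-Wagner Modelling of Social Reinforcement Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, penalized maximum-likelihood fitting and group-level
    analysis of a valenced Rescorla-Wagner reinforcement-learning model for a
    probabilistic two-option categorization task with social (point-light face)
    and non-social feedback. Separate learning rates, reward sensitivities and
    softmax inverse temperatures are estimated for rewarded (win) and
    non-rewarded (loss) events, per participant and condition. The package
    generates synthetic cohorts calibrated to the autism-spectrum-quotient (AQ)
    distribution of a neurotypical sample, fits the learner by bounded
    multi-start optimization with elastic-net shrinkage on logistic-transformed
    parameters, reproduces the behavioural mixed-logistic learning analysis and
    the parameter-level beta-likelihood mixed regressions on AQ, and validates
    the whole chain with parameter-recovery and posterior-predictive checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    lmerTest,
    glmmTMB,
    mgcv,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
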
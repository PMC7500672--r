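Package: gazerl
Title: Reinforcement Learning Models of Gaze-Cued Instrumental Avoidance
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation, likelihood-based fitting and comparison of
    reinforcement-learning models for a two-option instrumental avoidance
    task in which a social partner cues one option by gaze before each
    choice. Agents learn the safety probability of each option and the
    reliability of each partner with Rescorla-Wagner updates using
    asymmetric learning rates, combine both value sources in a softmax
    choice rule, and may carry cached partner reliability into new blocks
    of novel options ("weak" transfer) or additionally seed novel option
    values from it ("strong" transfer). The package implements the
    fourteen-model space (fixed, free, emotion-split and
    prediction-error-arbitrated weighting, with an optional fearful-face
    bonus), a synthetic-cohort generator, penalized maximum-likelihood and
    hierarchical MCMC fitting, participant-level cross-validated model
    comparison, model and parameter recovery harnesses, and ecological
    simulations contrasting weak and strong transfer when a partner's
    cueing strategy reverses or degrades.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
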
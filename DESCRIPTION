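Package: socialrl
Title: Social Reinforcement Learning: Simulation, Model Fitting and Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how imitation is integrated into human
    reinforcement learning on observational two-armed bandit tasks. Simulates
    task schedules in which private choice trials are interleaved with
    demonstrations from a skilled or unskilled demonstrator; implements a
    family of learner models (Rescorla-Wagner baselines, decision biasing,
    model-based imitation, value shaping, and a meta-learning variant with an
    adaptive imitation rate); fits them by maximum likelihood or maximum a
    posteriori with softmax action selection and choice autocorrelation;
    performs random-effects Bayesian model selection via exceedance
    probabilities; and provides model/parameter-recovery harnesses and
    model-free behavioral signatures (imitation rate, accumulation,
    propagation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
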
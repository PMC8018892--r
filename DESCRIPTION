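Package: riskaxioms
Title: Stochastic Axiom Tests and Value Models for Binary Risky Choice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the axiomatic analysis of binary risky choice.
    Simulates choice agents over gambles (probability distributions of
    reward magnitudes), tests the expected-utility axioms in their
    stochastic form (first-order stochastic dominance, weak and strong
    stochastic transitivity, and the continuity axiom with exact binomial
    inference and false-discovery-rate control), estimates indifference
    points with a softmax psychometric fit and indifference curves by
    nonlinear least squares, fits six economic value models (expected
    value, power and S-shaped expected utility, probability weighting,
    additive, mean-variance) to single-trial choices by maximum
    likelihood, reconstructs model-predicted indifference maps including
    the Marschak-Machina triangle representation, and compares models by
    RMSE, BIC, AIC and preference-deviation variance.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
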
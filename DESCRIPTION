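Package: lbarena
Title: Competitive Decision-Making with the Linear Ballistic Accumulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian analysis of deadline-bound
    point-scoring competitions in which both the participant and a
    computerized opponent make perceptual decisions governed by the Linear
    Ballistic Accumulator (LBA). Provides closed-form LBA first-passage
    mathematics, a factorial competition simulator with a calibrated
    opponent, trial-level regression of decision threshold and correct-
    response drift rate on score difference and time remaining, gradient-free
    differential-evolution MCMC for the hierarchical model, Savage-Dickey
    Bayes factors with conventional evidence labels, and Bayesian
    mixed-effects polynomial regressions of accuracy and response time.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
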
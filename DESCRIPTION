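Package: selbias
Title: Selection Bias in Multi-Arm Randomized Trials with Permuted Block
    Designs
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the impact of selection bias on the type I error
    probability of the global F-test in K-arm randomized clinical trials
    that allocate patients with the permuted block design. Implements two
    biasing policies generalizing the Blackwell-Hodges convergence
    guessing strategy to more than two arms, the exact conditional
    rejection probability of the F-test via the doubly noncentral F
    distribution, Monte Carlo and exact enumeration assessment of the
    proportion of randomization sequences with inflated type I error, a
    selection-bias-adjusted F-test with an estimator of the selection
    effect, and Cohen's-f effect size calibration for one-way ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
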
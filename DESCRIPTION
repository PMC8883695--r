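Package: causalfpr
Title: Causal False-Positive Risk of Confounders and Colliders in Linear
    Markovian Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation framework for quantifying the probability of
    falsely rejecting a true structural causal model (the causal
    false-positive risk) and the bias this induces on causal effect
    estimates.  Provides directed acyclic graph (DAG) primitives with
    d-separation, single-door and backdoor adjustment-set search; linear
    Gaussian Markovian structural causal models with exact implied
    covariance and path-tracing causal effects; closed-form Savage-Dickey
    Bayes factors for testing the vanishing and non-vanishing partial
    regression coefficients a DAG entails; rule-based adaptive DAG
    modification for the confounder and collider motifs; and a Monte
    Carlo driver that estimates the causal false-positive risk and the
    Monte Carlo mean of the average, direct and indirect causal effect
    estimates across a grid of coefficient settings and sample sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
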
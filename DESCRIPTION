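Package: audcm
Title: Effective Connectivity of the Auditory Cortex During Syllable
    Perception
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying how the place of
    articulation of stop consonants modulates auditory-cortex networks.
    Generates blocked consonant-vowel syllable designs with parametric
    place-of-articulation and voice-onset-time modulators, simulates
    region-of-interest BOLD time series from a five-node bilinear dynamic
    causal model (left/right medial and lateral auditory cortex plus left
    planum temporale), inverts such models with a damped Gauss-Newton
    scheme under Gaussian priors with a Laplace approximation to the model
    evidence, performs fixed- and random-effects Bayesian model selection
    and Bayesian model averaging over the sixteen-model modulation space,
    and runs the companion univariate analysis: a parametric general linear
    model with discrete-cosine high-pass filtering, one-sample group
    contrasts, and a 2x2x2x2 repeated-measures ANOVA with Greenhouse-Geisser
    correction and Fisher LSD post hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
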
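Package: twostepr
Title: Simulation, Model Fitting and Psychometrics for the Two-Stage Decision Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the two-stage (sequential two-step) decision task used
    to quantify model-based versus model-free control of choice. Provides a
    generative task simulator with Gaussian random-walk reward probabilities,
    the hybrid model-based/model-free reinforcement-learning choice likelihood,
    a joint choice and reaction-time likelihood coupling the learning model to
    a Wiener drift-diffusion process, individual maximum-likelihood and
    hierarchical expectation-maximization fitting with integrated-BIC model
    comparison, model-agnostic model-basedness scores from choices and from
    second-stage reaction times, and simulation studies of their psychometric
    properties: parameter recovery, split-half reliability with Spearman-Brown
    correction, temporal stability, and MANOVA-based statistical power for
    group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    lme4
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
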
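Package: occupriors
Title: Prior Sensitivity Tools for Bayesian Site-Occupancy Models
Version: 0.1.0
Authors@R:
    person("Avery", "Lockhart", email = "avery.lockhart@example.org",
           role = c("aut", "cre"))
Description: Simulate single-season site-occupancy detection histories with
    imperfect detection, fit the occupancy model by maximum likelihood and by
    a from-scratch latent-state MCMC sampler under a library of logit-scale
    priors (Normal, Logistic, Student-t, Cauchy, Jeffreys, uniform on the
    probability scale), compute the prior each choice induces on the
    probability scale through the logit link, and run prior-sensitivity
    sweeps that expose when nominally "vague" priors distort inference about
    occupancy probability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
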
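# occupriors

Prior-sensitivity tools for Bayesian site-occupancy models.

Detection/non-detection surveys underestimate where a species occurs
because a present species is often missed. The single-season occupancy
model corrects for that by modeling occupancy and detection jointly:

    y_i ~ Binomial(n_i, p * z_i),    z_i ~ Bernoulli(psi_i),
    logit(psi_i) = alpha + x_i beta'

with `y_i` detections in `n_i` occasions at site `i`, latent occupancy
state `z_i`, per-occasion detection probability `p`, and occupancy
probability `psi_i` on the logit scale.

When this model is fit in a Bayesian framework, the conventional
"vague" prior `alpha ~ Normal(0, sigma)` with large `sigma` is anything
but vague: pushed through the inverse logit it piles its mass against
`psi = 0` and `psi = 1` and can pull the posterior far from what the
data support. `occupriors` is a toolkit for seeing and quantifying
this:

* **simulate** detection histories with known truth
  (`simulate_occupancy()`),
* **fit** the model by maximum likelihood (`fit_occu_mle()`, the
  prior-free reference) and by a from-scratch latent-state MCMC sampler
  (`fit_occu_bayes()`) under a library of priors — Normal, Logistic,
  Student-t, Cauchy, Jeffreys, uniform-on-probability
  (`prior_spec()`),
* **expose** what any logit-scale prior implies on the probability
  scale (`induced_density()`, `sample_induced()`),
* **sweep** prior scales and compare every posterior to the MLE, with
  bimodality detection and Gelman-Rubin diagnostics (`sigma_sweep()`,
  `compare_to_mle()`, `detect_bimodality()`, `gelman_rubin()`),
* **drive it all from the shell** (`occu_cli()`: `simulate`, `fit-mle`,
  `fit-bayes`, `induced-prior`, `sweep`), with CSV in and CSV out.

It is aimed at ecologists and biostatisticians who fit occupancy (or
any logistic-link) models and want to know how much of their posterior
is data and how much is prior.

## Worked example

Simulate 100 sites surveyed 10 times with true occupancy 0.9 and
per-occasion detection 0.2, then compare fits:

```r
library(occupriors)
sim <- simulate_occupancy(100, 10, psi = 0.9, p = 0.2, seed = 1)
sim$data
#> Detection history: 100 sites, 10-10 occasions, 86 site(s) with >=1 detection (naive occupancy 0.860)

fit_occu_mle(sim$data)
#> Occupancy model, maximum likelihood fit
#>   log-likelihood -163.5630; converged: TRUE (restarts used: 5)
#>  parameter estimate     se   ci_lo   ci_hi       scale
#>      alpha   3.0930 1.0578  1.0198  5.1662       logit
#>    logit_p  -1.3560 0.0950 -1.5423 -1.1697       logit
#>    psi_ref   0.9566     NA  0.7349  0.9943 probability
#>          p   0.2049     NA  0.1762  0.2369 probability

fit <- fit_occu_bayes(sim$data, priors = prior_logistic(),
                      config = mcmc_config(seed = 2))
summary(fit)
#>  parameter median   mode  ci_lo  ci_hi   rhat
#>      alpha 2.8430 2.6511 1.8074 5.4643 1.0073
#>          p 0.2069 0.2053 0.1796 0.2366 1.0011
#>    psi_ref 0.9450 0.9383 0.8590 0.9958 1.0045
```

The naive occupancy (0.86) undercounts; the MLE corrects it to 0.957
with `p` back near its true 0.2, and under the weakly informative
Logistic(0,1) prior (which induces exactly a Uniform(0,1) prior on
`psi`) the posterior mode sits beside the MLE with R-hat ~ 1.

Now the point of the package — the same data under different Normal
prior scales:

```r
sw <- sigma_sweep(sim$data, sigma_values = c(0.5, 2, 1000),
                  priors = list(prior_logistic()),
                  config = mcmc_config(seed = 2))
sw
#> Prior-sensitivity sweep over 4 prior(s); MLE reference psi = 0.9566, p = 0.2049
#>           prior psi_mode psi_median mode_discrepancy bimodal max_rhat
#>   normal(0,0.5)   0.8409     0.8390          -0.1158   FALSE   1.0005
#>     normal(0,2)   0.9626     0.9488           0.0060   FALSE   1.0026
#>  normal(0,1000)   1.0000     1.0000           0.0434   FALSE   1.0020
#>   logistic(0,1)   0.9434     0.9433          -0.0132   FALSE   1.0021
```

A "tight" `sigma = 0.5` drags the mode 0.12 below the MLE (shrinkage
toward `psi = 0.5`); `sigma = 2` is approximately prior-free;
the "vague" `sigma = 1000` drives the posterior onto the `psi = 1`
boundary — the induced prior, not the data, is doing the talking. The
`logistic(0,1)` row stays on the MLE. `compare_to_mle(sw)` orders the
discrepancies; `plot(sw)` draws the posterior of each row against the
MLE reference line.

What each prior *means* on the probability scale can be inspected
directly:

```r
range(induced_density(prior_logistic())$density)  # exactly uniform
#> [1] 1 1
```

## Command line

```sh
Rscript -e 'occupriors::occu_cli()' simulate --sites 100 --occasions 10 \
    --psi 0.9 --p 0.2 --seed 1 --out runs/sim
Rscript -e 'occupriors::occu_cli()' sweep --data runs/sim/detections.csv \
    --sigmas 0.25,0.5,1,2,5,10,100,500,1000 --seed 2 --out runs/sweep
```

Every run writes its resolved configuration and a log (seed, timing,
acceptance rates, R-hat) beside its outputs, so any run is reproducible
from the config plus inputs.

## Documentation

The methods vignette (`vignettes/occupancy-priors.Rmd`) covers the
model, the induced-prior mathematics, sampler design, numerical
choices, and known limitations; every user-facing function has roxygen
documentation.
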
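test_that("latent-state update follows the exact full conditional", {
  dh <- detection_history(c(3, 0), 10)
  set.seed(1)
  z <- update_latent_z(dh, psi = c(0.5, 0.5), p = 0.2)
  expect_identical(z[1], 1L)                      # detected site forced
  # y = 0, p = 0: non-detection carries no information
  many0 <- detection_history(rep(0, 20000), 10)
  set.seed(2)
  z0 <- update_latent_z(many0, psi = 0.7, p = 0)
  expect_lt(abs(mean(z0) - 0.7), 3 * sqrt(0.7 * 0.3 / 20000))
  # Bayes-rule oracle at the stated world
  target <- 0.9 * 0.8^10 / (0.9 * 0.8^10 + 0.1)
  set.seed(3)
  zb <- update_latent_z(many0, psi = 0.9, p = 0.2)
  expect_lt(abs(mean(zb) - target), 3 * sqrt(target * (1 - target) / 20000))
})

test_that("detection update is the conjugate Beta draw", {
  one <- detection_history(2, 10)
  set.seed(4)
  draws <- replicate(20000, update_detection(one, z = 1L))
  # Beta(3, 9): mean 0.25
  expect_lt(abs(mean(draws) - 0.25),
            3 * sqrt(0.25 * 0.75 / 13) / sqrt(20000))
  # no occupied site: prior fallback Uniform(0,1)
  none <- detection_history(0, 10)
  set.seed(5)
  u <- replicate(5000, update_detection(none, z = 0L))
  expect_gt(ks.test(u, punif)$p.value, 0.01)
  expect_error(update_detection(one, z = 0L), "detected site")
})

test_that("regression update samples the prior when data are absent", {
  # zero sites: the Bernoulli likelihood is flat, MH must recover the prior
  spec <- prior_normal(2)
  alpha <- 0; out <- numeric(40000)
  set.seed(6)
  for (t in seq_along(out)) {
    up <- update_regression(alpha, numeric(0), integer(0), NULL,
                            list(spec), proposal_sd = 5)
    alpha <- up$alpha
    out[t] <- alpha
  }
  thin <- out[seq(20, length(out), by = 20)]
  expect_gt(ks.test(thin, pnorm, 0, 2)$p.value, 0.01)
})

test_that("a near-degenerate prior pins the intercept", {
  sim <- simulate_occupancy(50, 10, psi = 0.9, p = 0.2, seed = 7)
  fit <- fit_occu_bayes(sim$data, priors = prior_normal(1e-4),
                        config = short_cfg(seed = 8))
  expect_lt(max(abs(pooled_draws(fit, "alpha"))), 0.01)
  expect_lt(abs(median(pooled_draws(fit, "psi_ref")) - 0.5), 0.01)
})

test_that("the sampler matches the quadrature oracle on toy data", {
  dh <- toy10()
  fit <- fit_occu_bayes(dh, priors = prior_logistic(),
                        config = mcmc_config(seed = 9))
  oracle <- quad_posterior(dh$y, dh$n,
                           function(a) dlogis(a, log = TRUE))
  psi <- pooled_draws(fit, "psi_ref"); p <- pooled_draws(fit, "p")
  expect_lt(abs(mean(psi) - oracle$mean_psi), 0.01)
  expect_lt(abs(median(psi) - oracle$median_psi), 0.01)
  expect_lt(abs(mean(p) - oracle$mean_p), 0.01)
  expect_lt(abs(median(p) - oracle$median_p), 0.01)
})

test_that("fits are seed-deterministic and structurally valid", {
  sim <- simulate_occupancy(40, 8, psi = 0.7, p = 0.3, seed = 10)
  a <- fit_occu_bayes(sim$data, priors = prior_t(), config = short_cfg(11))
  b <- fit_occu_bayes(sim$data, priors = prior_t(), config = short_cfg(11))
  expect_identical(a$draws, b$draws)
  expect_true(all(pooled_draws(a, "p") >= 0 & pooled_draws(a, "p") <= 1))
  expect_true(all(pooled_draws(a, "psi_ref") >= 0 &
                  pooled_draws(a, "psi_ref") <= 1))
  expect_equal(dim(a$draws)[2], 1000L)            # n_iter - burn_in
  c_ <- fit_occu_bayes(sim$data, priors = prior_t(), config = short_cfg(12))
  expect_false(identical(a$draws, c_$draws))
})

test_that("adapted acceptance rates land in the Metropolis sweet spot", {
  sim <- simulate_occupancy(100, 10, psi = 0.9, p = 0.2, seed = 13)
  fit <- fit_occu_bayes(sim$data, priors = prior_normal(2),
                        config = mcmc_config(n_iter = 4000, burn_in = 2000,
                                             n_chains = 2, seed = 14))
  expect_true(all(fit$acceptance_rates >= 0.2 & fit$acceptance_rates <= 0.6))
})

test_that("jeffreys is refused for the covariate model", {
  sim <- simulate_occupancy(30, 5, alpha = 0, beta = 1, p = 0.4,
                            covariates = 1, seed = 15)
  expect_error(fit_occu_bayes(sim$data, x = sim$x,
                              priors = prior_jeffreys(),
                              config = short_cfg()),
               "intercept-only")
})

test_that("gelman_rubin separates mixed from unmixed chains", {
  set.seed(16)
  chain <- rnorm(1000)
  copies <- cbind(chain, chain, chain)
  expect_lt(abs(gelman_rubin(copies) - 1), 0.01)
  split_apart <- cbind(rnorm(1000, 0, 1), rnorm(1000, 10, 1))
  expect_gt(gelman_rubin(split_apart), 1.5)
  expect_error(gelman_rubin(matrix(rnorm(100), 100, 1)), "2 chains")
  # constant chains are trivially converged
  expect_equal(gelman_rubin(cbind(rep(2, 50), rep(2, 50))), 1)
})

test_that("posterior_mode locates closed-form and constant modes", {
  expect_equal(posterior_mode(rep(0.4, 200)), 0.4)
  set.seed(17)
  draws <- rbeta(50000, 20, 2)
  expect_lt(abs(posterior_mode(draws, 0, 1) - 19 / 20), 0.02)
  expect_error(posterior_mode(rnorm(50)), "100")
})

test_that("bimodal samples yield the higher-density mode and a flag", {
  set.seed(18)
  mix <- c(rbeta(25000, 40, 10), rbeta(25000, 300, 3))
  expect_gt(posterior_mode(mix, 0, 1), 0.95)      # the sharper component
  b <- detect_bimodality(mix)
  expect_true(b$bimodal)
  expect_length(b$modes, 2L)
})

test_that("summary pools chains and reports coherent intervals", {
  sim <- simulate_occupancy(60, 10, psi = 0.8, p = 0.3, seed = 19)
  fit <- fit_occu_bayes(sim$data, priors = prior_logistic(),
                        config = short_cfg(20, n_chains = 3L))
  s <- summary(fit)
  expect_setequal(s$parameter, c("alpha", "p", "psi_ref"))
  expect_true(all(s$ci_lo <= s$median & s$median <= s$ci_hi))
  p_draws <- pooled_draws(fit, "p")
  expect_equal(s$ci_lo[s$parameter == "p"],
               unname(quantile(p_draws, 0.025)))
  # symmetric, unimodal posterior: median and mode agree within MC error
  expect_lt(abs(s$median[s$parameter == "p"] - s$mode[s$parameter == "p"]),
            0.03)
  long <- draws_to_long(fit)
  expect_equal(nrow(long), prod(dim(fit$draws)))
  expect_equal(long$value[long$parameter == "p" & long$chain == 2 &
                          long$iteration == 5],
               unname(fit$draws[2, 5, "p"]))
})
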
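all_families <- function() {
  list(prior_normal(2), prior_logistic(), prior_t(),
       prior_cauchy(), prior_jeffreys(), prior_uniform_psi())
}

test_that("prior_log_density matches closed forms and normalizes", {
  expect_equal(prior_log_density(prior_logistic(), 0), log(0.25))
  expect_equal(prior_log_density(prior_normal(2), 0),
               log(1 / (2 * sqrt(2 * pi))))
  # uniform_probability on the logit scale IS Logistic(0,1)
  a <- seq(-8, 8, length.out = 50)
  expect_equal(prior_log_density(prior_uniform_psi(), a),
               dlogis(a, 0, 1, log = TRUE))
  # quadrature: every family's logit-scale density integrates to 1
  for (spec in all_families()) {
    total <- integrate(function(v) exp(prior_log_density(spec, v)),
                       -Inf, Inf, rel.tol = 1e-10)$value
    expect_lt(abs(total - 1), 1e-8)
  }
  expect_error(prior_log_density(prior_normal(1), Inf), "finite")
})

test_that("cauchy is student-t with one degree of freedom", {
  a <- c(-3, 0, 1.7)
  expect_equal(prior_log_density(prior_cauchy(0, 2.5), a),
               dcauchy(a, 0, 2.5, log = TRUE))
})

test_that("precision / sigma / variance converters are exact", {
  expect_identical(precision_from_sigma(1), 1)
  expect_equal(precision_from_sigma(10), 0.01)
  expect_equal(precision_from_sigma(0.25), 16)
  sig <- c(0.25, 1.3, 1000)
  expect_lt(max(abs(sigma_from_precision(precision_from_sigma(sig)) - sig)),
            1e-14)
  expect_equal(sigma_from_variance(2), sqrt(2))
  expect_error(precision_from_sigma(0), "> 0")
})

test_that("the prior mini-language round-trips every family", {
  texts <- c("normal(0,2)", "logistic(0,1)", "t(0,1.566,7.763)",
             "cauchy(0,2.5)", "jeffreys", "uniform_probability")
  for (txt in texts) {
    spec <- parse_prior(txt)
    expect_identical(format_prior(parse_prior(format_prior(spec))),
                     format_prior(spec))
  }
  expect_identical(parse_prior("t(0,1.566,7.763)")$family, "student_t")
  expect_error(parse_prior("gamma(1,1)"), "unknown prior family")
  expect_error(parse_prior("normal(0)"), "location, scale")
  expect_error(parse_prior("normal(a,b)"), "non-numeric")
})

test_that("induced densities integrate to 1 and are symmetric", {
  # light-boundary-mass families: grid trapezoid alone reaches 1
  for (spec in list(prior_normal(2), prior_logistic(), prior_t(),
                    prior_jeffreys(), prior_uniform_psi())) {
    d <- induced_density(spec)
    expect_lt(abs(trapz(d$psi_grid, d$density) - 1), 2e-3)
  }
  # heavy-tailed priors put real mass within 1e-6 of the boundary: the
  # grid integral plus the analytic clipped tail mass must reach 1
  L <- logit(1e-6)
  heavy <- list(list(spec = prior_cauchy(0, 2.5),
                     tail = 2 * pcauchy(L, 0, 2.5)),
                list(spec = prior_normal(1000),
                     tail = 2 * pnorm(L, 0, 1000)))
  for (h in heavy) {
    d <- induced_density(h$spec)
    expect_lt(abs(trapz(d$psi_grid, d$density) + h$tail - 1), 2e-3)
  }
  for (spec in all_families()) {
    d <- induced_density(spec)
    expect_true(all(is.finite(d$density)))
    # all library priors are location-0: f(psi) = f(1 - psi)
    rel <- abs(d$density - rev(d$density)) /
      pmax(d$density, rev(d$density), 1e-300)
    expect_lt(max(rel), 1e-10)
  }
})

test_that("logistic(0,1) induces exactly the Uniform(0,1) density", {
  d <- induced_density(prior_logistic())
  expect_lt(max(abs(d$density - 1)), 1e-12)
})

test_that("large-sigma normal priors push induced mass to the extremes", {
  d <- induced_density(prior_normal(1000))
  mid <- which.min(abs(d$psi_grid - 0.5))
  # local minimum at 0.5, maxima only near the grid ends
  expect_lt(d$density[mid], d$density[mid - 200])
  expect_lt(d$density[mid], d$density[mid + 200])
  # global maximum sits at a grid extreme (symmetric: either end)
  expect_true(min(which.max(d$density),
                  length(d$density) + 1 - which.max(d$density)) <= 5)
  # monotone onset: induced density at 0.5 strictly decreasing in sigma
  at_half <- vapply(c(2, 5, 10, 100, 1000), function(s)
    induced_density(prior_normal(s))$density[mid], 0)
  expect_true(all(diff(at_half) < 0))
})

test_that("jeffreys induces Beta(1/2, 1/2) mass piled at the boundary", {
  d <- induced_density(prior_jeffreys())
  at <- function(psi) d$density[which.min(abs(d$psi_grid - psi))]
  expect_gt(at(0.01), at(0.5))
  expect_equal(at(0.5), dbeta(0.5, 0.5, 0.5), tolerance = 1e-10)
})

test_that("the recommended t prior is near-uniform at psi = 0.5", {
  d <- induced_density(prior_t(0, 1.566, 7.763))
  mid <- d$density[which.min(abs(d$psi_grid - 0.5))]
  expect_lt(abs(mid - 1), 0.05)
  expect_equal(mid, dt(0, 7.763) / 1.566 / 0.25, tolerance = 1e-10)
})

test_that("sample_induced agrees with the density and is deterministic", {
  u <- sample_induced(prior_logistic(), 1e5, seed = 8)
  ks <- max(abs(sort(u) - (seq_along(u) - 0.5) / length(u)))
  expect_lt(ks, 1.63 / sqrt(1e5))               # 1% KS critical value
  expect_identical(sample_induced(prior_t(), 50, seed = 2),
                   sample_induced(prior_t(), 50, seed = 2))
  # binned draws vs the exact pushforward probabilities, n = 2e5
  pushforward_cdf <- list(
    "normal(0,2)" = function(q) pnorm(logit(q), 0, 2),
    "t(0,1.566,7.763)" = function(q) pt(logit(q) / 1.566, 7.763),
    "jeffreys" = function(q) pbeta(q, 0.5, 0.5))
  for (label in names(pushforward_cdf)) {
    spec <- parse_prior(label)
    draws <- sample_induced(spec, 2e5, seed = 31)
    breaks <- seq(0, 1, length.out = 51)
    breaks[c(1, 51)] <- c(1e-12, 1 - 1e-12)
    emp <- tabulate(findInterval(draws, breaks, all.inside = TRUE), 50) / 2e5
    th <- diff(pushforward_cdf[[label]](breaks))
    th <- th / sum(th)
    expect_lt(0.5 * sum(abs(emp - th)), 0.02)
  }
})
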
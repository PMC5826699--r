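# Independent oracles: every function here is deliberately coded from the
# model definition itself (plain probability arithmetic, enumeration,
# exhaustive search, dense quadrature) and never calls the code paths it
# checks.

# site likelihood by direct enumeration over the latent state z in {0, 1}
enum_site_lik <- function(y, n, psi, p) {
  p_y_given_z1 <- choose(n, y) * p^y * (1 - p)^(n - y)
  p_y_given_z0 <- as.numeric(y == 0)
  psi * p_y_given_z1 + (1 - psi) * p_y_given_z0
}

# dataset likelihood as a direct product of per-site probabilities
direct_dataset_lik <- function(y, n, psi, p) {
  prod(vapply(seq_along(y),
              function(i) enum_site_lik(y[i], n[i], psi[i], p), 0))
}

# exhaustive grid search of the no-covariate marginal likelihood
grid_mle <- function(y, n, step = 1e-3) {
  psi <- seq(step / 2, 1 - step / 2, by = step)
  p <- psi
  det <- y > 0
  ll <- matrix(0, length(psi), length(p))
  if (any(det)) {
    lbin <- vapply(p, function(pp)
      sum(dbinom(y[det], n[det], pp, log = TRUE)), 0)
    ll <- ll + sum(det) * log(psi) +
      matrix(lbin, length(psi), length(p), byrow = TRUE)
  }
  for (nn in unique(n[!det])) {
    m <- sum(n[!det] == nn)
    ll <- ll + m * log(outer(psi, (1 - p)^nn) + (1 - psi))
  }
  idx <- arrayInd(which.max(ll), dim(ll))
  list(psi = psi[idx[1]], p = p[idx[2]], loglik = max(ll))
}

# dense 2-D quadrature of the exact no-covariate posterior:
# posterior(alpha, p) propto exp(loglik) * prior(alpha) * Unif(0,1)(p)
quad_posterior <- function(y, n, log_prior_alpha,
                           a_lim = c(-14, 14), n_a = 801, n_p = 801) {
  agrid <- seq(a_lim[1], a_lim[2], length.out = n_a)
  pgrid <- seq(1 / (2 * n_p), 1 - 1 / (2 * n_p), length.out = n_p)
  psi <- plogis(agrid)
  ll <- matrix(0, n_a, n_p)
  for (i in seq_along(y)) {
    lik <- outer(psi, dbinom(y[i], n[i], pgrid))
    if (y[i] == 0) lik <- lik + (1 - psi)
    ll <- ll + log(lik)
  }
  lp <- ll + log_prior_alpha(agrid)
  w <- exp(lp - max(lp))
  wa <- rowSums(w); wa <- wa / sum(wa)
  wp <- colSums(w); wp <- wp / sum(wp)
  qtl <- function(x, wt, q) x[which(cumsum(wt) >= q)[1]]
  list(mean_psi = sum(wa * psi), median_psi = qtl(psi, wa, 0.5),
       mean_p = sum(wp * pgrid), median_p = qtl(pgrid, wp, 0.5),
       alpha_weights = wa, alpha_grid = agrid)
}

# the fixed 10-site toy dataset used by the quadrature-oracle checks
toy10 <- function() {
  occupriors::detection_history(y = c(3, 0, 2, 0, 1, 4, 0, 5, 2, 0),
                                n = 10)
}

short_cfg <- function(seed = 1L, n_iter = 2000L, burn_in = 1000L,
                      n_chains = 2L) {
  occupriors::mcmc_config(n_iter = n_iter, burn_in = burn_in,
                          n_chains = n_chains, seed = seed)
}

# trapezoid rule (kept independent of the package's internal helper)
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
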
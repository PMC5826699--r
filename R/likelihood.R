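#' Marginal log-likelihood of one site's detection count
#'
#' The zero-inflated-binomial site likelihood with the latent occupancy
#' state summed out:
#' \deqn{L_i = \psi_i \binom{n_i}{y_i} p^{y_i}(1-p)^{n_i-y_i}
#'       + (1-\psi_i)\,\mathbf{1}\{y_i = 0\}.}
#' The two branches are combined in log space with log-sum-exp, so the
#' result does not underflow even when `psi` sits within 1e-300 of a
#' boundary (which happens under very diffuse logit-scale priors) or
#' when `n` is of order 1e4.
#'
#' All arguments are vectorized over sites.
#'
#' @param y Detections per site, `0 <= y <= n`.
#' @param n Occasions per site, `n >= 1`.
#' @param psi Occupancy probability per site, in `[0, 1]`.
#' @param p Per-occasion detection probability, in `[0, 1]` (scalar or
#'   per-site).
#' @return Log-likelihood contribution per site.
#' @export
site_log_likelihood <- function(y, n, psi, p) {
  k <- max(length(y), length(n), length(psi), length(p))
  y <- rep_len(as.numeric(y), k); n <- rep_len(as.numeric(n), k)
  psi <- rep_len(as.numeric(psi), k); p <- rep_len(as.numeric(p), k)
  if (any(y < 0 | y > n | n < 1))
    stop(sprintf("invalid counts: need 0 <= y <= n, n >= 1 (first offender: y = %g, n = %g)",
                 y[which(y < 0 | y > n | n < 1)[1]],
                 n[which(y < 0 | y > n | n < 1)[1]]), call. = FALSE)
  if (any(psi < 0 | psi > 1 | p < 0 | p > 1))
    stop("psi and p must lie in [0, 1]", call. = FALSE)
  lbin <- stats::dbinom(y, n, p, log = TRUE)
  occ <- log(psi) + lbin                      # occupied branch
  out <- occ
  z0 <- y == 0                                # unoccupied branch exists
  if (any(z0)) {
    emp <- log1p(-psi[z0])
    a <- pmax(occ[z0], emp); b <- pmin(occ[z0], emp)
    lse <- ifelse(is.infinite(a) & a < 0, -Inf, a + log1p(exp(b - a)))
    out[z0] <- lse
  }
  out
}

#' Marginal log-likelihood of a full detection-history dataset
#'
#' Sums [site_log_likelihood()] across sites, with per-site occupancy
#' probabilities `psi_i = inv_logit(alpha + x_i beta')` from the
#' logit-scale occupancy regression.
#'
#' @param data A [detection_history()].
#' @param alpha Logit-scale intercept.
#' @param beta Logit-scale coefficients (empty when `x` is `NULL`).
#' @param p Per-occasion detection probability.
#' @param x Optional [covariate_matrix()] paired with `data`.
#' @return Scalar log-likelihood.
#' @export
dataset_log_likelihood <- function(data, alpha, beta = numeric(0), p,
                                   x = NULL) {
  stopifnot(inherits(data, "detection_history"))
  check_cov_consistency(data, x)
  eta <- linear_predictor(alpha, beta, x, n_sites = length(data$y))
  ll <- tryCatch(
    site_log_likelihood(data$y, data$n, inv_logit(eta), p),
    error = function(e) {
      stop(sprintf("site-level likelihood failed: %s", conditionMessage(e)),
           call. = FALSE)
    })
  sum(ll)
}
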
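#' MCMC configuration
#'
#' Defaults mirror the convention this toolkit is built around: 10,000
#' iterations with the first 5,000 discarded as burn-in, and 3 chains
#' started from dispersed random initial values so the Gelman-Rubin
#' diagnostic is meaningful.
#'
#' @param n_iter Total iterations per chain.
#' @param burn_in Iterations discarded (must be < `n_iter`).
#' @param n_chains Number of chains (>= 2 for Gelman-Rubin).
#' @param seed Integer seed; each chain derives its own stream from it.
#' @param adapt Adapt random-walk proposal scales during burn-in toward
#'   an acceptance rate of 0.44, then freeze (frozen scales preserve
#'   detailed balance in the retained chain).
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 10000L, burn_in = 5000L, n_chains = 3L,
                        seed = 1L, adapt = TRUE) {
  stopifnot(n_iter >= 2, burn_in >= 0, n_chains >= 1)
  if (burn_in >= n_iter)
    stop("burn_in must be smaller than n_iter", call. = FALSE)
  structure(list(n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in),
                 n_chains = as.integer(n_chains),
                 seed = as.integer(seed), adapt = isTRUE(adapt)),
            class = "mcmc_config")
}

#' Gibbs update of the latent occupancy states
#'
#' Full conditional of `z_i`: a detected site is occupied with
#' probability 1; for an all-zero history,
#' `P(z_i = 1 | y_i = 0) = psi_i (1-p)^{n_i} / (psi_i (1-p)^{n_i} + 1 - psi_i)`,
#' computed on the log scale so it stays exact when `psi_i` is pushed
#' against 1 by a diffuse prior.
#'
#' @param data A [detection_history()].
#' @param psi Per-site occupancy probabilities.
#' @param p Detection probability.
#' @return Integer 0/1 vector of latent states.
#' @export
update_latent_z <- function(data, psi, p) {
  stopifnot(inherits(data, "detection_history"))
  psi <- rep_len(psi, length(data$y))
  la <- log(psi) + data$n * log1p(-p)     # z = 1, all-zero history
  lb <- log1p(-psi)                        # z = 0
  pr <- 1 / (1 + exp(lb - la))
  pr[is.nan(pr)] <- ifelse(psi[is.nan(pr)] >= 0.5, 1, 0)  # 0/0 guards
  z <- as.integer(stats::runif(length(psi)) < pr)
  z[data$y > 0L] <- 1L
  z
}

#' Conjugate update of the detection probability
#'
#' Under the Uniform(0,1) prior on `p`, the full conditional given the
#' latent states is `Beta(1 + sum y_i, 1 + sum (n_i - y_i))` over the
#' currently occupied sites; with no occupied site it falls back to the
#' Uniform prior (Beta(1,1)).
#'
#' @param data A [detection_history()].
#' @param z Integer 0/1 latent states (must have `z_i = 1` wherever
#'   `y_i > 0`).
#' @return One draw of `p`.
#' @export
update_detection <- function(data, z) {
  stopifnot(inherits(data, "detection_history"),
            length(z) == length(data$y))
  if (any(data$y > 0L & z == 0L))
    stop("z = 0 at a detected site violates the model", call. = FALSE)
  occ <- z == 1L
  stats::rbeta(1, 1 + sum(data$y[occ]), 1 + sum(data$n[occ] - data$y[occ]))
}

# stable log(1 + exp(u))
log1pexp <- function(u) ifelse(u > 33, u, log1p(exp(u)))

# Bernoulli(z | inv_logit(eta)) log-likelihood, stable at extreme eta
bernoulli_loglik <- function(z, eta) sum(z * eta - log1pexp(eta))

#' One Metropolis pass over the occupancy regression coefficients
#'
#' Random-walk Metropolis, one coefficient at a time, against the
#' Bernoulli likelihood of the current latent states times the
#' coefficient's prior. Proposal standard deviations are supplied by the
#' caller (the sampler adapts them during burn-in).
#'
#' @param alpha,beta Current coefficient values.
#' @param z Latent 0/1 states.
#' @param x Optional [covariate_matrix()].
#' @param priors List of [prior_spec()], one for `alpha` and one per
#'   `beta`.
#' @param proposal_sd Numeric vector of proposal standard deviations,
#'   length `1 + length(beta)`.
#' @return List with `alpha`, `beta`, and logical `accepted` per
#'   coefficient.
#' @export
update_regression <- function(alpha, beta, z, x = NULL, priors,
                              proposal_sd) {
  k <- length(beta)
  stopifnot(length(priors) == k + 1L, length(proposal_sd) == k + 1L)
  xm <- if (is.null(x)) NULL
        else if (inherits(x, "covariate_matrix")) x$values else as.matrix(x)
  eta <- if (is.null(xm)) rep(alpha, length(z))
         else drop(alpha + xm %*% beta)
  cur <- c(alpha, beta)
  accepted <- logical(k + 1L)
  ll_cur <- bernoulli_loglik(z, eta)
  for (j in seq_len(k + 1L)) {
    prop <- cur[j] + stats::rnorm(1, 0, proposal_sd[j])
    d_eta <- if (j == 1L) prop - cur[j] else (prop - cur[j]) * xm[, j - 1L]
    eta_prop <- eta + d_eta
    ll_prop <- bernoulli_loglik(z, eta_prop)
    log_r <- (ll_prop + prior_log_density(priors[[j]], prop)) -
             (ll_cur + prior_log_density(priors[[j]], cur[j]))
    if (is.finite(log_r) && log(stats::runif(1)) < log_r) {
      cur[j] <- prop; eta <- eta_prop; ll_cur <- ll_prop
      accepted[j] <- TRUE
    }
  }
  list(alpha = cur[1], beta = cur[seq_len(k) + 1L], accepted = accepted)
}

#' Bayesian fit of the occupancy model by latent-state MCMC
#'
#' A from-scratch data-augmentation sampler: Gibbs update of the latent
#' occupancy states, conjugate Beta update of detection probability
#' under its Uniform(0,1) prior, and per-coordinate adaptive random-walk
#' Metropolis for the logit-scale regression coefficients under the
#' requested priors. Proposal scales adapt toward 44% acceptance during
#' burn-in only.
#'
#' Besides `alpha`, `beta` and `p`, each retained iteration stores
#' `psi_ref = inv_logit(alpha)`, occupancy probability at the reference
#' covariate point (all standardized covariates at 0); with no
#' covariates this is simply the occupancy probability.
#'
#' @param data A [detection_history()].
#' @param x Optional [covariate_matrix()].
#' @param priors A single [prior_spec()] shared by all coefficients, or
#'   a list of length `k + 1` (intercept first). The Jeffreys prior is
#'   only defined for the intercept-only model and is refused with
#'   covariates.
#' @param config An [mcmc_config()].
#' @return An object of class `occu_draws`: `draws` (chains x retained
#'   iterations x parameters array), `parameter_names`,
#'   `acceptance_rates` (per chain and coefficient, post burn-in),
#'   `priors`, and the `config` echo.
#' @examples
#' sim <- simulate_occupancy(50, 10, psi = 0.9, p = 0.2, seed = 1)
#' fit <- fit_occu_bayes(sim$data, priors = prior_logistic(),
#'                       config = mcmc_config(n_iter = 400, burn_in = 200,
#'                                            n_chains = 2))
#' summary(fit)
#' @export
fit_occu_bayes <- function(data, x = NULL, priors,
                           config = mcmc_config()) {
  stopifnot(inherits(data, "detection_history"),
            inherits(config, "mcmc_config"))
  check_cov_consistency(data, x)
  xm <- if (is.null(x)) NULL
        else if (inherits(x, "covariate_matrix")) x$values else as.matrix(x)
  k <- if (is.null(xm)) 0L else ncol(xm)
  if (inherits(priors, "prior_spec"))
    priors <- rep(list(priors), k + 1L)
  if (length(priors) != k + 1L)
    stop(sprintf("need %d prior(s) (intercept + %d coefficient(s)), got %d",
                 k + 1L, k, length(priors)), call. = FALSE)
  if (k > 0L && any(vapply(priors, function(s) s$family, "") == "jeffreys"))
    stop("the Jeffreys prior is only defined for the intercept-only model",
         call. = FALSE)

  S <- length(data$y)
  retained <- config$n_iter - config$burn_in
  par_names <- c("alpha", if (k > 0) paste0("beta_", seq_len(k)),
                 "p", "psi_ref")
  n_par <- length(par_names)
  draws <- array(NA_real_,
                 dim = c(config$n_chains, retained, n_par),
                 dimnames = list(NULL, NULL, par_names))
  acc_rates <- matrix(NA_real_, config$n_chains, k + 1L)

  for (chain in seq_len(config$n_chains)) {
    set.seed(config$seed + 1009L * chain)
    # dispersed, never-degenerate initials
    coefs <- vapply(priors, function(s) {
      v <- prior_sample(s, 1)
      while (abs(v) > 10) v <- prior_sample(s, 1)
      v
    }, 0)
    alpha <- coefs[1]; beta <- coefs[seq_len(k) + 1L]
    p <- stats::runif(1, 0.05, 0.95)
    z <- as.integer(data$y > 0L)
    z[data$y == 0L] <- stats::rbinom(sum(data$y == 0L), 1L, 0.5)

    log_sd <- rep(0, k + 1L)          # proposal scales start at 1
    batch_acc <- rep(0L, k + 1L); batch_n <- 0L; n_batches <- 0L
    post_acc <- rep(0L, k + 1L)

    for (t in seq_len(config$n_iter)) {
      psi <- inv_logit(if (is.null(xm)) rep(alpha, S)
                       else drop(alpha + xm %*% beta))
      z <- update_latent_z(data, psi, p)
      p <- update_detection(data, z)
      up <- update_regression(alpha, beta, z, x = xm, priors = priors,
                              proposal_sd = exp(log_sd))
      alpha <- up$alpha; beta <- up$beta
      batch_acc <- batch_acc + up$accepted
      batch_n <- batch_n + 1L
      if (config$adapt && t <= config$burn_in && batch_n == 50L) {
        n_batches <- n_batches + 1L
        rate <- batch_acc / 50
        log_sd <- log_sd + (rate - 0.44) / sqrt(n_batches)
        batch_acc[] <- 0L; batch_n <- 0L
      }
      if (t > config$burn_in) {
        post_acc <- post_acc + up$accepted
        draws[chain, t - config$burn_in, ] <-
          c(alpha, beta, p, inv_logit(alpha))
      }
    }
    acc_rates[chain, ] <- post_acc / retained
  }
  colnames(acc_rates) <- par_names[seq_len(k + 1L)]
  structure(list(draws = draws, parameter_names = par_names,
                 acceptance_rates = acc_rates,
                 priors = priors, config = config, k = k),
            class = "occu_draws")
}

#' @export
print.occu_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf(
    "Posterior draws: %d chain(s) x %d retained iterations x %d parameters (%s)\n",
    d[1], d[2], d[3], paste(x$parameter_names, collapse = ", ")))
  cat(sprintf("  priors: %s; mean acceptance %.2f\n",
              paste(vapply(x$priors, format_prior, ""), collapse = ", "),
              mean(x$acceptance_rates)))
  invisible(x)
}

#' Pooled draws of one parameter
#'
#' @param draws An `occu_draws`.
#' @param parameter Parameter name (e.g. `"psi_ref"`).
#' @return Numeric vector pooled over chains.
#' @export
pooled_draws <- function(draws, parameter) {
  stopifnot(inherits(draws, "occu_draws"))
  if (!parameter %in% draws$parameter_names)
    stop(sprintf("unknown parameter '%s'", parameter), call. = FALSE)
  as.vector(draws$draws[, , parameter])
}

#' Split-chain Gelman-Rubin diagnostic
#'
#' Potential scale reduction factor from between- and within-chain
#' variances, with each chain split in half so within-chain drift also
#' inflates the statistic. Values near 1 indicate the chains sample a
#' common distribution.
#'
#' @param x An `occu_draws` (returns a named vector, one value per
#'   parameter) or an iterations-by-chains numeric matrix (returns one
#'   value).
#' @return Potential scale reduction factor(s).
#' @export
gelman_rubin <- function(x) {
  if (inherits(x, "occu_draws")) {
    if (dim(x$draws)[1] < 2L)
      stop("Gelman-Rubin requires at least 2 chains", call. = FALSE)
    if (dim(x$draws)[2] < 10L)
      stop("Gelman-Rubin requires at least 10 retained iterations",
           call. = FALSE)
    out <- vapply(x$parameter_names, function(par)
      rhat_split(t(x$draws[, , par])), 0)
    names(out) <- x$parameter_names
    return(out)
  }
  x <- as.matrix(x)
  if (ncol(x) < 2L)
    stop("Gelman-Rubin requires at least 2 chains", call. = FALSE)
  rhat_split(x)
}

# x: iterations x chains
rhat_split <- function(x) {
  n <- nrow(x)
  nh <- n %/% 2L
  halves <- cbind(x[seq_len(nh), , drop = FALSE],
                  x[(n - nh + 1L):n, , drop = FALSE])
  w <- mean(apply(halves, 2, stats::var))
  if (!is.finite(w) || w == 0) return(1)   # constant chains
  b <- nh * stats::var(colMeans(halves))
  var_plus <- (nh - 1) / nh * w + b / nh
  sqrt(var_plus / w)
}

#' Posterior mode from samples
#'
#' The most probable value, estimated as the argmax of a Gaussian-kernel
#' density (Silverman bandwidth) on a 512-point grid spanning the sample
#' range, optionally clipped to known support (e.g. `[0, 1]` for a
#' probability).
#'
#' @param samples Numeric vector of at least 100 draws.
#' @param lower,upper Optional support bounds clipping the grid.
#' @return The mode location.
#' @export
posterior_mode <- function(samples, lower = -Inf, upper = Inf) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 100L)
    stop("need at least 100 samples for a kernel mode; run longer",
         call. = FALSE)
  if (stats::sd(samples) == 0) return(samples[1])
  from <- max(lower, min(samples))
  to <- min(upper, max(samples))
  d <- stats::density(samples, bw = "nrd0", n = 512L, from = from, to = to)
  d$x[which.max(d$y)]
}

#' Posterior summary table
#'
#' Pooled-chain median, kernel-density mode, equal-tailed 95% credible
#' interval (2.5% and 97.5% quantiles), and split-chain Gelman-Rubin
#' statistic per parameter. Probability-type parameters (`p`,
#' `psi_ref`) have their mode grid clipped to `[0, 1]`.
#'
#' @param object An `occu_draws`.
#' @param ... Unused.
#' @return A data.frame of class `occu_summary`.
#' @export
summary.occu_draws <- function(object, ...) {
  rh <- if (dim(object$draws)[1] >= 2L) gelman_rubin(object)
        else stats::setNames(rep(NA_real_, length(object$parameter_names)),
                             object$parameter_names)
  rows <- lapply(object$parameter_names, function(par) {
    s <- pooled_draws(object, par)
    prob <- par %in% c("p", "psi_ref")
    q <- stats::quantile(s, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(parameter = par,
               median = q[2],
               mode = posterior_mode(s, lower = if (prob) 0 else -Inf,
                                     upper = if (prob) 1 else Inf),
               ci_lo = q[1], ci_hi = q[3],
               rhat = unname(rh[par]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("occu_summary", "data.frame")
  out
}

#' @export
print.occu_summary <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  y[-1] <- lapply(y[-1], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Long-format draws table
#'
#' @param draws An `occu_draws`.
#' @return data.frame with columns `chain`, `iteration`, `parameter`,
#'   `value` — the CSV schema used by the command line.
#' @export
draws_to_long <- function(draws) {
  stopifnot(inherits(draws, "occu_draws"))
  d <- dim(draws$draws)
  expand <- expand.grid(chain = seq_len(d[1]), iteration = seq_len(d[2]),
                        parameter = draws$parameter_names,
                        stringsAsFactors = FALSE)
  expand$value <- as.vector(draws$draws)
  expand
}
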
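#' Simulate a single-season occupancy dataset
#'
#' Draws latent occupancy states `z_i ~ Bernoulli(psi_i)` and detection
#' counts `y_i ~ Binomial(n_i, p * z_i)`. Occupancy is either constant
#' (`psi`) or covariate-driven on the logit scale
#' (`psi_i = inv_logit(alpha + x_i beta')`). Covariates are drawn as
#' independent standard normals unless a matrix is supplied, mirroring
#' the standardized-covariate setting in which the regression priors of
#' this toolkit are meant to be interpreted.
#'
#' The latent truth `z` is returned alongside the data so recovery tests
#' never have to re-derive occupancy from detections. The same
#' `(config, seed)` always reproduces the same dataset.
#'
#' @param n_sites Number of surveyed sites (>= 1).
#' @param n_occasions Occasions per site (scalar or per-site, >= 1).
#' @param psi Constant occupancy probability; mutually exclusive with
#'   `alpha`/`beta`.
#' @param alpha,beta Logit-scale intercept and coefficients of the
#'   occupancy regression; use with `covariates`.
#' @param p Per-occasion detection probability.
#' @param covariates Either `NULL`, an integer k (draw k standard-normal
#'   columns), or a matrix / [covariate_matrix()] with `n_sites` rows.
#' @param seed Integer seed; recorded in the output.
#' @return An object of class `occu_sim`: list with `data` (a
#'   [detection_history()]), `x` (a [covariate_matrix()] or `NULL`),
#'   `z` (latent truth, 0/1), `psi` (per-site generating occupancy) and
#'   `config` (the resolved simulation settings).
#' @examples
#' sim <- simulate_occupancy(100, 10, psi = 0.9, p = 0.2, seed = 1)
#' sim$data
#' @export
simulate_occupancy <- function(n_sites, n_occasions, psi = NULL,
                               alpha = NULL, beta = NULL, p,
                               covariates = NULL, seed = 1L) {
  stopifnot(n_sites >= 1, all(n_occasions >= 1),
            is.numeric(p), p >= 0, p <= 1)
  if (is.null(psi) == is.null(alpha))
    stop("supply exactly one of `psi` or `alpha` (+ optional beta)",
         call. = FALSE)
  if (!is.null(psi) && (psi < 0 || psi > 1))
    stop("psi must lie in [0, 1]", call. = FALSE)
  n_occ <- rep_len(as.integer(n_occasions), n_sites)
  seed <- as.integer(seed)

  set.seed(seed)
  x <- NULL
  if (!is.null(covariates)) {
    if (is.numeric(covariates) && length(covariates) == 1L &&
        covariates == as.integer(covariates) && is.null(dim(covariates))) {
      k <- as.integer(covariates)
      vals <- matrix(stats::rnorm(n_sites * k), n_sites, k)
      x <- covariate_matrix(vals, names = paste0("x", seq_len(k)))
    } else {
      x <- if (inherits(covariates, "covariate_matrix")) covariates
           else covariate_matrix(covariates)
      if (nrow(x$values) != n_sites)
        stop("covariate rows must equal n_sites", call. = FALSE)
    }
  }
  if (is.null(psi)) {
    beta <- if (is.null(beta)) numeric(0) else as.numeric(beta)
    psi_i <- inv_logit(linear_predictor(alpha, beta, x, n_sites = n_sites))
  } else {
    if (!is.null(x))
      stop("covariates require alpha/beta, not a constant psi", call. = FALSE)
    psi_i <- rep(psi, n_sites)
  }

  z <- stats::rbinom(n_sites, 1L, psi_i)
  y <- stats::rbinom(n_sites, n_occ, p * z)
  cfg <- list(n_sites = n_sites, n_occasions = n_occasions,
              psi = psi, alpha = alpha, beta = beta, p = p,
              k_covariates = if (is.null(x)) 0L else ncol(x$values),
              seed = seed)
  structure(list(data = detection_history(y, n_occ),
                 x = x, z = z, psi = psi_i, config = cfg),
            class = "occu_sim")
}

#' @export
print.occu_sim <- function(x, ...) {
  cat(sprintf("Simulated occupancy dataset (seed %d):\n", x$config$seed))
  print(x$data)
  cat(sprintf("  true occupied sites: %d of %d\n",
              sum(x$z), length(x$z)))
  invisible(x)
}
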
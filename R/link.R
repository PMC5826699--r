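#' Inverse-logit (expit) transform
#'
#' Maps a logit-scale value to a probability, `exp(x) / (1 + exp(x))`,
#' using a branch that never overflows for large `|x|` (values of order
#' 1e3 arise routinely under very diffuse priors). `-Inf` and `Inf` map
#' to exactly 0 and 1.
#'
#' @param x Numeric vector on the logit (log-odds) scale.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @examples
#' inv_logit(0)            # 0.5
#' inv_logit(c(-5, 5))     # ~0.01, ~0.99
#' @seealso [logit()]
#' @export
inv_logit <- function(x) {
  stopifnot(is.numeric(x))
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  out[!pos] <- exp(x[!pos]) / (1 + exp(x[!pos]))
  out[is.na(x)] <- NA_real_
  out
}

#' Logit (log-odds) transform
#'
#' `log(psi / (1 - psi))`, the exact inverse of [inv_logit()]. Boundary
#' values 0 and 1 are a domain error: on the logit scale they correspond
#' to infinities, which the occupancy model never needs as data.
#'
#' @param psi Numeric vector of probabilities, strictly inside (0, 1).
#' @return Numeric vector on the logit scale.
#' @export
logit <- function(psi) {
  stopifnot(is.numeric(psi))
  bad <- !is.na(psi) & (psi <= 0 | psi >= 1)
  if (any(bad)) {
    stop(sprintf("logit() requires values strictly in (0, 1); got %s",
                 paste(format(psi[bad][seq_len(min(3, sum(bad)))]),
                       collapse = ", ")),
         call. = FALSE)
  }
  log(psi) - log1p(-psi)
}

#' Per-site linear predictor of the occupancy regression
#'
#' Computes `alpha + x %*% beta` for every site: the logit-scale
#' occupancy regression. With no covariates (`x = NULL`) `beta` must be
#' empty and the intercept is replicated across sites.
#'
#' @param alpha Scalar logit-scale intercept.
#' @param beta Numeric vector of logit-scale coefficients (length 0 when
#'   `x` is `NULL`).
#' @param x A [covariate_matrix()], a plain numeric matrix, or `NULL`.
#' @param n_sites Number of sites; required when `x` is `NULL`, ignored
#'   otherwise.
#' @return Numeric vector, one logit-scale value per site.
#' @export
linear_predictor <- function(alpha, beta = numeric(0), x = NULL,
                             n_sites = NULL) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  beta <- as.numeric(beta)
  if (is.null(x)) {
    if (length(beta) > 0L)
      stop("beta must be empty when no covariates are supplied", call. = FALSE)
    if (is.null(n_sites))
      stop("n_sites is required when x is NULL", call. = FALSE)
    return(rep(alpha, n_sites))
  }
  xm <- if (inherits(x, "covariate_matrix")) x$values else as.matrix(x)
  if (ncol(xm) != length(beta))
    stop(sprintf("beta has length %d but x has %d column(s)",
                 length(beta), ncol(xm)), call. = FALSE)
  drop(alpha + xm %*% beta)
}
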
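#' Prior specification for a logit-scale coefficient
#'
#' The prior families studied by this toolkit for the logit-scale
#' intercept and coefficients of the occupancy regression:
#'
#' * `normal(location, scale)` — the conventional Gaussian prior; `scale`
#'   is the standard deviation sigma (see [precision_from_sigma()] for
#'   the precision convention used by BUGS-family engines).
#' * `logistic(location, scale)` — `logistic(0, 1)` on the intercept
#'   induces exactly a Uniform(0,1) prior on occupancy probability.
#' * `student_t(location, scale, df)` — e.g. `t(0, 1.566, 7.763)`, a
#'   weakly informative choice whose induced probability-scale prior is
#'   near-uniform.
#' * `cauchy(location, scale)` — `cauchy(0, 2.5)`, the classic default
#'   for logistic regression coefficients; implemented internally as
#'   Student-t with df = 1.
#' * `jeffreys` — the transformation-invariant prior; on the probability
#'   scale it is Beta(1/2, 1/2), so on the logit scale it is that
#'   distribution's pushforward. Only meaningful for an intercept-only
#'   model (it is parameter-dependent with covariates) and refused there.
#' * `uniform_probability` — Uniform(0,1) on the probability scale; its
#'   logit-scale density is exactly Logistic(0, 1).
#'
#' @param family One of `"normal"`, `"logistic"`, `"student_t"`,
#'   `"cauchy"`, `"jeffreys"`, `"uniform_probability"`.
#' @param location,scale Location and scale of the logit-scale density
#'   (ignored by `jeffreys` / `uniform_probability`, which carry no free
#'   parameters).
#' @param df Degrees of freedom (`student_t` only).
#' @return An object of class `prior_spec`.
#' @examples
#' prior_normal(2)
#' parse_prior("t(0,1.566,7.763)")
#' @export
prior_spec <- function(family, location = 0, scale = 1, df = NULL) {
  family <- match.arg(family, c("normal", "logistic", "student_t",
                                "cauchy", "jeffreys",
                                "uniform_probability"))
  if (family %in% c("jeffreys", "uniform_probability")) {
    location <- 0; scale <- 1; df <- NULL
  } else {
    stopifnot(is.numeric(location), is.finite(location),
              is.numeric(scale), scale > 0)
    if (family == "student_t") {
      if (is.null(df) || !is.numeric(df) || df <= 0)
        stop("student_t requires df > 0", call. = FALSE)
    } else df <- NULL
  }
  structure(list(family = family, location = location,
                 scale = scale, df = df),
            class = "prior_spec")
}

#' @rdname prior_spec
#' @param sigma Standard deviation of the Normal prior.
#' @export
prior_normal <- function(sigma, location = 0)
  prior_spec("normal", location, sigma)

#' @rdname prior_spec
#' @export
prior_logistic <- function(location = 0, scale = 1)
  prior_spec("logistic", location, scale)

#' @rdname prior_spec
#' @export
prior_t <- function(location = 0, scale = 1.566, df = 7.763)
  prior_spec("student_t", location, scale, df)

#' @rdname prior_spec
#' @export
prior_cauchy <- function(location = 0, scale = 2.5)
  prior_spec("cauchy", location, scale)

#' @rdname prior_spec
#' @export
prior_jeffreys <- function() prior_spec("jeffreys")

#' @rdname prior_spec
#' @export
prior_uniform_psi <- function() prior_spec("uniform_probability")

#' @export
print.prior_spec <- function(x, ...) {
  cat("Prior:", format_prior(x), "\n")
  invisible(x)
}

#' Serialize / parse the textual prior mini-language
#'
#' Prior specs serialize to the flat text form `family(location, scale[,
#' df])` used by the command line, e.g. `normal(0,2)`, `logistic(0,1)`,
#' `t(0,1.566,7.763)`, `cauchy(0,2.5)`; the parameter-free families are
#' written bare as `jeffreys` and `uniform_probability`.
#'
#' @param spec A `prior_spec` (for `format_prior`).
#' @param text A string in the mini-language (for `parse_prior`).
#' @return `format_prior`: a string. `parse_prior`: a `prior_spec`.
#' @export
format_prior <- function(spec) {
  stopifnot(inherits(spec, "prior_spec"))
  switch(spec$family,
    jeffreys = "jeffreys",
    uniform_probability = "uniform_probability",
    student_t = sprintf("t(%s,%s,%s)", format(spec$location),
                        format(spec$scale), format(spec$df)),
    sprintf("%s(%s,%s)", spec$family, format(spec$location),
            format(spec$scale)))
}

#' @rdname format_prior
#' @export
parse_prior <- function(text) {
  text <- gsub("[[:space:]]", "", tolower(text))
  if (text %in% c("jeffreys", "jeffreys()")) return(prior_jeffreys())
  if (text %in% c("uniform_probability", "uniform_probability()",
                  "uniform_psi"))
    return(prior_uniform_psi())
  m <- regmatches(text, regexec("^([a-z_]+)\\(([^)]*)\\)$", text))[[1]]
  if (length(m) != 3L)
    stop(sprintf("cannot parse prior spec '%s'", text), call. = FALSE)
  fam <- switch(m[2], t = "student_t", student_t = "student_t",
                normal = "normal", logistic = "logistic",
                cauchy = "cauchy",
                stop(sprintf("unknown prior family '%s'", m[2]),
                     call. = FALSE))
  args <- suppressWarnings(as.numeric(strsplit(m[3], ",")[[1]]))
  if (anyNA(args))
    stop(sprintf("non-numeric parameter in prior spec '%s'", text),
         call. = FALSE)
  if (fam == "student_t") {
    if (length(args) != 3L)
      stop("t prior needs (location, scale, df)", call. = FALSE)
    prior_spec("student_t", args[1], args[2], args[3])
  } else {
    if (length(args) != 2L)
      stop(sprintf("%s prior needs (location, scale)", fam), call. = FALSE)
    prior_spec(fam, args[1], args[2])
  }
}

#' Log density of a prior on the logit scale
#'
#' Evaluates the prior's density for the logit-scale parameter itself.
#' For `uniform_probability` this is exactly the Logistic(0,1) density;
#' for `jeffreys` it is the logit-scale pushforward of Beta(1/2, 1/2),
#' i.e. `sqrt(psi (1 - psi)) / pi` with `psi = inv_logit(alpha)`.
#'
#' @param spec A [prior_spec()].
#' @param alpha Numeric vector of logit-scale values.
#' @return Log-density values.
#' @export
prior_log_density <- function(spec, alpha) {
  stopifnot(inherits(spec, "prior_spec"), is.numeric(alpha))
  if (any(!is.finite(alpha)))
    stop("alpha must be finite", call. = FALSE)
  z <- (alpha - spec$location) / spec$scale
  switch(spec$family,
    normal = stats::dnorm(alpha, spec$location, spec$scale, log = TRUE),
    logistic = stats::dlogis(alpha, spec$location, spec$scale, log = TRUE),
    student_t = stats::dt(z, spec$df, log = TRUE) - log(spec$scale),
    cauchy = stats::dt(z, 1, log = TRUE) - log(spec$scale),
    uniform_probability = stats::dlogis(alpha, 0, 1, log = TRUE),
    jeffreys = {
      # Beta(1/2,1/2) pushed through logit: f(a) = sqrt(psi(1-psi))/pi
      lpsi <- stats::plogis(alpha, log.p = TRUE)
      lq <- stats::plogis(-alpha, log.p = TRUE)
      0.5 * (lpsi + lq) - log(pi)
    })
}

#' Draw from a prior on the logit scale
#'
#' Seeded sampler used for prior-predictive checks, chain
#' initialization, and [sample_induced()].
#'
#' @param spec A [prior_spec()].
#' @param n Number of draws.
#' @param seed Optional integer seed (`NULL` leaves the RNG stream
#'   alone).
#' @return Numeric vector of logit-scale draws.
#' @export
prior_sample <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "prior_spec"), n >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  switch(spec$family,
    normal = stats::rnorm(n, spec$location, spec$scale),
    logistic = stats::rlogis(n, spec$location, spec$scale),
    student_t = spec$location + spec$scale * stats::rt(n, spec$df),
    cauchy = spec$location + spec$scale * stats::rt(n, 1),
    uniform_probability = stats::rlogis(n, 0, 1),
    jeffreys = logit(stats::rbeta(n, 0.5, 0.5)))
}

#' Convert between sigma, variance and precision
#'
#' BUGS-family MCMC engines parameterize the Normal distribution by the
#' precision `tau = 1 / sigma^2`, while this toolkit's public interface
#' uses the standard deviation `sigma` throughout (and some sensitivity
#' sweeps are quoted in the variance `sigma^2`). These converters make
#' the translation explicit instead of leaving it to memory.
#'
#' @param sigma Standard deviation (> 0).
#' @param tau Precision (> 0).
#' @param variance Variance (> 0).
#' @return The converted quantity.
#' @examples
#' precision_from_sigma(10)   # 0.01
#' sigma_from_variance(2)     # ~1.414
#' @export
precision_from_sigma <- function(sigma) {
  stopifnot(is.numeric(sigma), all(sigma > 0))
  1 / sigma^2
}

#' @rdname precision_from_sigma
#' @export
sigma_from_precision <- function(tau) {
  stopifnot(is.numeric(tau), all(tau > 0))
  1 / sqrt(tau)
}

#' @rdname precision_from_sigma
#' @export
sigma_from_variance <- function(variance) {
  stopifnot(is.numeric(variance), all(variance > 0))
  sqrt(variance)
}
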
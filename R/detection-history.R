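#' Detection history container
#'
#' A single-season detection history collapsed to per-site counts: `y[i]`
#' detections out of `n[i]` survey occasions at site `i`. Occasions with a
#' missing visit simply reduce `n[i]`; per-occasion structure beyond the
#' counts is not retained because the model's binomial observation layer
#' only consumes `(y, n)`.
#'
#' @param y Integer vector, detections per site (`0 <= y[i] <= n[i]`).
#' @param n Integer vector, occasions per site (`n[i] >= 1`). A scalar is
#'   recycled across sites.
#' @param site_ids Optional character labels, one per site; defaults to
#'   `site_1 ... site_S`. Must be unique.
#' @return An object of class `detection_history`: a list with elements
#'   `y`, `n`, `site_ids`.
#' @examples
#' dh <- detection_history(y = c(0, 2, 5), n = 5)
#' dh
#' @export
detection_history <- function(y, n, site_ids = NULL) {
  y <- as.integer(y)
  if (length(n) == 1L) n <- rep(n, length(y))
  n <- as.integer(n)
  if (length(y) == 0L) stop("need at least one site", call. = FALSE)
  if (length(n) != length(y))
    stop("y and n must have equal length", call. = FALSE)
  if (anyNA(y) || anyNA(n))
    stop("y and n must not contain NA", call. = FALSE)
  if (any(n < 1L))
    stop("every site needs at least one occasion (n >= 1)", call. = FALSE)
  bad <- which(y < 0L | y > n)
  if (length(bad))
    stop(sprintf("invalid counts at site index %d: y = %d, n = %d",
                 bad[1], y[bad[1]], n[bad[1]]), call. = FALSE)
  if (is.null(site_ids)) site_ids <- paste0("site_", seq_along(y))
  site_ids <- as.character(site_ids)
  if (length(site_ids) != length(y))
    stop("site_ids length must match y", call. = FALSE)
  if (anyDuplicated(site_ids))
    stop(sprintf("duplicate site label: '%s'",
                 site_ids[anyDuplicated(site_ids)]), call. = FALSE)
  structure(list(y = y, n = n, site_ids = site_ids),
            class = "detection_history")
}

#' @export
print.detection_history <- function(x, ...) {
  cat(sprintf(
    "Detection history: %d sites, %d-%d occasions, %d site(s) with >=1 detection (naive occupancy %.3f)\n",
    length(x$y), min(x$n), max(x$n), sum(x$y > 0), mean(x$y > 0)))
  invisible(x)
}

#' @export
length.detection_history <- function(x) length(x$y)

#' @export
as.data.frame.detection_history <- function(x, ...) {
  data.frame(site = x$site_ids, y = x$y, n = x$n,
             stringsAsFactors = FALSE)
}

#' Site covariate matrix
#'
#' A sites-by-k matrix of occupancy covariates with column names and,
#' once [standardize_covariates()] has been applied, a record of the
#' centers and scales so fitted effects can be mapped back to the raw
#' scale.
#'
#' @param values Numeric matrix (or data.frame coercible to one),
#'   one row per site.
#' @param names Optional character vector of k covariate names.
#' @param standardized Logical flag; set by [standardize_covariates()].
#' @param centers,scales Numeric vectors of length k recorded when
#'   standardized.
#' @return An object of class `covariate_matrix`.
#' @export
covariate_matrix <- function(values, names = NULL, standardized = FALSE,
                             centers = NULL, scales = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("covariates must not contain NA", call. = FALSE)
  if (is.null(names)) {
    names <- colnames(values)
    if (is.null(names)) names <- paste0("x", seq_len(ncol(values)))
  }
  if (length(names) != ncol(values))
    stop("names length must match number of columns", call. = FALSE)
  colnames(values) <- names
  if (standardized) {
    stopifnot(length(centers) == ncol(values),
              length(scales) == ncol(values))
  }
  structure(list(values = values, names = names,
                 standardized = isTRUE(standardized),
                 centers = centers, scales = scales),
            class = "covariate_matrix")
}

#' @export
print.covariate_matrix <- function(x, ...) {
  cat(sprintf("Covariate matrix: %d sites x %d covariate(s) [%s]%s\n",
              nrow(x$values), ncol(x$values),
              paste(x$names, collapse = ", "),
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

#' Standardize covariate columns
#'
#' Centers each column at its mean and scales by its sample standard
#' deviation (divisor `n - 1`), recording the centers and scales on the
#' returned object. Standardizing an already-standardized matrix is a
#' no-op. A constant column has no scale and is an error.
#'
#' @param x A [covariate_matrix()] or plain numeric matrix.
#' @return A standardized `covariate_matrix`.
#' @export
standardize_covariates <- function(x) {
  if (!inherits(x, "covariate_matrix")) x <- covariate_matrix(x)
  if (x$standardized) return(x)
  sds <- apply(x$values, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("covariate '%s' is constant and cannot be standardized",
                 x$names[which(sds == 0)[1]]), call. = FALSE)
  ctr <- colMeans(x$values)
  vals <- sweep(sweep(x$values, 2, ctr, "-"), 2, sds, "/")
  covariate_matrix(vals, names = x$names, standardized = TRUE,
                   centers = ctr, scales = sds)
}

# internal: number of sites implied by a covariate argument, with checks
check_cov_consistency <- function(data, x) {
  if (is.null(x)) return(invisible(NULL))
  xm <- if (inherits(x, "covariate_matrix")) x$values else as.matrix(x)
  if (nrow(xm) != length(data$y))
    stop(sprintf("covariate rows (%d) do not match number of sites (%d)",
                 nrow(xm), length(data$y)), call. = FALSE)
  invisible(NULL)
}
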
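#' Read a detection-history CSV
#'
#' Two dialects are accepted. The *wide* form has one column per survey
#' occasion (`site, occ_1, ..., occ_J`) with cells 0, 1, or blank for a
#' missed visit; it collapses to `y_i` = number of 1s and `n_i` = number
#' of non-missing cells, so missing occasions simply reduce `n_i`. The
#' *count* form carries the collapsed counts directly (`site, y, n`).
#' The two dialects round-trip losslessly at the `(y, n)` level.
#'
#' @param path CSV file path.
#' @return A [detection_history()].
#' @examples
#' wide <- system.file("extdata", "example_detections_wide.csv",
#'                     package = "occupriors")
#' read_detection_table(wide)
#' @export
read_detection_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("no such file: '%s'", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!"site" %in% names(df))
    stop(sprintf("'%s': first column must be named 'site'", path),
         call. = FALSE)
  site <- as.character(df$site)
  if (all(c("y", "n") %in% names(df))) {
    bad <- which(df$y > df$n)
    if (length(bad))
      stop(sprintf("'%s' row %d (site '%s'): y = %s exceeds n = %s",
                   path, bad[1], site[bad[1]], df$y[bad[1]], df$n[bad[1]]),
           call. = FALSE)
    return(detection_history(df$y, df$n, site_ids = site))
  }
  occ_cols <- setdiff(names(df), "site")
  if (!length(occ_cols))
    stop(sprintf("'%s': need either (y, n) columns or occasion columns",
                 path), call. = FALSE)
  cells <- as.matrix(df[occ_cols])
  suppressWarnings(storage.mode(cells) <- "double")
  bad <- which(!is.na(cells) & cells != 0 & cells != 1, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "'%s' row %d, column '%s' (site '%s'): cell must be 0, 1 or blank",
      path, bad[1, 1], occ_cols[bad[1, 2]], site[bad[1, 1]]),
      call. = FALSE)
  y <- rowSums(cells == 1, na.rm = TRUE)
  n <- rowSums(!is.na(cells))
  zero_occ <- which(n == 0)
  if (length(zero_occ))
    stop(sprintf("'%s' row %d (site '%s'): every occasion is missing",
                 path, zero_occ[1], site[zero_occ[1]]), call. = FALSE)
  detection_history(y, n, site_ids = site)
}

#' Write a detection history as a count-form CSV
#'
#' @param data A [detection_history()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detection_table <- function(data, path) {
  stopifnot(inherits(data, "detection_history"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a per-site covariate CSV
#'
#' A `site` column followed by one numeric column per covariate.
#'
#' @param path CSV file path.
#' @param x A [covariate_matrix()] (for writing).
#' @param site_ids Site labels written alongside the values.
#' @return `read_covariate_table`: a `covariate_matrix`.
#' @export
read_covariate_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("no such file: '%s'", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"site" %in% names(df))
    stop(sprintf("'%s': first column must be named 'site'", path),
         call. = FALSE)
  covariate_matrix(df[setdiff(names(df), "site")])
}

#' @rdname read_covariate_table
#' @export
write_covariate_table <- function(x, path, site_ids = NULL) {
  stopifnot(inherits(x, "covariate_matrix"))
  if (is.null(site_ids)) site_ids <- paste0("site_", seq_len(nrow(x$values)))
  df <- data.frame(site = site_ids, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a flat key-value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Every command
#' line run writes its resolved configuration beside its outputs so the
#' run is reproducible from the config plus the input files alone.
#'
#' @param path File path.
#' @param config Named list of atomic values (for writing); vectors are
#'   comma-joined.
#' @return `read_run_config`: a named list of strings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("no such file: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop(sprintf("'%s': cannot parse line '%s'", path,
                 lines[which(bad)[1]]), call. = FALSE)
  stats::setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, "", 1L))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  vals <- vapply(config, function(v)
    paste(vapply(v, function(e) format(e, trim = TRUE), ""),
          collapse = ","), "")
  writeLines(paste(names(config), vals, sep = " = "), path)
  invisible(path)
}
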
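#' File formats
#'
#' Everything on disk is self-describing CSV with declared headers; fitted
#' models are stored as an RDS payload next to a small JSON summary. All
#' writers produce byte-identical output for identical inputs.
#'
#' @name cli_io
NULL

write_csv_plain <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write epoch-level CSV
#'
#' Header: `participant_id, epoch_index, accel_mg, day_index, hour_of_day`.
#' @param epochs Epoch data frame.
#' @param path File path.
#' @export
write_epochs_csv <- function(epochs, path) {
  check_epochs(epochs)
  write_csv_plain(epochs, path)
}

#' @rdname write_epochs_csv
#' @export
read_epochs_csv <- function(path) {
  if (!file.exists(path)) stop("no such epoch file: ", path)
  check_epochs(utils::read.csv(path))
}

#' Read/write histogram tables
#'
#' Header: `participant_id, volume, sleep_fraction, valid_wear`, then one
#' `p_<lo>_<hi>` column per bin.
#' @param hist_table From [build_histograms()] (or a cohort table with the
#'   same columns).
#' @param path File path.
#' @param bins Bin scheme (written files are validated against it on read).
#' @export
write_histograms_csv <- function(hist_table, path) {
  write_csv_plain(hist_table, path)
}

#' @rdname write_histograms_csv
#' @export
read_histograms_csv <- function(path, bins = bin_scheme()) {
  if (!file.exists(path)) stop("no such histogram file: ", path)
  out <- utils::read.csv(path)
  miss <- setdiff(bins$labels, names(out))
  if (length(miss))
    stop("histogram file lacks bin column(s): ",
         paste(utils::head(miss, 3), collapse = ", "),
         if (length(miss) > 3) " ...")
  attr(out, "bins") <- bins
  out
}

#' Read/write cohort tables
#' @param cohort Cohort data frame.
#' @param path File path.
#' @param bins Bin scheme attached on read.
#' @export
write_cohort_csv <- function(cohort, path) {
  write_csv_plain(cohort, path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path, bins = bin_scheme()) {
  if (!file.exists(path)) stop("no such cohort file: ", path)
  out <- utils::read.csv(path)
  if ("bmi_category" %in% names(out))
    out$bmi_category <- factor(out$bmi_category,
                               levels = c("healthy", "overweight", "obese"))
  if ("center_id" %in% names(out))
    out$center_id <- factor(out$center_id)
  attr(out, "bins") <- bins
  out
}

#' Save / load a fitted model
#'
#' `path` gains two files: `<path>.rds` (the full `funcox` object, minus
#' the design matrix) and `<path>.json` (human-readable summary: sample
#' size, smoothing parameters, effective df, convergence).
#' @param fit A `funcox` fit.
#' @param path Path stem (no extension).
#' @export
write_model <- function(fit, path) {
  stopifnot(inherits(fit, "funcox"))
  slim <- fit
  slim$X <- NULL
  slim$prep <- NULL
  saveRDS(slim, paste0(path, ".rds"))
  summary <- list(n = fit$n, n_events = fit$n_events,
                  adjusted = fit$spec$adjusted,
                  lambda = as.list(fit$lambda), edf = as.list(fit$edf),
                  loglik = fit$loglik, laml = fit$laml,
                  converged = fit$converged,
                  volume_range = fit$volume_range)
  jsonlite::write_json(summary, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  f <- paste0(path, ".rds")
  if (!file.exists(f)) stop("no such model file: ", f)
  readRDS(f)
}
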
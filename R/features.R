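#' Epoch-level accelerometer features
#'
#' Epoch series are plain data frames with one row per (typically 5-second)
#' epoch and columns `participant_id`, `epoch_index`, `accel_mg`,
#' `day_index`, `hour_of_day`. Acceleration is the ENMO-style summary in
#' milligravities; values above 2000 mg are capped at 2000 on ingest, values
#' below 3 mg are classified as sleep. Two exposures are derived per
#' participant: physical-activity volume (the mean over *all* epochs,
#' including sleep-level ones) and the sleep-excluded intensity histogram of
#' relative frequencies over a [bin_scheme()].
#'
#' @name accel_features
NULL

check_epochs <- function(epochs) {
  need <- c("participant_id", "accel_mg")
  miss <- setdiff(need, names(epochs))
  if (length(miss))
    stop("epoch data lacks column(s): ", paste(miss, collapse = ", "))
  if (any(epochs$accel_mg < 0, na.rm = TRUE))
    stop("accel_mg must be nonnegative")
  epochs
}

cap_epochs <- function(accel_mg) pmin(accel_mg, 2000)

#' Wear-time validity
#'
#' A participant's recording is valid when at least three distinct days have
#' data and, pooling across days, every one of the 24 hour-of-day slots is
#' covered. An empty series is invalid, not an error.
#'
#' @param series Epoch data frame for one participant with `day_index` and
#'   `hour_of_day` columns.
#' @return `TRUE` or `FALSE`.
#' @export
validate_wear <- function(series) {
  if (is.null(series) || nrow(series) == 0) return(FALSE)
  if (!all(c("day_index", "hour_of_day") %in% names(series)))
    stop("validate_wear needs day_index and hour_of_day columns")
  length(unique(series$day_index)) >= 3 &&
    length(unique(series$hour_of_day %% 24)) == 24
}

#' Physical-activity volume
#'
#' Mean acceleration over all epochs, sleep-level epochs included: sleep is
#' excluded from the histogram, never from the volume.
#'
#' @param series Epoch data frame for one participant.
#' @return Volume in mg.
#' @export
compute_volume <- function(series) {
  check_epochs(series)
  if (nrow(series) == 0) stop("cannot compute volume of an empty series")
  mean(cap_epochs(series$accel_mg))
}

#' Sleep-excluded intensity histogram
#'
#' Bins the epochs of one participant into relative frequencies over a
#' [bin_scheme()]. Epochs below 3 mg count toward `sleep_fraction` only;
#' the `p` vector is normalized over epochs at or above 3 mg. If no epoch
#' reaches 3 mg the histogram is flagged empty and `p` is all `NA`.
#'
#' @param series Epoch data frame for one participant.
#' @param bins A `bin_scheme`.
#' @return An object of class `intensity_histogram`: list with
#'   `participant_id`, `p` (named by bin label), `volume`, `sleep_fraction`,
#'   `valid_wear`, `empty`, and the `bins` used.
#' @examples
#' s <- data.frame(participant_id = 1, epoch_index = 1:4,
#'                 accel_mg = c(2, 10, 10, 200),
#'                 day_index = 1, hour_of_day = 0)
#' h <- build_histogram(s, bin_scheme(edges = c(3, 60, 300, 500, 2000)))
#' h$p
#' @export
build_histogram <- function(series, bins = bin_scheme()) {
  check_epochs(series)
  stopifnot(inherits(bins, "bin_scheme"))
  a <- cap_epochs(series$accel_mg)
  n_all <- length(a)
  if (n_all == 0) stop("empty epoch series")
  awake <- a[a >= 3]
  sleep_fraction <- 1 - length(awake) / n_all
  K <- n_bins(bins)
  if (length(awake) == 0) {
    p <- rep(NA_real_, K)
    empty <- TRUE
  } else {
    cuts <- cut(awake, breaks = bins$edges, right = FALSE,
                include.lowest = TRUE)
    p <- as.numeric(table(cuts)) / length(awake)
    empty <- FALSE
  }
  names(p) <- bins$labels
  vw <- if (all(c("day_index", "hour_of_day") %in% names(series)))
    validate_wear(series) else NA
  structure(list(participant_id = series$participant_id[1], p = p,
                 volume = mean(a), sleep_fraction = sleep_fraction,
                 valid_wear = vw, empty = empty, bins = bins),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat("Intensity histogram for participant", as.character(x$participant_id),
      "\n  volume:", round(x$volume, 2), "mg; sleep fraction:",
      round(x$sleep_fraction, 3), "\n")
  if (x$empty) cat("  <empty: no epochs at or above 3 mg>\n")
  invisible(x)
}

#' Histogram table for a whole cohort
#'
#' Applies [build_histogram()] per participant and stacks the results into
#' one data frame: `participant_id`, `volume`, `sleep_fraction`,
#' `valid_wear`, then one `p_<lo>_<hi>` column per bin.
#'
#' @param epochs Epoch data frame for several participants.
#' @param bins A `bin_scheme`.
#' @return A data frame with attribute `"bins"`.
#' @export
build_histograms <- function(epochs, bins = bin_scheme()) {
  check_epochs(epochs)
  ids <- unique(epochs$participant_id)
  rows <- lapply(split(epochs, factor(epochs$participant_id, levels = ids)),
                 function(s) {
    h <- build_histogram(s, bins)
    c(volume = h$volume, sleep_fraction = h$sleep_fraction,
      valid_wear = as.numeric(isTRUE(h$valid_wear)), h$p)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(participant_id = ids, out)
  rownames(out) <- NULL
  attr(out, "bins") <- bins
  out
}

hist_p_matrix <- function(hist_table, bins) {
  m <- as.matrix(hist_table[, bins$labels, drop = FALSE])
  rownames(m) <- hist_table$participant_id
  m
}

#' Average daily minutes in an intensity range
#'
#' Converts histogram mass in `[lo_mg, hi_mg)` into average minutes per day,
#' scaling by the awake (non-sleep) fraction of the 1440-minute day:
#' `(1 - sleep_fraction) * sum(p_k in range) * 1440`. Sleep minutes per day
#' are `sleep_fraction * 1440`. The range must align with bin edges.
#'
#' @param hist An `intensity_histogram`, or a histogram table from
#'   [build_histograms()] (then a vector is returned).
#' @param lo_mg,hi_mg Range in mg; `hi_mg = Inf` means the top edge (2000).
#' @param bins Bin scheme; defaults to the one attached to `hist`.
#' @return Minutes per day (scalar or vector).
#' @export
minutes_in_range <- function(hist, lo_mg, hi_mg, bins = NULL) {
  if (inherits(hist, "intensity_histogram")) {
    bins <- hist$bins
    p <- matrix(hist$p, nrow = 1)
    sf <- hist$sleep_fraction
  } else {
    if (is.null(bins)) bins <- attr(hist, "bins")
    if (is.null(bins)) stop("supply a bin_scheme for a histogram table")
    p <- hist_p_matrix(hist, bins)
    sf <- hist$sleep_fraction
  }
  edges <- bins$edges
  if (identical(hi_mg, Inf)) hi_mg <- max(edges)
  ilo <- match(lo_mg, edges)
  ihi <- match(hi_mg, edges)
  if (is.na(ilo) || is.na(ihi) || ilo >= ihi) {
    near <- function(v) edges[which.min(abs(edges - v))]
    stop(sprintf(
      "range [%s, %s) does not align with bin edges; nearest edges are %s and %s",
      lo_mg, hi_mg, near(lo_mg), near(hi_mg)))
  }
  sel <- seq(ilo, ihi - 1)
  drop((1 - sf) * (p[, sel, drop = FALSE] %*% rep(1, length(sel))) * 1440)
}

#' @rdname minutes_in_range
#' @export
sleep_minutes <- function(hist) {
  sf <- if (inherits(hist, "intensity_histogram")) hist$sleep_fraction
        else hist$sleep_fraction
  sf * 1440
}

#' Time budget in walking-equivalent categories
#'
#' Average daily time in the standard reporting categories: sleep (<3 mg),
#' sedentary (3--60 mg), slow-walking equivalent (60--125 mg),
#' moderate-walking equivalent (125--300 mg) and brisk-walking equivalent or
#' higher (300+ mg). Sleep and sedentary are reported in hours, the rest in
#' minutes.
#'
#' @inheritParams minutes_in_range
#' @return A data frame with columns `sleep_h`, `sedentary_h`, `slow_min`,
#'   `moderate_min`, `brisk_min`.
#' @export
time_budget <- function(hist, bins = NULL) {
  data.frame(
    sleep_h = sleep_minutes(hist) / 60,
    sedentary_h = minutes_in_range(hist, 3, 60, bins) / 60,
    slow_min = minutes_in_range(hist, 60, 125, bins),
    moderate_min = minutes_in_range(hist, 125, 300, bins),
    brisk_min = minutes_in_range(hist, 300, Inf, bins))
}
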
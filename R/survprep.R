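#' Cohort assembly: eligibility, censoring, Kaplan-Meier summaries
#'
#' Analysis cohorts are complete-case: participants flagged with prevalent
#' cancer, coronary heart disease or stroke at accelerometer collection are
#' removed (the flags are precomputed booleans; hospital-record parsing
#' happens upstream), as is any row with a missing covariate. Exclusion
#' counts by reason are recorded on the returned table.
#'
#' @name survival_prep
NULL

eligibility_flags <- c("prevalent_cancer", "prevalent_chd",
                       "prevalent_stroke")

#' Apply eligibility and complete-case filtering
#'
#' Rows may carry either precomputed `time_years`/`event` (e.g. simulated
#' cohorts) or `accel_date`/`death_date` columns, in which case follow-up
#' is computed to `censor_date` (deaths on the censor date still count:
#' censoring happens at end of day).
#'
#' @param rows Cohort data frame. Missing flag columns are treated as
#'   all-zero.
#' @param censor_date Optional `Date`; required when follow-up must be
#'   computed from dates, and must postdate every accelerometer date.
#' @param covariates Columns required complete (default: the adjusted
#'   model's covariate set, when present).
#' @return The retained rows, with attributes `"exclusions"` (data frame of
#'   counts by reason) and any `"bins"` attribute preserved.
#' @export
apply_eligibility <- function(rows, censor_date = NULL,
                              covariates = NULL) {
  n0 <- nrow(rows)
  bins <- attr(rows, "bins")
  if (!is.null(censor_date)) {
    if (!"accel_date" %in% names(rows))
      stop("censor_date given but rows have no accel_date column")
    censor_date <- as.Date(censor_date)
    if (censor_date <= max(as.Date(rows$accel_date)))
      stop("censor_date precedes (or equals) the last accelerometer date")
    death <- as.Date(rows$death_date)
    died <- !is.na(death) & death <= censor_date
    end <- as.Date(ifelse(died, death, censor_date), origin = "1970-01-01")
    rows$time_years <- as.numeric(end - as.Date(rows$accel_date)) / 365.25
    rows$event <- as.integer(died)
  }
  if (!all(c("time_years", "event") %in% names(rows)))
    stop("rows need time_years and event (or dates plus censor_date)")
  if (is.null(covariates))
    covariates <- intersect(covariate_columns, names(rows))

  reasons <- character(0)
  drop <- rep(FALSE, n0)
  mark <- function(sel, why) {
    new <- sel & !drop
    drop <<- drop | sel
    reasons <<- c(reasons, stats::setNames(sum(new), why))
    invisible(NULL)
  }
  for (fl in eligibility_flags)
    if (fl %in% names(rows))
      mark(!is.na(rows[[fl]]) & rows[[fl]] > 0, fl)
  if (length(covariates))
    mark(!stats::complete.cases(rows[, covariates, drop = FALSE]),
         "missing_covariate")
  mark(is.na(rows$time_years) | rows$time_years <= 0 | is.na(rows$event),
       "invalid_follow_up")
  out <- rows[!drop, , drop = FALSE]
  excl <- data.frame(reason = names(reasons), n = as.integer(reasons),
                     row.names = NULL)
  attr(out, "exclusions") <- rbind(
    excl, data.frame(reason = "retained", n = nrow(out)))
  attr(out, "bins") <- bins
  out
}

#' @rdname apply_eligibility
#' @param cohort A filtered cohort.
#' @export
exclusion_log <- function(cohort) attr(cohort, "exclusions")

#' Truncate follow-up at an earlier horizon
#'
#' Sensitivity-analysis helper mirroring a pre-pandemic censor date for
#' simulated cohorts: events after `years` are recoded as censored at
#' `years`.
#'
#' @param cohort Cohort with `time_years` and `event`.
#' @param years New administrative horizon.
#' @export
truncate_followup <- function(cohort, years) {
  stopifnot(years > 0)
  late <- cohort$time_years > years
  cohort$event[late] <- 0L
  cohort$time_years <- pmin(cohort$time_years, years)
  cohort
}

#' Kaplan-Meier curves and log-rank test by volume quartile
#'
#' Cuts the cohort at the empirical volume quartiles (ties to the lower
#' quartile), estimates per-quartile Kaplan-Meier curves with Greenwood
#' 95% bands and runs the 3-df log-rank test. With no events the log-rank
#' statistic is undefined and flagged rather than computed.
#'
#' @param cohort Cohort with `time_years`, `event`, `volume`.
#' @return List of class `km_quartiles`: `curves` (data frame: quartile,
#'   time, survival, lower, upper, n_risk, n_event), `logrank` (chisq, df,
#'   p, or NULL with `no_events = TRUE`), `quartile_breaks`, `counts`.
#' @export
km_by_quartile <- function(cohort) {
  stopifnot(all(c("time_years", "event", "volume") %in% names(cohort)))
  br <- stats::quantile(cohort$volume, 0:4 / 4, names = FALSE)
  if (any(duplicated(br))) stop("degenerate volume quartile breaks")
  q <- cut(cohort$volume, breaks = br, include.lowest = TRUE,
           labels = paste0("Q", 1:4))
  if (any(table(q) == 0)) stop("a volume quartile has zero subjects")
  sf <- survival::survfit(
    survival::Surv(time_years, event) ~ q,
    data = data.frame(time_years = cohort$time_years,
                      event = cohort$event, q = q),
    conf.type = "log")   # Greenwood variance, log-transformed bands
  strata_names <- rep(sub("^q=", "", names(sf$strata)), sf$strata)
  curves <- data.frame(quartile = strata_names, time = sf$time,
                       survival = sf$surv, lower = sf$lower,
                       upper = sf$upper, n_risk = sf$n.risk,
                       n_event = sf$n.event)
  no_events <- sum(cohort$event) == 0
  logrank <- NULL
  if (!no_events) {
    sd <- survival::survdiff(
      survival::Surv(time_years, event) ~ q,
      data = data.frame(time_years = cohort$time_years,
                        event = cohort$event, q = q))
    df <- length(sd$n) - 1
    logrank <- list(chisq = sd$chisq, df = df,
                    p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
  }
  structure(list(curves = curves, logrank = logrank, no_events = no_events,
                 quartile_breaks = br, counts = as.integer(table(q))),
            class = "km_quartiles")
}

#' @export
print.km_quartiles <- function(x, ...) {
  cat("Kaplan-Meier by PA volume quartile\n")
  cat("  breaks (mg):", paste(round(x$quartile_breaks, 1), collapse = ", "),
      "\n  subjects:", paste(x$counts, collapse = ", "), "\n")
  if (x$no_events) cat("  no events: log-rank undefined\n")
  else cat(sprintf("  log-rank chi-square = %.2f on %d df, p = %.3g\n",
                   x$logrank$chisq, x$logrank$df, x$logrank$p))
  invisible(x)
}
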
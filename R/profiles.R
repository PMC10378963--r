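#' Risk profiles: realistic intensity patterns and their hazard ratios
#'
#' A risk profile is a realistic intensity histogram summarizing a
#' relatively high-, average- or low-risk distribution *shape* at a given
#' volume level. Within each volume stratum participants are ranked by
#' their fitted intensity-term contribution; the high-risk profile is the
#' mean histogram of the top decile, the low-risk profile the mean of the
#' bottom decile, and the average profile the mean of the middle quintile.
#' Averaging observed histograms keeps profiles inside the data cloud --
#' they are never model-optimal extremes.
#'
#' Profile hazard ratios carry simulation-based 95% credible intervals:
#' coefficient draws from the Gaussian large-sample posterior
#' `N(beta_hat, V_beta)` are pushed through the profile contrast.
#'
#' @name risk_profiles
NULL

#' Fitted weight function at the bin representatives
#' @param fit A `funcox` fit.
#' @return Numeric vector `w_hat(z_k)`.
#' @export
fitted_weights <- function(fit) {
  stopifnot(inherits(fit, "funcox"))
  drop(eval_basis(fit$int_basis, fit$z) %*% block_beta(fit, "int"))
}

profile_p <- function(x, bins) {
  if (inherits(x, "intensity_histogram")) {
    p <- x$p
  } else if (is.data.frame(x)) {
    p <- as.numeric(as.matrix(x[, bins$labels, drop = FALSE]))
  } else {
    p <- as.numeric(x)
  }
  if (length(p) != n_bins(bins))
    stop("profile has ", length(p), " bins; the fit uses ", n_bins(bins))
  p
}

#' Intensity-term log-hazard contribution
#'
#' `sum_k w_hat(z_k) p_k` for one or many histograms: the participant's
#' log-hazard contribution from the intensity distribution alone.
#'
#' @param fit A `funcox` fit.
#' @param hist An `intensity_histogram`, a histogram table/cohort data
#'   frame, or a matrix of relative frequencies.
#' @return Numeric vector.
#' @export
intensity_contribution <- function(fit, hist) {
  stopifnot(inherits(fit, "funcox"))
  bins <- fit$bins
  P <- if (inherits(hist, "intensity_histogram"))
    matrix(profile_p(hist, bins), nrow = 1)
  else if (is.data.frame(hist)) as.matrix(hist[, bins$labels, drop = FALSE])
  else if (is.matrix(hist)) hist
  else matrix(as.numeric(hist), nrow = 1)
  if (ncol(P) != n_bins(bins))
    stop("histogram bins do not match the fitted bin scheme")
  unname(drop(functional_design_row(P, fit$int_basis, fit$z) %*%
                block_beta(fit, "int")))
}

#' Construct high/average/low-risk profiles within volume strata
#'
#' @param fit A `funcox` fit.
#' @param cohort The cohort the fit was (or could have been) computed on;
#'   needs `volume` and the histogram columns.
#' @param n_strata Number of volume strata (default quartiles).
#' @param hi_cut,lo_cut Contribution quantiles bounding the high-risk
#'   (top `1 - hi_cut`) and low-risk (bottom `lo_cut`) membership.
#' @param mid Quantile window for the average profile.
#' @param min_stratum Minimum participants per stratum.
#' @return Data frame of class `risk_profiles`: one row per (stratum,
#'   label) plus `"overall"` average rows, with mean volume, sleep
#'   fraction, histogram columns and the time-budget summary; bin scheme
#'   attached as attribute `"bins"`.
#' @export
construct_profiles <- function(fit, cohort, n_strata = 4,
                               hi_cut = 0.9, lo_cut = 0.1,
                               mid = c(0.4, 0.6), min_stratum = 100) {
  stopifnot(inherits(fit, "funcox"))
  bins <- fit$bins
  P <- hist_p_matrix(cohort, bins)
  ok <- rowSums(is.na(P)) == 0
  cohort <- cohort[ok, , drop = FALSE]
  P <- P[ok, , drop = FALSE]
  br <- stats::quantile(cohort$volume, 0:n_strata / n_strata,
                        names = FALSE)
  strat <- cut(cohort$volume, breaks = br, include.lowest = TRUE,
               labels = paste0("Q", seq_len(n_strata)))
  if (any(table(strat) < min_stratum))
    stop("every stratum needs at least ", min_stratum, " participants")
  contrib <- intensity_contribution(fit, P)

  mean_profile <- function(sel, label, stratum) {
    p <- colMeans(P[sel, , drop = FALSE])
    d <- data.frame(stratum = stratum, label = label,
                    n = sum(sel),
                    mean_volume = mean(cohort$volume[sel]),
                    sleep_fraction = mean(cohort$sleep_fraction[sel]))
    cbind(d, as.data.frame(as.list(p), col.names = bins$labels))
  }
  rows <- list()
  for (s in c("overall", levels(strat))) {
    sel <- if (s == "overall") rep(TRUE, nrow(P)) else strat == s
    cs <- contrib[sel]
    qs <- stats::quantile(cs, c(lo_cut, mid, hi_cut), names = FALSE)
    rows <- c(rows, list(
      mean_profile(sel & contrib >= qs[4], "high", s),
      mean_profile(sel & contrib >= qs[2] & contrib <= qs[3], "average", s),
      mean_profile(sel & contrib <= qs[1], "low", s)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- cbind(out, time_budget(out, bins))
  attr(out, "bins") <- bins
  attr(out, "quartile_breaks") <- br
  class(out) <- c("risk_profiles", class(out))
  out
}

#' Extract one profile row
#' @param profiles A [construct_profiles()] result.
#' @param stratum `"overall"` or a stratum label such as `"Q1"`.
#' @param label `"high"`, `"average"` or `"low"`.
#' @return The single matching profile row.
#' @export
get_profile <- function(profiles, stratum, label) {
  r <- profiles[profiles$stratum == stratum & profiles$label == label, ]
  if (nrow(r) != 1) stop("no unique profile (", stratum, ", ", label, ")")
  r
}

## joint posterior draws of the coefficient vector
draw_beta <- function(fit, n_draws, seed) {
  V <- (fit$Vbeta + t(fit$Vbeta)) / 2
  R <- tryCatch(chol(V), error = function(e)
    stop("posterior covariance is not positive definite"))
  with_seed(seed, {
    Zm <- matrix(stats::rnorm(n_draws * ncol(R)), n_draws)
    sweep(Zm %*% R, 2, fit$coefficients, "+")
  })
}

#' Profile hazard ratio with simulation-based credible interval
#'
#' HR of profile `a` versus profile `b` through the intensity term only:
#' per posterior draw, `exp(sum_k w(z_k) (p_a - p_b))`; the point estimate
#' is the posterior median and the interval the 2.5/97.5 percentiles.
#'
#' @param fit A `funcox` fit.
#' @param profile_a,profile_b Histograms (profile rows, histograms or `p`
#'   vectors) sharing the fit's bins.
#' @param n_draws Posterior draws (default 10,000).
#' @param seed Seed; defaults to the fit spec's seed.
#' @return List of class `profile_hr`: `hr`, `lo`, `hi`, `plugin` (the
#'   point evaluation at `beta_hat`), `n_draws`, `seed`.
#' @export
profile_hr <- function(fit, profile_a, profile_b, n_draws = 10000,
                       seed = NULL) {
  stopifnot(inherits(fit, "funcox"))
  if (is.null(seed)) seed <- fit$spec$seed
  bins <- fit$bins
  dp <- profile_p(profile_a, bins) - profile_p(profile_b, bins)
  cvec <- drop(functional_design_row(matrix(dp, 1), fit$int_basis, fit$z))
  idx <- fit$idx$int
  mu <- sum(cvec * fit$coefficients[idx])
  V <- (fit$Vbeta[idx, idx] + t(fit$Vbeta[idx, idx])) / 2
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("posterior covariance is not positive semidefinite")
  R <- chol(V + diag(1e-12 * max(diag(V)), ncol(V)))
  # draw the whole coefficient block so that swapping the profiles negates
  # the contrast draw-by-draw: HR(a,b) * HR(b,a) = 1 per draw
  draws <- with_seed(seed, {
    Zm <- matrix(stats::rnorm(n_draws * ncol(R)), n_draws)
    mu + drop(Zm %*% (R %*% cvec))   # beta = beta_hat + t(R) z, V = R'R
  })
  # quantiles on the log scale keep HR(a,b) * HR(b,a) = 1 exact even
  # through the order-statistic interpolation
  qs <- exp(stats::quantile(draws, c(0.5, 0.025, 0.975), names = FALSE))
  structure(list(hr = qs[1], lo = qs[2], hi = qs[3], plugin = exp(mu),
                 n_draws = n_draws, seed = seed),
            class = "profile_hr")
}

#' @export
print.profile_hr <- function(x, ...) {
  cat(sprintf("profile HR %.3f (95%% CrI %.3f, %.3f) [%d draws, seed %d]\n",
              x$hr, x$lo, x$hi, x$n_draws, x$seed))
  invisible(x)
}

#' Profile hazard-ratio curves by volume quartile
#'
#' For each volume quartile, profiles interpolating low -> average -> high
#' risk are compared to a single reference: a participant at the overall
#' median volume with the overall average profile. The contrast combines
#' the volume-smooth difference (quartile mean volume vs reference volume)
#' with the intensity-term difference, with credible intervals from joint
#' posterior draws.
#'
#' @param fit A `funcox` fit.
#' @param cohort Cohort data frame (for profile construction).
#' @param profiles Optional precomputed [construct_profiles()] result.
#' @param n_grid Interpolation points from low to high risk.
#' @param n_draws,seed Posterior simulation controls.
#' @return Data frame: stratum, s (0 = low, 0.5 = average, 1 = high),
#'   volume, hr, lo, hi.
#' @export
profile_hr_by_volume <- function(fit, cohort, profiles = NULL,
                                 n_grid = 9, n_draws = 10000,
                                 seed = NULL) {
  stopifnot(inherits(fit, "funcox"))
  if (is.null(seed)) seed <- fit$spec$seed
  if (is.null(profiles)) profiles <- construct_profiles(fit, cohort)
  bins <- fit$bins
  ref_vol <- stats::median(cohort$volume, na.rm = TRUE)
  p_ref <- profile_p(get_profile(profiles, "overall", "average"), bins)
  idx <- c(fit$idx$vol, fit$idx$int)
  Bv_ref <- eval_basis(fit$vol_basis, ref_vol)
  row_ref <- cbind(Bv_ref,
                   functional_design_row(matrix(p_ref, 1), fit$int_basis,
                                         fit$z))
  draws <- draw_beta(fit, n_draws, seed)[, idx, drop = FALSE]
  svals <- seq(0, 1, length.out = n_grid)
  strata <- unique(profiles$stratum[profiles$stratum != "overall"])
  out <- lapply(strata, function(st) {
    p_lo <- profile_p(get_profile(profiles, st, "low"), bins)
    p_av <- profile_p(get_profile(profiles, st, "average"), bins)
    p_hi <- profile_p(get_profile(profiles, st, "high"), bins)
    vol_st <- get_profile(profiles, st, "average")$mean_volume
    Bv <- eval_basis(fit$vol_basis, vol_st)
    rows <- lapply(svals, function(s) {
      p_s <- if (s <= 0.5) (1 - 2 * s) * p_lo + 2 * s * p_av
             else (2 - 2 * s) * p_av + (2 * s - 1) * p_hi
      row_s <- cbind(Bv, functional_design_row(matrix(p_s, 1),
                                               fit$int_basis, fit$z))
      cvec <- drop(row_s - row_ref)
      qs <- exp(stats::quantile(draws %*% cvec, c(0.5, 0.025, 0.975),
                                names = FALSE))
      data.frame(stratum = st, s = s, volume = vol_st,
                 hr = qs[1], lo = qs[2], hi = qs[3])
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
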
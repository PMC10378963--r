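#' Reproducible analysis pipeline
#'
#' `run_pipeline()` chains the stages -- simulate (optional), features,
#' cohort prep, unadjusted and adjusted fits, curve/HR tables, risk
#' profiles, plots -- writing every artifact plus a JSON manifest recording
#' the configuration, seeds and output checksums, so a rerun with the same
#' config is byte-identical.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param cohort_csv Optional path to an existing cohort CSV; when `NULL` a
#'   cohort is simulated from `sim`.
#' @param epochs_csv Optional epoch-level CSV to run feature extraction on
#'   (features are merged into the cohort by participant id).
#' @param sim A [sim_config()] used when simulating.
#' @param bins Bin scheme.
#' @param spec_adjusted,spec_unadjusted [model_spec()]s for the two fits.
#' @param censor_years Optional earlier follow-up horizon (sensitivity).
#' @param n_draws Posterior draws for profile HRs.
#' @param seed Master seed for posterior simulation.
#' @param plots Render PNG plots.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir = "accelcox-run",
                       cohort_csv = NULL, epochs_csv = NULL,
                       sim = sim_config(),
                       bins = bin_scheme(),
                       spec_unadjusted = model_spec(adjusted = FALSE),
                       spec_adjusted = model_spec(adjusted = TRUE),
                       censor_years = NULL,
                       n_draws = 10000, seed = 1L, plots = TRUE) {
  structure(as.list(environment()), class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the [run_config()] arguments; `sim`
#' and model specs are given as nested maps of their constructor
#' arguments.
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("out_dir", "cohort_csv", "epochs_csv", "censor_years",
              "n_draws", "seed", "plots"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$sim)) args$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$spec_adjusted))
    args$spec_adjusted <- do.call(model_spec, y$spec_adjusted)
  if (!is.null(y$spec_unadjusted))
    args$spec_unadjusted <- do.call(
      model_spec, c(y$spec_unadjusted, list(adjusted = FALSE)))
  do.call(run_config, args)
}

#' Run the full pipeline
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest list; all artifacts are written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (f in c(config$cohort_csv, config$epochs_csv))
    if (!is.null(f) && !file.exists(f))
      stop("input file does not exist: ", f)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(...) file.path(config$out_dir, ...)
  bins <- config$bins
  artifacts <- character(0)
  emit <- function(x, name) {
    write_csv_plain(x, outp(name))
    artifacts <<- c(artifacts, name)
    invisible(NULL)
  }

  ## stage: cohort (simulate or load)
  truth <- NULL
  if (is.null(config$cohort_csv)) {
    sim <- generate_cohort(config$sim)
    cohort <- sim$cohort
    bins <- sim$bins
    truth <- sim$truth
    emit(cohort, "cohort.csv")
  } else {
    cohort <- read_cohort_csv(config$cohort_csv, bins)
  }

  ## stage: features from epochs, if supplied
  if (!is.null(config$epochs_csv)) {
    epochs <- read_epochs_csv(config$epochs_csv)
    feats <- build_histograms(epochs, bins)
    emit(feats, "histograms.csv")
    keep <- setdiff(names(cohort),
                    c("volume", "sleep_fraction", bins$labels))
    cohort <- merge(cohort[, keep], feats[feats$valid_wear > 0, ],
                    by = "participant_id")
    attr(cohort, "bins") <- bins
  }

  ## stage: prep
  if (!is.null(config$censor_years))
    cohort <- truncate_followup(cohort, config$censor_years)
  cohort <- apply_eligibility(cohort)
  emit(exclusion_log(cohort), "exclusions.csv")
  km <- km_by_quartile(cohort)
  emit(km$curves, "km_curves.csv")

  ## stage: fits and summaries
  fit_u <- fit_funcox(cohort, config$spec_unadjusted, bins)
  fit_a <- fit_funcox(cohort, config$spec_adjusted, bins)
  write_model(fit_u, outp("model_unadjusted"))
  write_model(fit_a, outp("model_adjusted"))
  artifacts <- c(artifacts, "model_unadjusted.rds", "model_unadjusted.json",
                 "model_adjusted.rds", "model_adjusted.json")
  emit(covariate_hr_table(fit_a), "covariate_hr.csv")
  seg <- rbind(cbind(model = "unadjusted", hr_per_mg_segment(fit_u)),
               cbind(model = "adjusted", hr_per_mg_segment(fit_a)))
  emit(seg, "segment_hr.csv")
  emit(volume_curve(fit_a), "volume_curve.csv")
  emit(intensity_weight_curve(fit_a), "intensity_weight_curve.csv")

  ## stage: risk profiles
  profiles <- construct_profiles(fit_a, cohort)
  emit(as.data.frame(profiles), "profiles.csv")
  emit(profiles[, c("stratum", "label", "sleep_h", "sedentary_h",
                    "slow_min", "moderate_min", "brisk_min")],
       "time_budget.csv")
  contrasts <- list(c("high", "average"), c("average", "low"),
                    c("high", "low"))
  ph <- do.call(rbind, lapply(
    unique(profiles$stratum), function(st) do.call(rbind, lapply(
      contrasts, function(cc) {
        h <- profile_hr(fit_a, get_profile(profiles, st, cc[1]),
                        get_profile(profiles, st, cc[2]),
                        n_draws = config$n_draws, seed = config$seed)
        data.frame(stratum = st, contrast = paste(cc, collapse = "_vs_"),
                   hr = h$hr, lo = h$lo, hi = h$hi)
      }))))
  emit(ph, "profile_hr.csv")
  phv <- profile_hr_by_volume(fit_a, cohort, profiles,
                              n_draws = config$n_draws, seed = config$seed)
  emit(phv, "profile_hr_by_volume.csv")

  ## stage: plots
  if (isTRUE(config$plots)) {
    save_plot <- function(p, name) {
      ggplot2::ggsave(outp(name), p, width = 7, height = 5, dpi = 150)
      artifacts <<- c(artifacts, name)
    }
    save_plot(plot_km(km), "km.png")
    save_plot(plot_volume_curve(volume_curve(fit_a)), "volume_curve.png")
    save_plot(plot_intensity_weight(intensity_weight_curve(fit_a)),
              "intensity_weight.png")
    save_plot(plot_profile_hr(phv), "profile_hr.png")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("accelcox")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    sim_seed = if (is.null(config$cohort_csv)) config$sim$seed,
    n = nrow(cohort), n_events = sum(cohort$event),
    logrank_p = if (!km$no_events) km$logrank$p,
    artifacts = artifacts,
    md5 = as.list(tools::md5sum(file.path(config$out_dir, artifacts))))
  jsonlite::write_json(manifest, outp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Sensitivity analysis over spline dimensions and censoring
#'
#' Refits the model over a grid of basis dimensions and optional earlier
#' censoring horizons, reporting volume-segment HRs and the overall
#' high-vs-low profile HR side by side. Failures in a grid cell are
#' recorded and do not stop the run.
#'
#' @param cohort Analysis cohort.
#' @param bins Bin scheme.
#' @param k_vol,k_int Vectors of basis dimensions to cross.
#' @param censor_years Optional vector of follow-up horizons (`NA` = full).
#' @param adjusted Fit the adjusted model.
#' @param n_draws,seed Posterior simulation controls.
#' @return Data frame: one row per grid cell with segment HRs, the
#'   high-vs-low profile HR, effective dfs, event count and an `error`
#'   column (NA on success).
#' @export
sensitivity_runner <- function(cohort, bins = attr(cohort, "bins"),
                               k_vol = c(8, 10, 14), k_int = c(8, 10, 14),
                               censor_years = NA, adjusted = TRUE,
                               n_draws = 2000, seed = 1L) {
  grid <- expand.grid(k_vol = k_vol, k_int = k_int,
                      censor_years = censor_years)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    base <- data.frame(k_vol = g$k_vol, k_int = g$k_int,
                       censor_years = g$censor_years)
    tryCatch({
      co <- if (is.na(g$censor_years)) cohort
            else truncate_followup(cohort, g$censor_years)
      fit <- fit_funcox(co, model_spec(adjusted = adjusted,
                                       k_vol = g$k_vol, k_int = g$k_int,
                                       seed = seed), bins)
      seg <- hr_per_mg_segment(fit)
      pr <- construct_profiles(fit, co)
      hl <- profile_hr(fit, get_profile(pr, "overall", "high"),
                       get_profile(pr, "overall", "low"),
                       n_draws = n_draws, seed = seed)
      segs <- stats::setNames(as.list(seg$hr),
                              paste0("hr_seg_", seq_len(nrow(seg))))
      cbind(base, as.data.frame(segs),
            data.frame(hr_high_vs_low = hl$hr,
                       edf_vol = fit$edf[["vol"]],
                       edf_int = fit$edf[["int"]],
                       n_events = fit$n_events,
                       error = NA_character_))
    }, error = function(e) {
      cbind(base, data.frame(error = conditionMessage(e)))
    })
  })
  nm <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (m in setdiff(nm, names(r))) r[[m]] <- NA
    r[, nm]
  })
  do.call(rbind, rows)
}
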
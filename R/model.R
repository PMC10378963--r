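#' Model specification for the smooth additive Cox model
#'
#' The unadjusted model contains the volume smooth and the constrained
#' functional intensity term only; the adjusted model adds the parametric
#' confounders (sex, age, education, Townsend index, self-reported poor
#' health, longstanding illness, current smoking, exceeding alcohol
#' guidelines, BMI category) and an assessment-center random effect,
#' realized as an i.i.d. Gaussian ridge penalty with its own smoothing
#' parameter.
#'
#' @param adjusted Logical; include confounders and the center effect.
#' @param k_vol,k_int Basis dimensions of the volume smooth and the
#'   intensity weight smooth (defaults 10; sensitivity analyses vary both).
#' @param lambda Optional named numeric vector of fixed smoothing
#'   parameters (`vol`, `int`, and `center` when adjusted). `NULL` selects
#'   them by LAML.
#' @param maxit,tol Newton iteration cap and gradient-norm tolerance.
#' @param seed Seed recorded with the fit (used by downstream posterior
#'   simulation defaults).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(adjusted = TRUE, k_vol = 10, k_int = 10,
                       lambda = NULL, maxit = 200, tol = 1e-6, seed = 1L) {
  if (!is.null(lambda)) {
    need <- if (adjusted) c("vol", "int", "center") else c("vol", "int")
    if (!all(need %in% names(lambda)))
      stop("fixed lambda must be named: ", paste(need, collapse = ", "))
    if (any(lambda <= 0)) stop("lambda must be positive")
  }
  structure(list(adjusted = adjusted, k_vol = k_vol, k_int = k_int,
                 lambda = lambda, maxit = maxit, tol = tol,
                 seed = as.integer(seed)),
            class = "model_spec")
}

covariate_columns <- c("sex_male", "age_years", "degree_educated",
                       "townsend", "poor_health", "longstanding_illness",
                       "current_smoker", "exceeds_alcohol", "bmi_category")

#' Fit the smooth additive Cox model
#'
#' Maximizes the penalized Breslow partial likelihood of a Cox model whose
#' log-hazard adds (i) a thin-plate smooth of PA volume (sum-to-zero
#' constrained, linear component retained), (ii) the functional intensity
#' term: the histogram's relative frequencies weighted by a thin-plate
#' smooth weight function whose constant *and* linear components are
#' removed, so the term is orthogonal to mean intensity, (iii) parametric
#' confounders and (iv) a ridge-penalized assessment-center effect (both
#' only when `adjusted`). Smoothing parameters are selected by LAML unless
#' fixed in the [model_spec()]. The posterior covariance `V_beta` is the inverse
#' penalized information at the optimum, giving the usual Bayesian
#' credible-interval interpretation of penalized-spline uncertainty.
#'
#' @param cohort Data frame with `time_years`, `event`, `volume`, histogram
#'   columns matching `bins`, and (if adjusted) the confounder columns and
#'   `center_id`.
#' @param spec A [model_spec()].
#' @param bins Bin scheme of the histogram columns; defaults to the
#'   `"bins"` attribute of `cohort`.
#' @return Object of class `funcox`.
#' @export
fit_funcox <- function(cohort, spec = model_spec(), bins = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(bins)) bins <- attr(cohort, "bins")
  if (is.null(bins)) stop("supply the bin scheme of the histogram columns")
  need <- c("time_years", "event", "volume", bins$labels)
  if (spec$adjusted) need <- c(need, covariate_columns, "center_id")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks column(s): ",
                         paste(miss, collapse = ", "))
  P <- hist_p_matrix(cohort, bins)
  keep <- stats::complete.cases(cohort[, need]) & rowSums(is.na(P)) == 0
  if (any(!keep)) {
    cohort <- cohort[keep, , drop = FALSE]
    P <- P[keep, , drop = FALSE]
  }
  n <- nrow(cohort)
  if (sum(cohort$event) < 10)
    stop("need at least 10 events to fit (got ", sum(cohort$event), ")")

  z <- bins$z
  vol <- cohort$volume
  vol_parent <- build_tprs(vol, basis_dim = spec$k_vol)
  vol_basis <- remove_span(vol_parent, "constant", at = vol)
  X_vol <- eval_basis(vol_basis, vol)
  int_parent <- build_tprs(z, basis_dim = spec$k_int)
  int_basis <- remove_span(int_parent, c("constant", "linear"), at = z)
  X_int <- functional_design_row(P, int_basis, z)

  parts <- list()
  blocks <- list()
  col_at <- 0
  add_part <- function(name, Xp, S = NULL, penalized = FALSE) {
    idx <- col_at + seq_len(ncol(Xp))
    parts[[name]] <<- Xp
    if (penalized) {
      bl <- block_logdet(S)
      blocks[[name]] <<- list(idx = idx, S = S, rank = bl$rank,
                              logdet = bl$logdet)
    }
    col_at <<- col_at + ncol(Xp)
    idx
  }
  idx_para <- NULL
  if (spec$adjusted) {
    X_para <- covariate_model_matrix(cohort)
    idx_para <- add_part("para", X_para)
  }
  idx_vol <- add_part("vol", X_vol, vol_basis$S, penalized = TRUE)
  idx_int <- add_part("int", X_int, int_basis$S, penalized = TRUE)
  idx_center <- NULL
  if (spec$adjusted) {
    center <- factor(cohort$center_id)
    X_c <- stats::model.matrix(~ 0 + center)
    colnames(X_c) <- levels(center)
    idx_center <- add_part("center", X_c, diag(ncol(X_c)),
                           penalized = TRUE)
  }
  X <- do.call(cbind, parts)
  qrX_rank <- qr(crossprod(X) +
                   assemble_penalty(ncol(X), blocks, rep(1, length(blocks))),
                 tol = 1e-12)$rank
  if (qrX_rank < ncol(X))
    stop("penalized design is rank deficient (rank ", qrX_rank, " < ",
         ncol(X), " columns)")

  prep <- cox_prep(cohort$time_years, cohort$event)
  if (is.null(spec$lambda)) {
    sel <- select_lambda(X, prep, blocks)
    rho <- sel$rho
    beta0 <- sel$beta
  } else {
    lam_names <- vapply(names(blocks), function(nm)
      switch(nm, vol = "vol", int = "int", center = "center"), character(1))
    rho <- log(spec$lambda[lam_names])
    beta0 <- NULL
  }
  lambda <- exp(rho)
  names(lambda) <- names(blocks)
  Spen <- assemble_penalty(ncol(X), blocks, lambda)
  fit <- newton_cox(X, prep, Spen, beta0 = beta0,
                    maxit = spec$maxit, tol = spec$tol)
  if (!fit$converged)
    warning(sprintf(
      "Newton iteration stopped at gradient norm %.2e after %d iterations",
      fit$gnorm, fit$iterations))
  Vb <- tryCatch(chol2inv(chol(fit$Hp)), error = function(e)
    solve(fit$Hp + diag(1e-8, ncol(X))))
  Vb <- (Vb + t(Vb)) / 2
  Fmat <- Vb %*% fit$H
  edf <- vapply(blocks, function(b) sum(diag(Fmat)[b$idx]), numeric(1))
  beta <- fit$beta
  names(beta) <- colnames(X)

  structure(list(
    coefficients = beta, Vbeta = Vb, lambda = lambda,
    edf = edf, loglik = fit$ll, penalized_ll = fit$penalized_ll,
    laml = laml_value(log(lambda), X, prep, blocks,
                      local({e <- new.env(); e$beta <- beta; e})),
    gradient_norm = fit$gnorm, iterations = fit$iterations,
    converged = fit$converged,
    idx = list(para = idx_para, vol = idx_vol, int = idx_int,
               center = idx_center),
    blocks = blocks,
    vol_basis = vol_basis, int_basis = int_basis,
    bins = bins, z = z,
    volume_range = range(vol),
    volume_quartiles = stats::quantile(vol, 0:4 / 4, names = FALSE),
    eta = drop(X %*% beta),
    n = n, n_events = sum(cohort$event),
    spec = spec,
    center_levels = if (spec$adjusted) levels(factor(cohort$center_id)),
    X = X, prep = prep), class = "funcox")
}

#' @export
print.funcox <- function(x, ...) {
  cat("Smooth additive Cox model (",
      if (x$spec$adjusted) "adjusted" else "unadjusted", ")\n", sep = "")
  cat("  n =", x$n, "participants,", x$n_events, "events\n")
  cat("  smoothing parameters (LAML):",
      paste(sprintf("%s = %.3g", names(x$lambda), x$lambda),
            collapse = ", "), "\n")
  cat("  effective df:",
      paste(sprintf("%s = %.2f", names(x$edf), x$edf), collapse = ", "),
      "\n")
  cat("  partial log-likelihood:", format(x$loglik), "; converged:",
      x$converged, "\n")
  invisible(x)
}

block_beta <- function(fit, block) fit$coefficients[fit$idx[[block]]]
block_V <- function(fit, block)
  fit$Vbeta[fit$idx[[block]], fit$idx[[block]], drop = FALSE]

#' Hazard-ratio table for the parametric covariates
#'
#' Reports HR and 95% CI per covariate on the conventional reporting
#' scales: age per 10 years, Townsend index per study standard deviation
#' (2.8), all others per unit/category.
#'
#' @param fit An adjusted `funcox` fit.
#' @param townsend_sd Reporting scale for the Townsend index.
#' @return Data frame: term, scale, hr, lo, hi, beta, se.
#' @export
covariate_hr_table <- function(fit, townsend_sd = 2.8) {
  stopifnot(inherits(fit, "funcox"))
  if (is.null(fit$idx$para))
    stop("covariate HRs require an adjusted fit")
  beta <- block_beta(fit, "para")
  se <- sqrt(diag(block_V(fit, "para")))
  scale <- rep(1, length(beta))
  names(scale) <- names(beta)
  scale["age_years"] <- 10
  scale["townsend"] <- townsend_sd
  hr <- exp(beta * scale)
  lo <- exp((beta - 1.96 * se) * scale)
  hi <- exp((beta + 1.96 * se) * scale)
  data.frame(term = names(beta), scale = scale, hr = hr, lo = lo, hi = hi,
             beta = beta, se = se, row.names = NULL)
}

#' Fitted volume smooth with 95% bands
#'
#' @param fit A `funcox` fit.
#' @param grid Volumes (mg) to evaluate at; default 200 points over the
#'   observed range. Points outside the observed range are flagged
#'   `extrapolated` with a warning.
#' @return Data frame: volume, estimate, lo, hi, se, extrapolated.
#' @export
volume_curve <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "funcox"))
  rng <- fit$volume_range
  if (is.null(grid)) grid <- seq(rng[1], rng[2], length.out = 200)
  extra <- grid < rng[1] | grid > rng[2]
  if (any(extra))
    warning(sum(extra), " grid point(s) outside the observed volume range")
  B <- eval_basis(fit$vol_basis, grid)
  est <- drop(B %*% block_beta(fit, "vol"))
  se <- sqrt(pmax(rowSums((B %*% block_V(fit, "vol")) * B), 0))
  data.frame(volume = grid, estimate = est, lo = est - 1.96 * se,
             hi = est + 1.96 * se, se = se, extrapolated = extra)
}

#' Hazard ratio per 1 mg of volume over curve segments
#'
#' Summarizes the nonlinear volume smooth by the chord slope of the fitted
#' log-hazard over each segment: `HR = exp((f(b) - f(a)) / (b - a))`, with
#' CI from the corresponding contrast of the posterior covariance.
#'
#' @param fit A `funcox` fit.
#' @param segments List of `c(a, b)` volume ranges in mg; the default uses
#'   the conventional 0--20, 20--30, 30--80, 80+ segmentation clipped to
#'   the observed range.
#' @return Data frame: segment, a, b, hr, lo, hi.
#' @export
hr_per_mg_segment <- function(fit, segments = NULL) {
  stopifnot(inherits(fit, "funcox"))
  rng <- fit$volume_range
  if (is.null(segments)) {
    edges <- c(max(0, rng[1]), 20, 30, 80, rng[2])
    edges <- unique(pmin(pmax(edges, rng[1]), rng[2]))
    segments <- Map(c, edges[-length(edges)], edges[-1])
  }
  rows <- lapply(segments, function(s) {
    a <- s[1]; b <- s[2]
    if (!(a < b)) stop("degenerate segment [", a, ", ", b, "]")
    Bc <- (eval_basis(fit$vol_basis, b) - eval_basis(fit$vol_basis, a)) /
      (b - a)
    est <- drop(Bc %*% block_beta(fit, "vol"))
    se <- sqrt(max(drop(Bc %*% block_V(fit, "vol") %*% t(Bc)), 0))
    data.frame(segment = sprintf("%g-%g mg", a, b), a = a, b = b,
               hr = exp(est), lo = exp(est - 1.96 * se),
               hi = exp(est + 1.96 * se))
  })
  do.call(rbind, rows)
}

#' Fitted intensity weight function with 95% bands
#'
#' Evaluates the constrained weight smooth `w_hat(z)`; by construction it
#' contains no affine component over the bin representatives.
#'
#' @param fit A `funcox` fit.
#' @param grid Intensities (mg); default 200 points spanning the bin
#'   representatives. Must lie in \[3, 2000\].
#' @return Data frame: z, estimate, lo, hi, se.
#' @export
intensity_weight_curve <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "funcox"))
  if (is.null(grid)) grid <- seq(min(fit$z), max(fit$z), length.out = 200)
  if (any(grid < 3 | grid > 2000))
    stop("intensity grid must lie within [3, 2000] mg")
  B <- eval_basis(fit$int_basis, grid)
  est <- drop(B %*% block_beta(fit, "int"))
  se <- sqrt(pmax(rowSums((B %*% block_V(fit, "int")) * B), 0))
  data.frame(z = grid, estimate = est, lo = est - 1.96 * se,
             hi = est + 1.96 * se, se = se)
}

#' Fitted center (random) effects
#' @param fit An adjusted `funcox` fit.
#' @return Named vector of shrunken center effects.
#' @export
center_effects <- function(fit) {
  stopifnot(inherits(fit, "funcox"))
  if (is.null(fit$idx$center)) stop("fit has no center effect")
  b <- block_beta(fit, "center")
  names(b) <- fit$center_levels
  b
}
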
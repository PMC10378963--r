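# Independent oracles used across the suite. All are deliberately naive
# (double loops, generic optimizers) and share no code with the package's
# fitting path.

# Breslow partial log-likelihood by direct risk-set enumeration
naive_cox_loglik <- function(beta, X, time, event) {
  eta <- drop(X %*% beta)
  ll <- 0
  for (i in which(event > 0)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# brute-force maximizer of the (optionally penalized) partial likelihood
naive_cox_fit <- function(X, time, event, Spen = NULL) {
  p <- ncol(X)
  if (is.null(Spen)) Spen <- matrix(0, p, p)
  negpll <- function(b)
    -(naive_cox_loglik(b, X, time, event) - 0.5 * sum(b * (Spen %*% b)))
  opt <- stats::optim(rep(0, p), negpll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  opt$par
}

# two-group log-rank statistic: sum over event times of observed minus
# expected in group 1, variance by the hypergeometric formula
naive_logrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- group == sort(unique(group))[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event > 0]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(event > 0 & time == t)
    d1 <- sum(event > 0 & time == t & g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(o_minus_e = o_minus_e, var = v, chisq = o_minus_e^2 / v)
}

# product-limit estimator from first principles (deaths before censorings)
naive_km <- function(time, event) {
  ts <- sort(unique(time[event > 0]))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (k in seq_along(ts)) {
    n <- sum(time >= ts[k])
    d <- sum(event > 0 & time == ts[k])
    s <- s * (1 - d / n)
    out$surv[k] <- s
  }
  out
}

# small simulated survival data with plain covariates
toy_surv <- function(n, beta, seed, h0 = 0.1, censor = 8) {
  withr::with_seed(seed, {
    X <- cbind(x1 = stats::rnorm(n), x2 = stats::rbinom(n, 1, 0.4),
               x3 = stats::runif(n))
    eta <- drop(X %*% beta)
    lat <- -log(stats::runif(n)) / (h0 * exp(eta))
    list(X = X, time = pmin(lat, censor),
         event = as.integer(lat <= censor))
  })
}

# fast study-conditions cohort at an elevated event rate (~10%)
quick_sim <- function(n = 1000, seed = 1, ...) {
  generate_cohort(sim_config(n_participants = n, baseline_hazard = 0.017,
                             seed = seed, ...))
}

# same conditions with the hazard driven by the activity terms only, so an
# unadjusted fit is correctly specified (covariates are confounded with
# volume by design in the full generator)
pure_sim <- function(n = 1000, seed = 1, ...) {
  generate_cohort(sim_config(n_participants = n, baseline_hazard = 0.017,
                             covariate_effects = NULL, center_sd = 0,
                             seed = seed, ...))
}

# epoch series helper: repeats `accel` in whole cycles (value proportions
# are preserved exactly) over a day/hour grid with the requested coverage
make_epochs <- function(accel, id = 1L, days = 7, hours = 0:23) {
  if (length(accel) == 0)
    return(data.frame(participant_id = integer(0), epoch_index = integer(0),
                      accel_mg = numeric(0), day_index = integer(0),
                      hour_of_day = integer(0)))
  grid <- expand.grid(hour_of_day = hours, day_index = seq_len(days))
  k <- nrow(grid)
  n <- length(accel) * max(1, ceiling(k / length(accel)))
  idx <- seq_len(n)
  data.frame(participant_id = id, epoch_index = idx,
             accel_mg = rep(accel, n / length(accel)),
             day_index = grid$day_index[(idx - 1) %% k + 1],
             hour_of_day = grid$hour_of_day[(idx - 1) %% k + 1])
}
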
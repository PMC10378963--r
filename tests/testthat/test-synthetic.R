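test_that("configuration rejects invalid counts and rates", {
  expect_error(sim_config(n_participants = 0), "positive")
  expect_error(sim_config(baseline_hazard = -1), "baseline_hazard")
  expect_error(sim_config(censor_time_years = 0), "censor_time_years")
  bad <- default_mixture_spec()
  bad$dirichlet_mean <- c(0.5, 0.2, 0.1, 0.1, 0.2)
  expect_error(sim_config(mixture_spec = bad), "probability")
})

test_that("identical seeds reproduce the cohort exactly", {
  a <- generate_cohort(sim_config(n_participants = 50, seed = 99))
  b <- generate_cohort(sim_config(n_participants = 50, seed = 99))
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth$eta, b$truth$eta)
  c <- generate_cohort(sim_config(n_participants = 50, seed = 100))
  expect_false(identical(a$cohort$time_years, c$cohort$time_years))
})

test_that("an all-sleep mixture leaves empty histograms and only the
           covariate part of the linear predictor", {
  mix <- default_mixture_spec()
  mix$dirichlet_mean <- c(1, 0, 0, 0, 0)
  cfg <- sim_config(n_participants = 40, mixture_spec = mix,
                    true_volume_effect = function(v) rep(0, length(v)),
                    true_weight_function = function(z) rep(0, length(z)),
                    covariate_effects = NULL, center_sd = 0, seed = 3)
  sim <- generate_cohort(cfg)
  expect_true(all(is.na(hist_p_matrix(sim$cohort, sim$bins))))
  expect_equal(sim$cohort$sleep_fraction, rep(1, 40))
  expect_equal(sim$truth$eta, rep(0, 40))
})

test_that("event fraction matches the exponential closed form", {
  cfg <- sim_config(n_participants = 5000, baseline_hazard = 0.01,
                    true_volume_effect = function(v) rep(0, length(v)),
                    true_weight_function = function(z) rep(0, length(z)),
                    covariate_effects = NULL, center_sd = 0,
                    censor_time_years = 6.4, seed = 17)
  sim <- generate_cohort(cfg)
  p <- 1 - exp(-0.01 * 6.4)
  se <- sqrt(p * (1 - p) / 5000)
  expect_lt(abs(mean(sim$cohort$event) - p), 3 * se)
})

test_that("true survival curve has the closed form S(t)=exp(-h0 e^eta t)", {
  cfg <- sim_config(baseline_hazard = 0.1)
  S <- true_survival_curve(cfg, eta = 0)
  expect_equal(S(0), 1)
  expect_equal(S(10), exp(-1))
  S2 <- true_survival_curve(cfg, eta = log(2))
  expect_equal(S2(5), exp(-1))
})

test_that("Kaplan-Meier of generated data tracks the true survival curve", {
  cfg <- sim_config(n_participants = 3000, baseline_hazard = 0.05,
                    true_volume_effect = function(v) rep(0, length(v)),
                    true_weight_function = function(z) rep(0, length(z)),
                    covariate_effects = NULL, center_sd = 0,
                    censor_time_years = 6.4, seed = 31)
  sim <- generate_cohort(cfg)
  sf <- survival::survfit(survival::Surv(time_years, event) ~ 1,
                          data = sim$cohort, conf.int = 0.99)
  S <- true_survival_curve(cfg, eta = 0)
  inside <- S(sf$time) >= sf$lower & S(sf$time) <= sf$upper
  expect_gt(mean(inside), 0.98)
})

test_that("generator reproduces the target descriptive marginals", {
  sim <- generate_cohort(sim_config(n_participants = 10000, seed = 5))
  co <- sim$cohort
  expect_gt(stats::median(co$volume), 25)
  expect_lt(stats::median(co$volume), 32)
  P <- hist_p_matrix(co, sim$bins)
  frac500 <- mean((1 - co$sleep_fraction) * P[, ncol(P)])
  expect_lt(frac500, 0.005)
  expect_gt(frac500, 0)       # thin right tail present, not absent
  tb <- colMeans(time_budget(co))
  target <- c(sleep_h = 7.2, sedentary_h = 13.2, slow_min = 140,
              moderate_min = 62, brisk_min = 7)
  expect_true(all(abs(tb / target - 1) < 0.15))
  # events near the observed 22.2 per 1000 under the default hazard
  expect_gt(1000 * mean(co$event), 12)
  expect_lt(1000 * mean(co$event), 35)
})

test_that("raising a covariate log-HR raises the event fraction", {
  eff_lo <- c(sex_male = 0)
  eff_hi <- c(sex_male = 1.5)
  f <- function(eff, s) {
    cfg <- sim_config(n_participants = 10000, covariate_effects = eff,
                      baseline_hazard = 0.017, center_sd = 0, seed = s)
    mean(generate_cohort(cfg)$cohort$event)
  }
  expect_gt(f(eff_hi, 41), f(eff_lo, 41))
})

test_that("with no effects, survival is exchangeable across strata", {
  pvals <- vapply(1:200, function(r) {
    cfg <- sim_config(n_participants = 120, baseline_hazard = 0.08,
                      true_volume_effect = function(v) rep(0, length(v)),
                      true_weight_function = function(z) rep(0, length(z)),
                      covariate_effects = NULL, center_sd = 0,
                      seed = 5000 + r)
    co <- generate_cohort(cfg)$cohort
    sd <- survival::survdiff(survival::Surv(time_years, event) ~ sex_male,
                             data = co)
    stats::pchisq(sd$chisq, 1, lower.tail = FALSE)
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("epoch-level simulation agrees with the analytic features", {
  sim <- generate_cohort(sim_config(n_participants = 30, seed = 13))
  ep <- simulate_epochs(sim, participants = 1:3)
  expect_true(all(ep$accel_mg >= 0 & ep$accel_mg <= 2000))
  expect_equal(nrow(ep), 3 * 17280 * 7)
  feats <- build_histograms(ep, sim$bins)
  expect_true(all(feats$valid_wear == 1))
  P_exact <- hist_p_matrix(sim$cohort, sim$bins)[1:3, ]
  P_emp <- hist_p_matrix(feats, sim$bins)
  expect_lt(max(abs(P_emp - P_exact)), 0.005)
  expect_lt(max(abs(feats$volume - sim$cohort$volume[1:3])), 0.5)
  expect_lt(max(abs(feats$sleep_fraction - sim$cohort$sleep_fraction[1:3])),
            0.01)
  # deterministic in the cohort seed
  ep2 <- simulate_epochs(sim, participants = 1:3)
  expect_identical(ep, ep2)
})
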
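# one small fitted cohort shared across this file
sim_fit <- local({
  sim <- quick_sim(n = 900, seed = 8)
  fit <- fit_funcox(sim$cohort, model_spec(adjusted = FALSE, seed = 8))
  list(sim = sim, fit = fit)
})

test_that("the partial-likelihood score at beta = 0 matches pencil-and-paper
           risk sets", {
  # 6 subjects, times 1..6, deaths at 1, 3, 4, 6, binary covariate
  X <- matrix(c(1, 0, 1, 0, 1, 0), ncol = 1)
  time <- 1:6
  event <- c(1, 0, 1, 1, 0, 1)
  prep <- accelcox:::cox_prep(time, event)
  d <- accelcox:::cox_derivs(prep, X, 0)
  # by hand: (1 - 3/6) + (1 - 2/4) + (0 - 1/3) + (0 - 0) = 2/3
  expect_equal(drop(d$g), 2 / 3, tolerance = 1e-12)
  expect_equal(d$ll, log(1 / 6) + log(1 / 4) + log(1 / 3) + log(1))
})

test_that("the compiled derivative kernel matches the pure-R reference", {
  td <- toy_surv(300, c(0.4, -0.2, 0.6), seed = 13)
  tt <- round(td$time, 1) + 0.05            # include ties
  prep <- accelcox:::cox_prep(tt, td$event)
  for (b in list(c(0, 0, 0), c(0.5, -0.7, 0.3))) {
    a <- accelcox:::cox_derivs(prep, td$X, b)
    r <- accelcox:::cox_derivs_r(prep, td$X, b)
    expect_equal(a$ll, r$ll, tolerance = 1e-12)
    expect_lt(max(abs(a$g - unname(r$g))), 1e-10)
    expect_lt(max(abs(a$H - unname(r$H))), 1e-10)
  }
})

test_that("parametric Newton agrees with a brute-force maximizer and with
           an independent Cox implementation", {
  td <- toy_surv(200, c(0.5, -0.7, 0.3), seed = 14)
  prep <- accelcox:::cox_prep(td$time, td$event)
  mine <- accelcox:::newton_cox(td$X, prep, matrix(0, 3, 3))
  expect_true(mine$converged)
  expect_lt(max(abs(mine$beta - naive_cox_fit(td$X, td$time, td$event))),
            1e-6)
  cf <- survival::coxph(survival::Surv(td$time, td$event) ~ td$X,
                        ties = "breslow")
  expect_lt(max(abs(mine$beta - unname(stats::coef(cf)))), 1e-8)
})

test_that("tied event times use shared Breslow risk sets", {
  td <- toy_surv(150, c(0.4, 0, -0.5), seed = 15)
  tt <- ceiling(td$time)                       # force heavy ties
  prep <- accelcox:::cox_prep(tt, td$event)
  mine <- accelcox:::newton_cox(td$X, prep, matrix(0, 3, 3))
  cf <- survival::coxph(survival::Surv(tt, td$event) ~ td$X,
                        ties = "breslow")
  expect_lt(max(abs(mine$beta - unname(stats::coef(cf)))), 1e-8)
})

test_that("penalized partial likelihood agrees with the risk-set-expanded
           penalized Poisson fit", {
  td <- toy_surv(200, c(0.5, -0.7, 0.3), seed = 16)
  Spen <- diag(c(2, 0.5, 1))
  prep <- accelcox:::cox_prep(td$time, td$event)
  mine <- accelcox:::newton_cox(td$X, prep, Spen)
  pois <- fit_poisson_equivalent(td$X, td$time, td$event, Spen)
  expect_true(pois$converged)
  expect_lt(max(abs(mine$beta - pois$beta)), 1e-4)
})

test_that("a full smooth fit converges with sensible structure", {
  fit <- sim_fit$fit
  expect_true(fit$converged)
  expect_true(all(fit$lambda > 0))
  expect_equal(fit$Vbeta, t(fit$Vbeta), tolerance = 1e-10)
  expect_gte(min(eigen(fit$Vbeta, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-10)
  expect_equal(length(fit$coefficients),
               length(fit$idx$vol) + length(fit$idx$int))
  co <- sim_fit$sim$cohort
  few <- rbind(co[co$event == 0, ][1:80, ], co[co$event == 1, ][1:5, ])
  expect_error(fit_funcox(few, model_spec(adjusted = FALSE)), "10 events")
})

test_that("infinite penalty on the empty-null-space smooth removes it", {
  fit <- fit_funcox(sim_fit$sim$cohort,
                    model_spec(adjusted = FALSE,
                               lambda = c(vol = 1e8, int = 1e8)))
  expect_lt(max(abs(fitted_weights(fit))), 1e-4)
  # the volume smooth keeps only its unpenalized linear component
  vc <- volume_curve(fit, grid = c(20, 30, 40, 50))
  slopes <- diff(vc$estimate) / diff(vc$volume)
  expect_lt(max(abs(slopes - slopes[1])), 1e-6)
})

test_that("covariate HRs are reported on conventional scales", {
  sim <- quick_sim(n = 1200, seed = 18)
  fit <- fit_funcox(sim$cohort, model_spec(adjusted = TRUE, seed = 18))
  tab <- covariate_hr_table(fit)
  expect_setequal(tab$term,
                  c("sex_male", "age_years", "degree_educated", "townsend",
                    "poor_health", "longstanding_illness", "current_smoker",
                    "exceeds_alcohol", "bmi_overweight", "bmi_obese"))
  expect_equal(tab$scale[tab$term == "age_years"], 10)
  expect_equal(tab$scale[tab$term == "townsend"], 2.8)
  expect_equal(tab$hr, exp(tab$beta * tab$scale))
  expect_equal(tab$lo, exp((tab$beta - 1.96 * tab$se) * tab$scale))
  expect_true(all(tab$lo < tab$hr & tab$hr < tab$hi))
  # strong configured effects land the right side of 1
  expect_gt(tab$hr[tab$term == "sex_male"], 1)
  expect_gt(tab$hr[tab$term == "age_years"], 1)
  expect_error(covariate_hr_table(sim_fit$fit), "adjusted")
  # center effects exist for the adjusted fit and are shrunken
  ce <- center_effects(fit)
  expect_equal(length(ce), length(unique(sim$cohort$center_id)))
  expect_error(center_effects(sim_fit$fit), "center")
})

test_that("the volume curve and segment HRs are chord-consistent", {
  fit <- sim_fit$fit
  vc <- volume_curve(fit, grid = c(15, 20, 30, 40))
  seg <- hr_per_mg_segment(fit, list(c(15, 20), c(20, 30), c(30, 40)))
  chord <- exp(diff(vc$estimate) / diff(vc$volume))
  expect_equal(seg$hr, chord, tolerance = 1e-10)
  expect_error(hr_per_mg_segment(fit, list(c(20, 20))), "degenerate")
  expect_warning(volume_curve(fit, grid = c(5, 30)), "outside")
})

test_that("a linear fitted log-hazard gives the same HR on every segment", {
  fit <- fit_funcox(sim_fit$sim$cohort,
                    model_spec(adjusted = FALSE,
                               lambda = c(vol = 1e8, int = 1)))
  seg <- hr_per_mg_segment(fit, list(c(15, 20), c(20, 40), c(40, 60)))
  expect_lt(diff(range(seg$hr)), 1e-5)
})

test_that("the intensity weight curve carries no affine component", {
  fit <- sim_fit$fit
  wz <- fitted_weights(fit)
  co <- qr.solve(cbind(1, fit$z), wz)
  expect_lt(max(abs(co)), 1e-8)
  cw <- intensity_weight_curve(fit, grid = fit$z)
  expect_equal(cw$estimate, wz, tolerance = 1e-10)
  expect_true(all(cw$lo <= cw$estimate & cw$estimate <= cw$hi))
  expect_error(intensity_weight_curve(fit, grid = c(1, 50)), "within")
})

test_that("linear predictors are invariant to affine covariate
           reparameterization and HRs rescale exactly", {
  td <- toy_surv(250, c(0.5, -0.7, 0.3), seed = 19)
  prep <- accelcox:::cox_prep(td$time, td$event)
  f1 <- accelcox:::newton_cox(td$X, prep, matrix(0, 3, 3))
  X2 <- td$X
  X2[, 1] <- (td$X[, 1] - 5) / 10               # affine reparameterization
  f2 <- accelcox:::newton_cox(X2, prep, matrix(0, 3, 3))
  expect_equal(f2$beta[1], f1$beta[1] * 10, tolerance = 1e-6)
  expect_equal(drop(td$X %*% f1$beta) - mean(td$X %*% f1$beta),
               drop(X2 %*% f2$beta) - mean(X2 %*% f2$beta),
               tolerance = 1e-6)
})

test_that("the center ridge shrinks to zero as its lambda grows", {
  sim <- quick_sim(n = 800, seed = 20, center_sd = 0.3)
  fit <- fit_funcox(sim$cohort,
                    model_spec(adjusted = TRUE,
                               lambda = c(vol = 1, int = 1, center = 1e9)))
  expect_lt(max(abs(center_effects(fit))), 1e-4)
  fit2 <- fit_funcox(sim$cohort,
                     model_spec(adjusted = TRUE,
                                lambda = c(vol = 1, int = 1, center = 0.1)))
  expect_gt(stats::sd(center_effects(fit2)), stats::sd(center_effects(fit)))
})

test_that("fixed smoothing parameters are honored and reported", {
  fit <- fit_funcox(sim_fit$sim$cohort,
                    model_spec(adjusted = FALSE,
                               lambda = c(vol = 3, int = 7)))
  expect_equal(unname(fit$lambda), c(3, 7))
  expect_error(model_spec(adjusted = FALSE, lambda = c(vol = 1)), "named")
  expect_error(model_spec(lambda = c(vol = -1, int = 1, center = 1)),
               "positive")
})
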
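# accelcox

Smooth additive Cox models for accelerometer-measured physical activity:
how much does overall activity **volume** matter for all-cause mortality,
and — at a fixed volume — how much does the **shape** of the intensity
distribution matter?

Wrist accelerometry yields, per person, a week of 5-second epoch
accelerations (ENMO-style, milligravities). `accelcox` reduces them to two
exposures — PA volume (mean acceleration) and the sleep-excluded intensity
histogram — and fits the Cox model

```
log h_i(t) = log h_0(t) + f(volume_i) + Σ_k w(z_k) p_ik + x_i'γ + b_center(i)
```

where `f` is a penalized thin-plate smooth of volume and the histogram
enters as a *functional predictor*: relative frequencies `p_ik` weighted by
a smooth weight function `w` evaluated at the bin representatives `z_k`.
The constant **and linear** components of `w` are removed from its basis,
so the functional term is exactly orthogonal to mean intensity and
describes only the additional association of distribution shape beyond
volume. Smoothing parameters are selected by Laplace-approximate marginal
likelihood; ties are Breslow; the center effect is a Gaussian ridge.
Uncertainty follows the Bayesian view of penalized splines, with
simulation-based credible intervals for derived hazard ratios.

The package is self-contained for development and validation: a synthetic
cohort generator (`generate_cohort`) draws epoch-level-consistent intensity
mixtures, covariates and proportional-hazards survival from a *known*
volume effect and weight function, so every stage can be tested against
ground truth without access-controlled cohort data.

## Worked example

```r
library(accelcox)

# a synthetic cohort at an elevated event rate so the fit is quick
sim <- generate_cohort(sim_config(n_participants = 4000,
                                  baseline_hazard = 0.017, seed = 11))
cohort <- apply_eligibility(sim$cohort)

km <- km_by_quartile(cohort)
km
#> Kaplan-Meier by PA volume quartile
#>   breaks (mg): 11, 23.2, 27.8, 33.6, 89.7
#>   subjects: 1000, 1000, 1000, 1000
#>   log-rank chi-square = 18.50 on 3 df, p = 0.000347

fit <- fit_funcox(cohort, model_spec(adjusted = FALSE, seed = 11))
fit
#> Smooth additive Cox model (unadjusted)
#>   n = 4000 participants, 499 events
#>   smoothing parameters (LAML): vol = 0.0223, int = 0.000146
#>   effective df: vol = 3.00, int = 2.30
#>   partial log-likelihood: -4087.187 ; converged: TRUE

hr_per_mg_segment(fit)
#>         segment       a        b        hr        lo        hi
#> 1 11.0136-20 mg 11.0136 20.00000 0.9621056 0.9178344 1.0085122
#> 2      20-30 mg 20.0000 30.00000 0.9648733 0.9416862 0.9886313
#> 3      30-80 mg 30.0000 80.00000 1.0172441 0.9955625 1.0393979
#> 4 80-89.7438 mg 80.0000 89.74375 1.0544480 0.9840444 1.1298887
```

The survival curves separate by volume quartile (worst survival in the
lowest quartile), and the first segment says: below 20 mg, each 1 mg of
additional volume is associated with a ~4% lower hazard (the generator's
true conditional value is 9% per mg; estimates at the sparse low-volume
boundary are attenuated, and the unadjusted fit mixes in confounding —
see the vignette). Risk profiles compare realistic histogram shapes at
fixed volume:

```r
profiles <- construct_profiles(fit, cohort)
profile_hr(fit, get_profile(profiles, "overall", "high"),
                get_profile(profiles, "overall", "low"), seed = 11)
#> profile HR 1.643 (95% CrI 1.218, 2.210) [10000 draws, seed 11]
```

A participant whose intensity distribution matches the high-risk profile
(more mass below ~100 mg, less above ~250 mg) carries ~64% higher hazard
than one at the same volume with the low-risk profile. `run_pipeline()`
chains all stages (simulate/load → features → prep → fits → curves →
profiles → plots) into one output directory with a JSON manifest;
`inst/cli/accelcox.R` exposes the same stages as shell subcommands.

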
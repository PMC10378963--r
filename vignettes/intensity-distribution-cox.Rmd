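---
title: "Modelling all-cause mortality from the accelerometer intensity distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling all-cause mortality from the accelerometer intensity distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelcox)
```

## The problem

Wrist-worn accelerometers summarize physical activity (PA) as an
acceleration value (ENMO-style, in milligravities, mg) per short epoch,
typically every five seconds over a week. Two exposures can be derived per
person: the **PA volume** — the mean acceleration over all epochs — and the
**intensity distribution** — the histogram of relative frequencies of
epochs across acceleration intervals, after excluding epochs below 3 mg
(classified as sleep). Volume and the distribution are deeply entangled:
mean intensity is a functional of the histogram, and neighboring histogram
bins are strongly collinear, which defeats naive per-bin regression.

`accelcox` fits a smooth additive Cox proportional-hazards model that
separates the two exposures. The log-hazard for participant $i$ is

$$
\log h_i(t) = \log h_0(t) + f(v_i) + \sum_k w(z_k)\,p_{ik}
            + x_i^\top\gamma + b_{c(i)},
$$

where $v_i$ is PA volume, $p_{ik}$ the relative frequency in intensity bin
$k$ with representative intensity $z_k$, $f$ a thin plate regression
spline (TPRS), $w$ a TPRS **weight function** turning the histogram into a
functional predictor (a weighted average of relative frequencies),
$\gamma$ parametric confounder effects and $b_{c(i)}$ a Gaussian
assessment-center effect. Estimation maximizes the Breslow-tie penalized
partial likelihood; smoothing parameters maximize the Laplace-approximate
marginal likelihood (LAML).

## Separating volume from distribution shape

Because $\bar z_i \approx \sum_k z_k p_{ik}$, a weight function with an
affine component $a + b z$ duplicates information already carried by the
volume term. The package therefore removes the span $\{1, z\}$ from the
weight-function basis: basis columns evaluated at the bin representatives
are constrained to be orthogonal (uniform inner product over the $z_k$) to
constant and linear functions, by absorbing the two linear constraints into
a reduced basis. Afterward the functional term is *exactly* invariant — to
machine precision, which the tests assert — to adding any affine function
of intensity to $w$, and to moving histogram mass along the removed linear
direction. The weight function then answers only: *given this volume, does
the shape of the intensity distribution shift risk?*

The volume smooth itself keeps its linear component and carries only the
usual sum-to-zero identifiability constraint.

Whether to remove the affine span before or after the eigen-reduction of
the TPRS penalty is a genuinely open choice; the package projects the
reduced basis (the constraint holds exactly either way; the penalties
differ only in the discarded high-frequency tail).

## Thin plate regression splines

Both smooths use the 1-d thin plate family: radial kernel $|r|^3/12$, whose
wiggliness penalty is exactly zero on affine functions. The full-rank
radial basis on $m$ knots is reduced to `basis_dim` columns by
eigen-decomposing the kernel matrix and keeping the leading eigenvectors
after absorbing the thin-plate side conditions; evaluation points are
affinely rescaled to $[0,1]$ for conditioning. When the smooth is built
over many distinct values, up to 200 quantile-spaced knots are used.
Defaults: `basis_dim = 10` for both smooths (the sensitivity runner varies
both), bins from `bin_scheme()` — 5-mg cells up to 100 mg where most mass
and the high-risk region lie, 12.5-mg cells to 250 mg, 25-mg cells to
500 mg, and a terminal 500–2000 mg cell represented at 600 mg rather than
its midpoint, because observed epochs above 500 mg are a fraction of a
percent and sit almost entirely below 750 mg; a midpoint representative at
1250 mg would hand that near-empty cell extreme leverage.

## Fitting and uncertainty

For fixed smoothing parameters $\lambda$ the penalized partial likelihood
is maximized by Newton iteration with step halving (gradient tolerance
1e-6, at most 200 iterations, both configurable); ties share Breslow risk
sets. $\lambda$ maximizes
$\ell_p(\hat\beta) + \tfrac12\log|S_\lambda|_+ - \tfrac12\log|H+S_\lambda|$,
the LAML criterion that the counting-process (piecewise-exponential
Poisson) representation of the Cox model yields up to $\lambda$-free
terms; the package also ships the explicit risk-set-expanded penalized
Poisson fitter, and the test suite requires both routes to agree on
$\hat\beta$ to 1e-4. Optimization is Nelder–Mead over $\log\lambda$ with a
step-scale convergence rule: near the optimum LAML differences are $O(0.1)$
on an objective of $O(10^3)$, so a relative-tolerance stop would quit at
the starting point. When a near-infinite $\lambda$ makes the predicted
Newton gain smaller than the roundoff of the log-likelihood, the optimum is
declared resolved at machine precision.

The partial-likelihood derivative kernel (log-likelihood, score and the
risk-set-accumulated Hessian) is compiled C++ with an O(n p²) sweep over
the time-sorted data; a pure-R reference implementation ships alongside it
and the tests require the two to agree to near machine precision, which is
what makes the hundred-replicate simulations in the validation suite
affordable.

Uncertainty uses the standard Bayesian reading of penalized splines: the
posterior covariance is the inverse penalized information, coefficient
draws are Gaussian, and derived quantities (profile hazard ratios) carry
simulation-based credible intervals — quantiles are taken on the log scale
so that swapping the two profiles inverts the interval exactly. The center
effect is an i.i.d. Gaussian ridge with its own $\lambda$, the
penalized-spline form of a random intercept.

## Reported summaries

* `covariate_hr_table()` — HRs with age per 10 years and the Townsend
  deprivation index per standard deviation (2.8).
* `hr_per_mg_segment()` — the nonlinear volume curve summarized as chord
  HRs per 1 mg over 0–20, 20–30, 30–80, 80+ mg (clipped to the observed
  range; evaluating outside it is refused).
* `intensity_weight_curve()` — $\hat w(z)$ with 95% bands; areas with
  positive weight mark intensity ranges whose occupancy raises risk at
  fixed volume.
* `construct_profiles()` / `profile_hr()` — within volume quartiles,
  participants are ranked by their intensity-term contribution
  $\sum_k \hat w(z_k) p_{ik}$; the high-risk profile is the mean histogram
  of the top decile, low-risk the bottom decile, average the middle
  quintile (cutoffs configurable). Averaging observed histograms keeps
  profiles realistic — they are never model-optimal extremes. Profile HRs
  compare such profiles through the intensity term, and
  `profile_hr_by_volume()` adds the volume-smooth difference relative to a
  reference at the overall median volume with the overall average profile.

## The synthetic cohort generator

Ground truth for every stage comes from `generate_cohort()`. Each
participant draws a five-component intensity mixture — sleep (<3 mg),
sedentary (3–60), light (60–125), moderate (125–300), vigorous
(300–2000 mg) — with Dirichlet weights whose mean is the published overall
time budget (7.2 h sleep, 13.2 h sedentary, 140/62/7 min in the three
walking-equivalent ranges) and concentration 35; within components,
intensities are log-normal truncated to the component range, with
per-person jitter of the log-location (`shape_sd`) so histograms vary in
all directions, not only along the 4-dimensional mixture simplex — without
that, the functional term would be unidentifiable by construction. These
choices were calibrated once against published descriptive margins (median
volume ≈ 28.4 mg, spread ≈ 8.3 mg, ≈0.2% of epochs above 500 mg) and then
frozen.

Covariates reproduce the published sample margins (58% female, age
61.8 ± 7.8, 2% poor health, 26% longstanding illness, 7% smokers,
41/41/19% BMI categories, 22 centers); age, poor health and longstanding
illness are drawn *confounded* with volume (older and less healthy →
lower volume), because that — not the conditional volume effect, which is
weak across the bulk of the volume range — is what produces the marked
marginal survival separation by volume quartile, with the lowest quartile
worst. Simulations that isolate recovery of the activity terms switch the
covariate effects off (`covariate_effects = NULL`), making the unadjusted
model correctly specified.

Survival times are exponential given the linear predictor: constant
baseline hazard 0.0024/yr (≈22 deaths per 1000 over follow-up),
administrative censoring at 6.4 years. The default true volume effect is
piecewise linear — slope −0.09/mg below 20 mg, flat to 55 mg, +0.10/mg to
80 mg, flat above — giving chords of 0.91/mg below 20 and 1.05/mg over
30–80 while keeping hazard at the top quartile's mean volume near the flat
region, so low-volume risk curves lie above high-volume ones. The default
true weight function is a sigmoid, positive below ~100 mg and negative
above ~250 mg, amplitude ±6, making within-quartile high-vs-low decile
profile contrasts of order HR 1.3–1.7. Because only the affine-free part
of $w$ is identifiable, the generator stores the constrained truth
(`constrain_weights()`) as the estimand.

By default histograms and volumes are computed analytically from each
person's mixture (the expectation of a 120,960-epoch week, whose
multinomial noise is negligible at that epoch count);
`simulate_epochs()` materializes actual epoch series — the tests confirm
the two routes agree. Epoch-level realism ends there: device noise,
non-wear gaps and circadian autocorrelation are not simulated, covariate
confounding is limited to three variables with fixed strengths, and
censoring is a single scalar horizon rather than a staggered recruitment
range. Passing tests therefore
demonstrate correct recovery of a known data-generating process of this
family, not robustness to those real-data features.

## Numerical and design notes

* Histogram epochs are capped at 2000 mg, never dropped; an all-sleep
  record yields an empty (flagged) histogram, not an error.
* Quartile cuts assign boundary ties downward; Kaplan–Meier bands use the
  Greenwood variance (log scale); deaths precede censorings at tied times.
* Eligibility filtering consumes precomputed boolean disease flags
  (hospital-record parsing is upstream of this package) and is
  complete-case, with per-reason exclusion counts logged; deaths on the
  censor date count as events (censoring at end of day).
* Wear validity requires ≥3 distinct days and all 24 clock hours covered
  (pooled across days).
* A rank-deficient penalized design, degenerate volume quartiles, a
  stratum below 100 participants, or fewer than 10 events raise immediate
  errors naming the problem.

## Known limitations

Estimation near the edges of the volume distribution is boundary-biased
under global smoothing-parameter selection: where data thin out (volumes
below ~16 mg in the default generator), steep features of the true curve
are flattened, and chord HRs measured there are attenuated — an
independent penalized-Cox implementation reproduces the same values, so
this is a property of the estimator class, not of this implementation. At
a few hundred events the LAML criterion may legitimately shrink the whole
intensity term away; several thousand participants at a ~10% event rate
are needed before the weight function is reliably recovered (the package's
own simulations use 2,000–10,000). Confidence in the far right tail of the
intensity axis is intrinsically poor because almost no epochs — and very
few deaths — occur there.
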
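---
title: "Screening intraoperative hypotension burden against neurocognitive outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening intraoperative hypotension burden against neurocognitive outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemoscreen)
```

## The problem

Neurocognitive impairment is a recognized complication of on-pump cardiac
surgery, and intraoperative hypotension is one of its suspected mechanisms.
A patient's impairment status is commonly defined by a drop of two or more
points on the Montreal Cognitive Assessment (MoCA) between the preoperative
baseline and a one-month follow-up. The question this package addresses is
whether the hemodynamic burden recorded by the anesthesia monitor during
surgery — how deep, how long and how much the mean arterial pressure (MAP)
sat below clinically motivated thresholds — predicts that binary outcome.

The analysis is deliberately exhaustive rather than confirmatory: instead of
pre-selecting a model, every non-empty subset of a per-threshold predictor
roster is screened with logistic regression and with a random-forest
classifier, and the screen's aggregate behaviour (any omnibus significance?
any accurate classifier?) is the finding.

## Pipeline

### Artifact filtering

Invasive pressure exports carry flushes, line disconnections and transducer
artifacts. `flag_artifacts()` applies five removal criteria to the raw
series: systolic outside 20–300 mmHg; systolic at or below diastolic + 5
mmHg; diastolic outside 5–225 mmHg; and systolic variation (in either
direction) of at least 80 mmHg within 1 minute or 40 mmHg within 2 minutes.
Three readings of the windowed criteria are possible; this package compares
each sample against *every* earlier sample inside the trailing window (max
excursion, not adjacent-sample differences), flags the *later* sample of an
offending pair (a jump is evidence against the newer reading), and computes
all flags in one pass on the raw input so the result does not depend on
removal order. A violation in any pressure channel removes the whole sample
row; samples with missing pressures are dropped beforehand and counted in
the filter report.

### Period segmentation and burden metrics

Each patient record carries half-open `[start, end)` bypass and cross-clamp
windows, the clamp window nested in the bypass window. `segment_period()`
extracts either segment; the cross-clamp segment has no pulse channel (no
heartbeat while the aorta is clamped). Bypass metrics include the nested
clamp interval — the bypass period *is* the superset period, and excluding
the clamp would leave a metric over a disconnected time set.

For thresholds of 75, 65 and 55 mmHg, `build_feature_table()` derives per
patient and period:

* **AMD** — absolute maximum decrease, `max(0, T - min(MAP))`, mmHg;
* **Time_Under** — each retained sample below `T` is credited a fixed
  nominal 2.4 s and the durations are summed;
* **Area** — the Riemann sum `sum((T - MAP_i) * 2.4)` over samples below
  the threshold, mmHg·s;
* **TWA** — Area divided by the full segment duration, mmHg.

Two conventions deserve note. First, "under threshold" is strict (`<`): a
sample at exactly `T` contributes zero area either way, and strictness keeps
`Time_Under = 0` exactly when `Area = 0`. Second, the Riemann sum as written
would go negative for above-threshold samples; contributions are clipped at
zero, which is the only reading consistent with an *area between the
threshold and the curve*. Per-sample crediting uses the nominal 2.4 s
cadence, not actual inter-sample gaps — the retained data are irregular
after filtering, and the fixed-duration convention makes `Time_Under` a
simple count scaled by the cadence. These identities then hold by
construction and are enforced in the test suite: `Area <= AMD * Time_Under`,
`TWA * duration = Area`, monotonicity in the threshold, and
`AMD(T+10) - AMD(T)` in `[0, 10]`.

The full predictor set is 30 variables: demographics (`Age`, `Flow`, `BSA`),
nine bypass and nine cross-clamp burden metrics, period averages
(`*_Av_Sys`, `*_Av_Dia`, `*_Av_SpO2`, plus `Bypass_Av_PLS` — no pulse
average exists for the clamp period), and the window durations `Bypass_min`
and `Cross_min` taken from the recorded windows rather than sample counts.

### Combination enumeration

Each period and threshold defines a roster: 12 parameters for bypass, 11 for
cross-clamp. All `2^12 - 1 = 4095` (resp. `2^11 - 1 = 2047`) non-empty
subsets are enumerated per roster. Because 9 (resp. 8) parameters are common
to the three thresholds, subsets drawn only from the common names are
identical across rosters and are kept once:

```{r combos}
b  <- deduplicate(do.call(rbind, lapply(build_groups("bypass"), enumerate_subsets)))
cr <- deduplicate(do.call(rbind, lapply(build_groups("cross"),  enumerate_subsets)))
c(bypass = nrow(b), cross = nrow(cr), total = total_analyses(b, cr))
```

The closed form is `3(2^n - 1) - 2(2^c - 1)` per period; the test suite
checks it against brute-force set hashing for generic `(n, c)`. Subsets of
the five parameters shared *across* periods are intentionally not merged —
the two per-period counts are summed (the arithmetic `11263 + 5631 = 16894`
demonstrably sums them); `total_analyses(..., global_dedup = TRUE)` offers
the stricter count for users who want it. Enumeration order is lexicographic
by bitmask, so screen outputs are reproducible and resumable.

### Logistic screen

For each combination, `fit_logistic()` maximizes the binomial likelihood of
\(P(Y=1\mid X) = e^{\beta_0+\sum\beta_j X_j}/(1+e^{\beta_0+\sum\beta_j X_j})\)
by IRLS (tolerance `1e-8`, 100 iterations) and records the intercept-only
log-likelihood \(\ln L_0\) in closed form. From these:

* the **omnibus test**: \(2(\ln L_M - \ln L_0) \sim \chi^2_{df}\), the
  likelihood-ratio test of the predictors jointly;
* **Cox & Snell** \(R^2 = 1 - (L_0/L_M)^{2/n}\) and **Nagelkerke**
  \(R^2_N = R^2_{CS} / (1 - L_0^{2/n})\), both evaluated on the
  log-likelihood scale with exponentiation deferred to the ratio so that
  likelihoods like \(0.5^{500}\) cannot underflow;
* **Wald** tables: per-term `Exp(beta)` odds ratios with
  `exp(beta ± 1.96·SE)` intervals (the 1.96 convention matches how such
  tables are conventionally printed).

Predictors enter in raw units by default (odds ratios per mmHg, per second,
per mmHg·s), with `standardize = TRUE` available. Quasi-complete separation
— common at `n = 28` with up to 12 predictors — is detected and flagged;
fits with at least `n/3` predictors are additionally flagged
overparameterized. Both are reported, never silently dropped. No
multiple-testing correction is applied by default (the screen is a
sensitivity sweep, and its aggregate null behaviour is the object of
interest); Bonferroni and Benjamini–Hochberg are available as options.

### Random-forest screen

The forest itself is Breiman's algorithm via the `randomForest` package
(`K = 100` trees, unlimited depth, `sqrt(p)` features per split — all
exposed in `forest_config()`, since no single convention is canonical).
Everything around it is computed in-package: the stratified 70/30 split
(class ratio preserved within one sample), stratified 5-fold
cross-validation accuracy, the per-class precision/recall/F1/support
classification report with macro and support-weighted averages, normalized
impurity-decrease importances, and partial dependence.

`partial_dependence()` implements the empirical form of the partial
dependence function \(\bar F_l(z_l) = \int \hat F(z_l, z_{\setminus l})\,
p_{\setminus l}(z_{\setminus l})\, dz_{\setminus l}\) directly: for each
grid value the target feature is overwritten in every row and the predicted
class-1 probabilities are averaged. For an additive prediction function this
reproduces the component function up to an additive constant, and averaging
the curve over the observed feature values recovers the mean prediction —
both checked in the tests against hand-built models.

### Study-design power computation

`power_sample_size()` inverts the exact noncentral-t power function of the
two-sided two-sample t-test (via `power.t.test`), rounds the per-group size
up and doubles it. At Cohen's d = 0.5, 80% power, two-sided alpha 0.05:

```{r power}
unlist(power_sample_size(0.5, 0.80, 0.05))
```

The normal-approximation shortcut gives 126 and is *not* used; the exact-t
convention (128) is the standard tool behaviour. The test suite also checks
inverse consistency: achieved power at the returned size is at least the
request, and one pair fewer falls below it.

## The synthetic cohort

No patient-level data accompany the design this package implements, so
`generate_cohort()` simulates cohorts with the statistical structure the
analysis assumes; it is first-class, tested code, not a fixture.

Per patient: a MAP setpoint drawn from N(72, 8) mmHg; a mean-reverting
random walk around it (innovation SD 1.2 mmHg per step, reversion 0.03,
clipped to 20–130 mmHg); and transient hypotensive episodes — half-cosine
dips at 1.2 per hour, 10–40 mmHg deep, 10–20 minutes long. The episodes are
what carry MAP below 55 mmHg: a mean-reverting walk alone essentially never
does, which would make the deep-burden metrics degenerate at zero. Their
flanks are slow enough that genuine dips mostly survive the 2-minute
variation criterion. Systolic and diastolic are offset from MAP by noisy
pulse pressures with floors guaranteeing `sys > mean > dia` (and a pulse
pressure above the 5 mmHg artifact margin) at every clean sample; SpO2 and
pulse are level-shifted by period, with pulse absent during cross-clamp.
Timestamps advance by 2.4 s with ±20% uniform jitter (only the average
cadence is meaningful). Bypass duration is N(115, 30) minutes with the
cross-clamp window (N(72, 25) min, truncated) placed uniformly inside it.
Artifacts of all five kinds are injected at configurable per-sample rates
(defaults 0.1–0.2%), each corrupted sample violating its intended criterion.

Outcome labels: with `effect_feature = "none"`, Bernoulli(10/28) independent
of everything — the null cohort. Otherwise the label follows a logistic
model on the named feature standardized across the cohort, with slope
`effect_beta` log-odds per SD, so parameter recovery is well-posed. MoCA
pre-scores are discrete uniform 24–30 and the post-score is derived from the
label (drop ≥ 2 iff label 1); grouping uses the label, the scores are
carried for reporting. One master seed spawns per-patient seeds by fixed
arithmetic, so identical configurations give identical cohorts patient by
patient.

What the generator does **not** emulate: pulsatile waveforms, drug and
perfusionist interventions, correlations between demographics and
hemodynamics, or the covariance structure of real monitor artifacts. Passing
tests therefore demonstrate that the *pipeline* is correct and calibrated on
data with the assumed structure — not that real hemodynamic data predict (or
fail to predict) neurocognitive outcomes. On default settings the filter
removes roughly a fifth of the synthetic samples (mostly dip flanks caught
by the 2-minute criterion), which is comparable in magnitude to the heavy
filtering real monitor exports undergo.

## Problem sizes and numerical choices

The test suite exercises the screens at the scales the analysis targets: the
full 16,894-combination logistic screen on a 28-patient cohort (it completes
in seconds), null calibration of the omnibus test over 500 effect-free
28-patient cohorts (rejection rate within three Monte-Carlo SDs of 0.05 and
Kolmogorov–Smirnov uniformity of the p-values), and slope recovery within
±0.35 of a planted 1.5 log-odds/SD effect at `n = 300`. Simulated surgeries
in these sweeps use 35-minute bypass runs — the calibration and recovery
properties do not depend on recording length, and the package's own choice
is to spend replication budget on cohorts rather than minutes of signal.
Forest screens are far costlier per combination than logistic ones;
`run_pipeline()` therefore thins the forest manifest to a seed-determined
subsample (`rf_max_combos`) by default, and screening all combinations is a
flag away for users with the budget.

Degenerate inputs are defined, not errors: empty windows give empty
segments; an empty segment gives zero burden (TWA is missing, and the
patient is excluded from the feature table with a warning only if the whole
bypass segment is empty); a single-class outcome makes Nagelkerke R²
undefined and flagged; a constant feature collapses its PDP to one point.

## Limitations

* The screens' multiplicity is by design unadjusted; their output is the
  aggregate pattern, and individual small p-values in 16,894 correlated
  tests mean little.
* At `n = 28`, large subsets are routinely separated or overparameterized;
  the flags make this visible but cannot repair it (penalized or exact
  logistic regression is out of scope).
* The likelihood-ratio omnibus test is mildly liberal at `n = 28`; the
  calibration suite bounds, but does not remove, this small-sample effect.
* Relative (percent-of-baseline) MAP thresholds, cerebral oximetry, emboli
  and hematocrit channels are out of scope.
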
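---
title: "Simulating, predicting and mitigating nocturnal hypoglycemia with noctiguard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating, predicting and mitigating nocturnal hypoglycemia with noctiguard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noctiguard)
```

## Scope and design

`noctiguard` studies nocturnal hypoglycemia (NH) in type 1 diabetes under
multiple-daily-injection therapy in four connected stages: a virtual
cohort generator, CGM preprocessing and night labeling, bedtime feature
engineering with SVM model building, and an in-silico rescue-carbohydrate
intervention. Everything downstream of the generator consumes only the
artifacts a real study would produce (time-stamped CGM, bolus, meal, step
and sleep logs), so the pipeline runs unchanged on real exports once
parsed into the same plain tables.

## The virtual patient model

The simulator is deliberately minimal: two lumped states, plasma glucose
$G$ (mg/dL) and a remote insulin-action compartment $I_{act}$ (U),

$$\frac{dG}{dt} = S_G\,(G_b - G) + Ra(t) + EGP
  - SI\, m(t)\, I_{act}\left[(1-w) + w\,\frac{G}{G_b}\right],
  \qquad
  \frac{dI_{act}}{dt} = u(t) - \frac{I_{act}}{\tau_{act}}.$$

Carbohydrate (meals, rescue snacks) appears in plasma through the
two-equal-compartment gut model, whose impulse response is the
bi-exponential $Ra(t) = D f\, t\, e^{-t/\tau_{max}}/\tau_{max}^2$: zero at
ingestion, peak at $\tau_{max}$, total mass $Df$. Boluses reach the action
compartment through the same family of curves
($\tau \approx 45$ min) on top of a constant basal rate. $EGP$ is fixed at
the value that balances basal insulin action, so with no events and no
overnight modification the model sits exactly at $G_b$ — a property the
test suite asserts.

Three choices deserve explanation:

* **Split insulin action ($w = 0.6$).** Insulin-mediated glucose disposal
  is partly proportional to glucose itself (the classical remote-action
  $X \cdot G$ term of minimal models) and partly independent of it. The
  proportional share makes carbohydrate elevations clear faster exactly
  when insulin action is high and makes lows self-limiting; the additive
  share preserves a persistent hypoglycemic drive. The 60/40 split is the
  value at which a 30 g bedtime snack prevents roughly half of the
  episodes it reaches — the dose–response reported for the study this
  package emulates. The two pure extremes bracket it badly: fully
  additive action lets the snack's glucose elevation linger for hours
  (nearly every treated episode prevented), fully proportional action
  erases it within the hour (almost none prevented).

* **Pre-dawn sensitivity profile.** The overnight insulin-sensitivity
  modification that generates NH is a single per-patient multiplier
  $m \ge 1$ applied inside 00:00–06:00, but scaled along a fixed skewed
  bump $s(x) \propto x^3(1-x)$ (zero at both window edges, peak three
  quarters in, about 04:30). A constant in-window factor drives glucose to
  a shifted equilibrium and holds it there, producing implausible
  multi-hour lows whose nadir always falls at 06:00; the bump instead
  yields episodic lows clustered in the pre-dawn hours with spontaneous
  recovery, which is where clinical CGM studies place NH and which keeps
  the ratio of level-2 (<54 mg/dL) to level-1 (<70 mg/dL) exposure small,
  as observed in free-living cohorts.

* **Exact integration.** Both state equations are linear with piecewise
  constant (or piecewise-defined) coefficients on the 1-minute grid, so
  each step uses the closed-form exponential update; the recurrence is
  unrolled with cumulated products. There is no solver tolerance to tune
  and the steady state is preserved to machine precision. Traces leaving
  (0, 600] mg/dL are clipped to [1, 600] with a warning.

## The cohort generator

`generate_cohort()` draws patients and nights from fixed ranges chosen to
represent adults with long-standing T1D under MDI:

| quantity | distribution | units |
|---|---|---|
| body mass | U(55, 90) | kg |
| glucose distribution volume | U(1.6, 2.0) | dL/kg |
| basal glucose $G_b$ | U(125, 150) | mg/dL |
| glucose effectiveness $S_G$ | U(0.005, 0.008) | 1/min |
| endogenous glucose production | U(0.9, 1.3) | mg/dL/min |
| basal insulin | U(0.7, 1.2) | U/h |
| insulin action time | U(200, 260) | min |
| meal $\tau_{max}$ | U(60, 80) | min |
| carbohydrate bioavailability | U(0.80, 0.95) | — |
| CGM noise | 5 | mg/dL (sd) |

The carb ratio is derived from the patient's own sensitivity (the ratio
that balances a meal against its bolus) with a ±15% personal bias —
patients under long-term MDI carry approximately correct ratios, and an
uncorrelated ratio would make baseline (unmodified) nights routinely
hypoglycemic.

Each night draws a dinner (55 ± 12 g at ~20:20) with a ±15%
carbohydrate-estimation error propagated to the bolus, a sleep onset
(23:45 ± 25 min), a daily step count, an optional evening activity bout
(probability 0.35), a lognormal day-level basal-glucose drift (7%), a
lognormal night-sensitivity perturbation (12%), CGM noise, and sensor
gaps (Poisson starts, lognormal durations, losing roughly 10–20% of
nights). Two couplings give the prediction task its information
structure: evening activity scales the night's sensitivity excess (so the
activity features genuinely predict), and the day-level drift is visible
in the whole evening trace (so the CGM features predict how close the
night starts to the 70 mg/dL boundary). Night-to-night sensitivity noise
remains unobservable, bounding achievable accuracy away from perfection.

Calibration: for each patient the multiplier is bisected on [1, 8]
against the fraction of NH nights over that patient's pre-drawn nights;
the fraction is monotone in the multiplier because each night's trace is
pointwise decreasing in it, so bisection is exact up to one night. Targets
are scattered ±5 percentage points around the requested cohort fraction
(default 1/3). Failure to bracket raises an error carrying the achieved
fractions at both bracket ends.

## Preprocessing and labeling

CGM gaps of at most 120 min (interior runs on the regular grid) are
linearly interpolated; longer runs and edge gaps stay missing. A night is
labeled positive when three or more consecutive non-missing readings in
the 6 h after sleep onset are below 70 mg/dL — on the 15-min grid this is
at least 45 min below threshold, and a missing sample breaks a run. A
window with no qualifying run but a gap longer than 120 min is
*unevaluable* (`NA`) and excluded from the instance pool; records whose
6-h pre-sleep window retains an unfillable gap are dropped, and the
counts of dropped and surviving records always reconcile.

## Features

Prediction time is the last CGM sample at or before sleep onset. The 17
features (15 without physical activity) are listed in `nh_feature_names()`
and computed by `build_feature_vector()`; conventions worth noting:
hourly means use the available samples of their hour and an empty hour
rejects the instance; the 30/60-min deltas use exact grid samples; bolus
on board uses a linear remaining-fraction curve with a 240-min action
time; carbohydrate on board uses the closed-form bi-exponential
cumulative; activity on board is an exponentially decaying accumulation
(60-min constant); the risk indices use the standard Kovatchev transform,
every reading contributing to LBGI, HBGI or (at the risk-neutral glucose)
neither; the area below 70 mg/dL is trapezoidal with linearly
interpolated threshold crossings. All of these curves and constants are
arguments, not magic numbers.

## Model building

`nh_fit()` implements the nested resampling: an outer stratified
five-fold loop for generalization estimates, an inner stratified
five-fold grid search over $(C, \gamma)$ maximizing the chosen metric
(Gmean by default; ties break toward smaller $C$, then smaller $\gamma$,
preferring smoother models), inverse-frequency class weights against the
~1:2 imbalance, and standardization fitted on each training portion only.
Default grids are $C \in 2^{\{-5,-3,\dots,15\}}$,
$\gamma \in 2^{\{-15,-13,\dots,3\}}$; the examples and the acceptance
script use small sub-grids ($3 \times 3$) that reach the same operating
region in a fraction of the time. Population evaluation holds one patient
out entirely, trains the nested scheme on the rest and reports the median
of the five outer models' performance on the held-out patient;
personalized evaluation repeats a stratified 80/20 split five times.
Patients whose data cannot support a model (single class) are reported as
non-evaluable rather than silently skipped. The SVM itself is `e1071`'s;
every split, search, score and audit is this package's own code, and the
test suite checks the absence of patient leakage, the stratification
balance, determinism under fixed seeds, and that label permutation
destroys measured skill.

## The intervention study

`mitigation_study()` emulates a predictor by its (SE, SP): per night an
independent uniform deviate decides the prediction (probability SE of a
positive on true-NH nights, 1−SP on the rest). Predicted-positive nights
receive rescue carbohydrate (bioavailability 1, the snack grid defaults
to 20/25/30/35 g and $\tau_{max}$ 20/40/60 min) at 23:30 — before the
evaluation window — and are re-simulated with the same sensitivity,
drift and CGM-noise draws as baseline. These common random numbers make
arm contrasts exact: the set of NH nights under a larger dose is nested
inside that under a smaller dose, which the tests assert across seeds.
Outcomes per night are the NH indicator and percent time below 54, below
70, in 70–180 and above 180 mg/dL over 00:00–06:00 (the last three
summing to 100 exactly); summaries report per-patient values, cohort
medians (midpoint convention), relative reductions
$(\text{base}-\text{treated})/\text{base}\times 100$, and two-sided exact
Wilcoxon signed-rank p-values. The exact null distribution is computed by
the generating-function recursion over (doubled, midranked) ranks —
identical to enumerating all $2^n$ sign assignments, verified against
literal enumeration in the tests — with zero differences dropped and a
tie-corrected normal approximation beyond n = 25.

## Problem sizes and what the tests show

The unit suite runs on a 4-patient × 40-night cohort; the acceptance
suite and `scripts/acceptance.R` generate the full 10-patient × 89-night
cohort (the 89-night horizon is what makes a patient with 29
hypoglycemic nights report 32.58%), run the intervention at SE 0.73 / SP
0.75 with 20 and 30 g at $\tau_{max}$ 40 min, and evaluate the
leave-one-patient-out SVM on a $3\times3$ grid. On one CPU the whole
acceptance computation takes a few minutes.

Passing these checks shows that the pipeline's logic is sound and that a
cohort calibrated to the published prevalence reproduces the published
intervention arithmetic and dose–response; it does not show that the
virtual cohort matches real free-living physiology. Known gaps: the
model has no counter-regulatory hormones and no dawn rise in glucose
production; rescue carbohydrate can overshoot into the above-180 range
more than real patients do (our time-in-range consequently dips under
treatment where the study reported a small rise); sensor error is plain
Gaussian without drift or compression artifacts; and nights are
simulated as independent scenarios rather than a continuous 12-week
timeline. Real-data performance of any predictor trained here must be
established on real data.
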
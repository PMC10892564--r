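---
title: "Cadence-based recovery monitoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cadence-based recovery monitoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After total hip or knee arthroplasty, recovery has traditionally been
assessed at clinic visits — sparse snapshots that miss how patients
actually move at home. A wrist-worn tracker reporting step counts per
minute turns daily life into a continuous functional assessment. This
package implements the full analysis chain for such data: per-day digital
biomarkers, their day-to-day stability, responder stratification, and
trajectory modelling of the return to pre-operative activity.

```{r setup}
library(stepcadence)
```

## Per-day biomarkers

From one patient-day of minute-resolution step counts we compute, after
removing device artefacts (minutes above 150 steps — implausible cadence
for this population — are dropped and logged):

* **Daily steps** — sum over retained minutes.
* **P1M, peak 1-minute cadence** — the highest single-minute step count:
  the "best natural effort" cadence the patient can produce in free
  living.
* **P6MC, peak 6-minute consecutive cadence** — the highest *mean*
  cadence over any six consecutive minutes, scanned with a sliding window
  that advances one minute at a time over every start minute of the day.
  It is the free-living analogue of a six-minute walk test and reads as a
  sustained-capacity measure; being a mean, P6MC ≤ P1M always.
* **Intensity minutes** — each retained minute falls in exactly one
  cadence band: sedentary `[0, 20)`, light `[20, 100)`, moderate
  `[100, 130)` (≈ ≥3 METs at the conventional 100 steps/min threshold),
  vigorous `[130, 150]`. Intensity is aggregated to minutes per
  post-operative week, the scale of physical-activity recommendations.

Two conventions deserve a note. The cadence-band sources leave 100 and
130 steps/min formally unassigned ("<100", ">100 and <130", ">130"); we
use half-open bands so 100 is moderate — consistent with "moderate
corresponds to a threshold of 100 steps/min" — and 130 vigorous. All
four thresholds are configurable via `intensity_thresholds()`.

Missing minutes are ambiguous because wear time is not monitored. We
therefore never impute at the I/O layer; inside a P6MC window a missing
minute counts as 0 steps (inactivity), whereas a minute *removed as an
outlier* invalidates every window containing it — a measurement error
must not masquerade as rest. A day whose every minute was removed yields
`NA` sentinels for both cadence peaks rather than a fabricated 0.

## Intraweek variability

A biomarker useful for monitoring should read similarly across the days
of a week. For each patient, surgery-anchored week (days `7k−6..7k`) and
metric we compute the coefficient of variation, sd/mean with the `n−1`
standard deviation, requiring at least 4 observed days (configurable; the
source analyses do not state a minimum). Cohort aggregation is median
[p25; p75] across patients — per-patient CVs first, never pooled days —
matching the skew-aware reporting style of this literature. The CV is
scale-invariant, so it compares metrics with different units fairly.

## MCID stratification

Patients are labelled by whether their Forgotten Joint Score improved by
at least the minimal clinically important difference at 3 months:
17.5 points after total hip, 16.6 after total knee, 12.5 after
unicondylar knee arthroplasty. Equality counts as achieving the MCID (it
is a *minimal* important difference). Revision and resurfacing procedures
have no published threshold and are excluded from stratified analyses, as
are patients missing the 3-month score.

## Trajectory model

Daily outcomes over the modelled range (days 1–60 for hip, 1–90 for knee
in the motivating study) are repeated measures per patient:

$$y_{it} = \alpha + \beta_1\,\mathrm{day}_t + \beta_2\,\mathrm{group}_i
 + \beta_3\,(\mathrm{day}\times\mathrm{group})_{it}
 + \beta_4\,\mathrm{age}_i + \beta_5\,\mathrm{gender}_i
 + a_i + \varepsilon_{it},$$

with one random intercept per patient, $a_i \sim N(0, \mu^2)$, and
independent residuals $\varepsilon_{it} \sim N(0, \sigma^2)$. Before
fitting, each group's mean at the first modelled session is subtracted
from all of that group's values, so both trajectories start at mean zero
and $\beta_2 + \beta_3 t$ measures divergence after the first session.
MCID+ is the reference level of the recovery factor (total knee is the
reference when contrasting surgery types); age and the male indicator are
mean-centered so the intercept refers to the reference group at the
cohort-average covariates.

Estimation is full maximum likelihood, written in-package: with
$\lambda = \mu^2/\sigma^2$ fixed, each patient block has covariance
$\sigma^2(I + \lambda J)$, whose inverse is available in closed form, so
$\beta$ is a GLS solve and $\sigma^2$ profiles out — leaving a
one-dimensional search over $\lambda$. The maximized likelihood is
verified in the test suite against a direct multivariate-normal density
oracle and against lme4's ML fit. Degenerate inputs are handled
explicitly: noiseless data returns the least-squares solution with
$\mu^2 = 0$ and a warning; a variance ratio estimated at the zero
boundary warns of a singular fit but returns it.

Day enters linearly (no splines — none are described in the motivating
analysis). This matters for interpretation: true recovery is concave, so
the linear contrast extrapolated to early days can overstate early group
differences. Estimated separation days are therefore best read
comparatively across outcomes, not as absolute onsets.

### Derived quantities

* **Pre-operative reference** — the group mean of per-patient pre-op
  means (equal patient weighting) with a t-based 95% CI. The estimator is
  a package choice; the source figures show pre-operative bands without
  defining one.
* **Return day** — the smallest integer day in the modelled range at
  which the group's predicted trajectory, back on the original scale
  (group first-session mean added), reaches the reference *mean* (not a
  CI bound). CI by parametric bootstrap of the fixed effects
  (default 1000 draws from $N(\hat\beta, \widehat{\mathrm{vcov}})$,
  seeded); draws that never reach the reference enter the day quantiles
  as "not reached".
* **Separation day** — the smallest integer day at which the Wald 95% CI
  of $\beta_2 + \beta_3 t$ excludes zero, using the quadratic form of the
  contrast variance; CI again by parametric bootstrap (the contrast
  covariance held at its estimate). The source names only "95% confidence
  intervals"; Wald-plus-bootstrap is the package's documented choice.

Return-day evaluation on integer days only, trajectories at population
level (random intercept 0, centered covariates at their means).

## The synthetic cohort

Real cohorts of this kind are not shareable, so the generator *is* the
test bed, with known ground truth. Its defaults state the emulated world:

* Pre-operative level calibrated to the reported population medians:
  bout cadence 62 steps/min, 6 bouts/day of geometric mean length 10 min,
  3 single-minute bursts at 1.5× the day's bout cadence (the P1M signal),
  and ~120 incidental sub-20-step minutes — together ≈ 4480 steps/day,
  P1M ≈ 92, P6MC ≈ 61.
* Recovery follows `level(t) = drop + (1 + gain − drop)(1 − e^{−t/τ})`:
  a drop to 35% of baseline, then saturating recovery. Timescales are 60
  days (MCID+) and 75 days (MCID−), with plateau gains solved so the true
  baseline-crossing days are 33 and 40 — the order of magnitude reported
  for this population. τ = 60 was chosen at design time so that the
  *linear* model's fitted crossing of the steps-scale curve over days
  1..74 sits within half a day of the true crossing; steeper curvature
  (shorter τ) would bias any linear fit late.
* Two multiplicative lognormal noise channels, day volume (CV 0.8) and
  day cadence (CV 0.4), reproduce the observed contrast that daily-steps
  variability is roughly double cadence variability. Noise has median 1
  (not mean 1) so cohort medians sit on the calibration targets and
  multiplicative noise cancels out of baseline-crossing computations.
* A persistent per-patient lognormal level (CV 0.3 on volume, half that
  on the log scale for cadence) supplies the between-patient
  heterogeneity the random intercept absorbs. Recovery is relative to the
  patient's own baseline, so this does not move the true crossing day.
* `recovery_on` selects the generative channel of recovery. The default
  `"both"` (patients walk fewer minutes *and* more slowly) makes daily
  steps scale like `level²` and cadence like `level` — all outcomes still
  cross baseline on the same day. For comparing how early different
  outcomes separate groups, the calibrated world `recovery_on = "cadence"`
  gives every outcome the *same* baseline-relative group effect, so the
  only difference between steps and P6MC is their noise. Under `"both"`,
  steps' doubled relative effect offsets most of their noise penalty and
  the cadence-first ordering holds only ~75% of the time; under the
  equal-effect calibration it is essentially deterministic.
* FJS scores are drawn so labels match the generating group exactly
  (misclassification configurable), and a uniform dropout rate is the
  only missingness mechanism.

What the generator does **not** emulate: wear-time and
missing-not-at-random patterns, within-patient day-to-day correlation of
the noise (days are independent given the curve), autocorrelated
residuals, gait quality, device undercounting at slow speeds, and any
true age or gender effect on activity (the model still estimates
$\beta_4, \beta_5$; their truth is zero). A green end-to-end test
therefore establishes that the pipeline recovers the truth of *this*
stated world — not that the model is robust to realistic wear artefacts.

## Numerical choices

* P6MC window scan: day-major layout padded between days so windows never
  span midnight; invalid slots carry a large negative sentinel rather
  than NA to stay on the rolling-sum fast path. The vectorized cohort
  scan is tested for exact equality against both the one-day
  implementation and an independent exhaustive window scan.
* λ search on a log grid over $[10^{-8}, 10^{6}]$ with the λ = 0 boundary
  checked explicitly; residual variance below `1e-12` of the response
  scale triggers the noiseless branch.
* Bootstrap draws use a Cholesky of the fixed-effect covariance, with an
  eigenvalue fallback for semi-definite matrices from degenerate fits.
* Separation-day monotonicity in the interaction only holds when main
  effect and interaction share a sign; with opposite signs a larger
  interaction can first cancel the contrast. Tests restrict accordingly.
* CSV round-trips are bit-exact for integer fields; cadence values
  round-trip to 15 significant digits (the text representation's printed
  precision).

## Limitations

Beyond the generator's stated idealizations: the linear-day model is a
deliberate simplification of concave recovery (see above); residuals of
multiplicative data fitted additively are heteroscedastic, which the
diagnostics (`residual_diagnostics()`) make visible but the model does
not correct; and the cohort-specific coefficient tables of the motivating
study are not reproducible, since its data are unavailable — the package
validates against known synthetic truth instead.
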
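# stepcadence

Cadence-based digital biomarkers for rehabilitation monitoring after hip
and knee arthroplasty.

Patients recovering from joint replacement are traditionally assessed at
clinic visits; a wrist-worn activity tracker that records **steps per
minute, continuously** turns everyday life into the assessment. This
package implements the full analysis chain for such minute-level step
streams, for biostatisticians and rehabilitation researchers:

* **Per-day digital biomarkers** — daily steps; **P1M** (peak 1-minute
  cadence, the best single-minute effort); **P6MC** (peak 6-minute
  consecutive cadence, the highest mean steps/min over any 6 consecutive
  minutes — a free-living six-minute-walk analogue,
  `max_j (Σ_{i=j..j+5} X_i)/6`); minutes per cadence intensity band
  (sedentary < 20, light 20–99, moderate ≥ 100, vigorous ≥ 130 steps/min),
  after removal of > 150 steps/min device artefacts.
* **Intraweek variability** — per-patient coefficient of variation
  (sd/mean) of each biomarker across the days of each post-operative
  week, aggregated as cohort median [p25; p75]. Cadence metrics are
  markedly more stable than daily steps (~0.4 vs ~0.8).
* **MCID stratification** — patients labelled MCID+/MCID− by whether the
  Forgotten Joint Score change at 3 months reaches the minimal clinically
  important difference (17.5 total hip / 16.6 total knee / 12.5
  unicondylar knee).
* **Recovery trajectories** — a random-intercept linear mixed model,
  `y_it = α + β₁·day + β₂·group + β₃·day×group + β₄·age + β₅·gender
  + a_i + ε_it`, fitted by maximum likelihood after normalizing each
  group to its first-session mean; from it, the **return day** (first day
  the predicted trajectory reaches the pre-operative reference) and the
  **separation day** (first day the Wald 95% CI of the group contrast
  `β₂ + β₃·t` excludes 0), both with parametric-bootstrap CIs.
* **Synthetic cohorts** — a calibrated generator with known ground truth
  (bout-structured minutes, two noise channels, exponential-saturation
  recovery with configurable baseline-crossing days), standing in for the
  proprietary patient data such studies cannot share.
* **CLI pipeline** — `simulate` / `summarize` / `analyze` stages, JSON
  config, one seed governing every draw, byte-identical reruns.

## Worked example

```r
library(stepcadence)

sim <- simulate_cohort(generator_params(
  n_per_group = c(MCID_plus = 30L, MCID_minus = 30L), seed = 42L))
ds  <- summarize_days(sim$streams, sim$meta)

cohort_cv_profile(ds)[week_index == 3]
#>    metric week_index median_cv    p25_cv    p75_cv n_patients
#> 1:    p1m          3 0.3607960 0.2845543 0.4258195         60
#> 2:   p6mc          3 0.4245713 0.3406423 0.5552291         60
#> 3:  steps          3 0.8016294 0.6328234 0.9281643         60
```

Daily steps vary about twice as much from day to day (CV 0.80) as the
cadence peaks (0.36–0.42): cadence is the steadier read on motor
function.

```r
fit <- fit_mixed_model(ds, sim$meta, outcome = "steps",
                       day_range = c(1L, 74L))
fit
#> Random-intercept recovery model (ML)
#>   outcome: steps  groups: MCID_plus vs MCID_minus  days: 1..74
#>              estimate       se
#> (Intercept)  461.9433 455.1719
#> day          135.9865   5.7824
#> group       -924.7737 646.2163
#> day:group    -18.2985   8.1776
#> age_c         17.6829  32.7738
#> gender_c    -751.9455 566.9353
#>   sigma2 = 3.387e+07, mu2 = 4.299e+06, logLik = -44860.5715, n = 4440 obs / 60 patients

pre <- preop_reference(ds, sim$truth$patient_groups, "steps")
time_to_preop_return(fit, pre, "MCID_plus",  n_boot = 1000, seed = 42)
#> return day 36, 95% CI [31, 42]
time_to_preop_return(fit, pre, "MCID_minus", n_boot = 1000, seed = 42)
#> return day 39, 95% CI [33, 46]
group_separation_day(fit, n_boot = 1000, seed = 42)
#> separation from day 14, 95% CI [1, not reached]
```

Read: patients gain ~136 steps/day of activity per post-operative day;
the MCID− group recovers ~18 steps/day more slowly (`day:group`; MCID+ is
the reference). The fitted trajectories reach the pre-operative level on
day 36 (MCID+) vs 39 (MCID−) — this cohort's generating truth was 33 and
40 (`sim$truth$groups$crossing_day`) — and the groups' trajectories
statistically separate from day 14. On the same cohort the lower-noise
P6MC outcome separates the groups earlier than daily steps, the core
rationale for cadence-based monitoring.

The same analysis from a shell:

```sh
Rscript inst/cli/stepcadence.R pipeline --config config.json --out results/
```

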
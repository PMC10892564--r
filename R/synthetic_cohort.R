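# Synthetic rehabilitation cohorts with known ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# pre-operative activity near the cohort medians reported for this
# population (~4477 steps/day, P1M ~92, P6MC ~61 steps/min), a post-operative
# drop followed by exponential-saturation recovery with group-specific
# timescales (MCID+ faster than MCID-), and two separate multiplicative
# noise channels so that day-volume variability (~CV 0.8) is roughly double
# cadence variability (~CV 0.4). Walking happens in multi-minute bouts
# (P6MC is only meaningful inside bouts), single-minute bursts carry the
# P1M signal, and non-bout minutes hold small incidental counts (< 20).

#' Recovery-level curve
#'
#' `level(t) = drop + (1 + gain - drop) * (1 - exp(-t / tau))` for
#' post-operative day `t >= 1`: activity starts at `drop` times baseline,
#' crosses baseline, and saturates at `1 + gain` times baseline.
#'
#' @param t Post-operative day(s).
#' @param drop Fraction of baseline on day ~0.
#' @param gain Plateau excess over baseline.
#' @param tau Recovery timescale in days.
#' @return Activity level as a fraction of baseline.
#' @export
recovery_level <- function(t, drop, gain, tau) {
  drop + (1 + gain - drop) * (1 - exp(-t / tau))
}

#' Solve the plateau gain for a target baseline-crossing day
#'
#' Returns the `gain` for which `recovery_level(crossing_day, ...) = 1`
#' exactly, so the smallest integer day at or above baseline is
#' `crossing_day`.
#'
#' @param crossing_day Target first day at/above baseline.
#' @param drop,tau See [recovery_level()].
#' @return The plateau gain (may exceed 1 for slow timescales).
#' @export
calibrate_gain <- function(crossing_day, drop, tau) {
  drop - 1 + (1 - drop) / (1 - exp(-crossing_day / tau))
}

#' Parameters of the synthetic-cohort generator
#'
#' Defaults state the emulated world: Table-3-style pre-operative medians
#' (bout cadence 62 steps/min with 1.5x single-minute bursts gives P6MC ~61
#' and P1M ~92; 6 bouts/day x 10 min plus bursts and incidental movement
#' gives ~4480 steps/day), lognormal day noise with CV 0.8 on volume and
#' 0.4 on cadence (median-1 parameterization, so cohort medians sit on the
#' targets), drop to 35% of baseline after surgery, and recovery timescales
#' 60 / 75 days with plateau gains solved so the true baseline-crossing
#' days are 33 (MCID+) and 40 (MCID-).
#'
#' @param n_per_group Named integer vector of patients per recovery group.
#' @param joint `"hip"` or `"knee"`.
#' @param surgery_type Length-1, or named per group (e.g.
#'   `c(total = ..., unicondylar = ...)` for surgery-type contrasts).
#' @param preop_days,followup_days Days recorded before / after surgery.
#' @param surgery_date Common surgery date (determinism; day alignment is
#'   translation-equivariant so the value is immaterial).
#' @param cadence_target Within-bout walking cadence at baseline, steps/min.
#' @param burst_ratio Single-minute burst cadence as a multiple of the
#'   day's bout cadence (carries the P1M signal).
#' @param n_bursts Burst minutes per day.
#' @param bout_rate Mean walking bouts per day at baseline.
#' @param bout_duration_mean Mean bout duration, minutes (geometric).
#' @param cadence_sd_within_bout Per-minute cadence SD inside a bout.
#' @param incidental_minutes Mean non-bout movement minutes per day at
#'   baseline (counts < 20 steps/min, i.e. sedentary-band).
#' @param steps_noise_cv Lognormal CV of the day-volume multiplier.
#' @param cadence_noise_cv Lognormal CV of the day-cadence multiplier.
#' @param patient_level_cv Lognormal CV of a persistent per-patient
#'   activity multiplier (applied to volume and cadence alike) — the
#'   between-patient heterogeneity the model's random intercept absorbs.
#'   A patient's own recovery is relative to their own baseline, so this
#'   does not move the true crossing day.
#' @param recovery_on Which generative channel the recovery-level curve
#'   multiplies. `"both"` (default): patients walk fewer minutes and more
#'   slowly after surgery, so daily steps scale like `level^2` while the
#'   cadence metrics scale like `level`. `"cadence"` or `"volume"`: the
#'   curve acts through one channel only, giving every outcome the same
#'   baseline-relative group effect — the calibration used when comparing
#'   how early different outcomes separate recovery groups.
#' @param postop_drop Fraction of baseline activity at day ~0.
#' @param recovery_timescale Named per group, days.
#' @param crossing_days Named per group: true first day at/above baseline;
#'   used to solve `plateau_gain` when the latter is `NULL`.
#' @param plateau_gain Named per group, or `NULL` to calibrate from
#'   `crossing_days`.
#' @param age_mean,age_sd,female_fraction,bmi_mean,bmi_sd Demographics.
#' @param fjs_pre_mean,fjs_pre_sd Pre-operative Forgotten Joint Score.
#' @param misclassification_rate Probability that a patient's FJS change is
#'   drawn from the other group's distribution (label noise; default 0).
#' @param dropout_rate Probability that a day is not recorded at all
#'   (simple uniform non-wear; default 0).
#' @param inject_outliers If `TRUE`, sprinkle device-artefact minutes
#'   (> 150 steps) at `outlier_rate` per minute-slot for QC fault testing.
#' @param outlier_rate Expected artefact minutes per day when injecting.
#' @param seed Integer seed governing every random draw.
#' @return A validated `generator_params` object.
#' @export
generator_params <- function(n_per_group = c(MCID_plus = 40L, MCID_minus = 40L),
                             joint = "hip",
                             surgery_type = "total",
                             preop_days = 14L,
                             followup_days = 74L,
                             surgery_date = as.Date("2023-03-01"),
                             cadence_target = 62,
                             burst_ratio = 1.5,
                             n_bursts = 3L,
                             bout_rate = 6,
                             bout_duration_mean = 10,
                             cadence_sd_within_bout = 5,
                             incidental_minutes = 120,
                             steps_noise_cv = 0.8,
                             cadence_noise_cv = 0.4,
                             patient_level_cv = 0.3,
                             recovery_on = c("both", "volume", "cadence"),
                             postop_drop = 0.35,
                             recovery_timescale = c(MCID_plus = 60, MCID_minus = 75),
                             crossing_days = c(MCID_plus = 33, MCID_minus = 40),
                             plateau_gain = NULL,
                             age_mean = 62, age_sd = 10,
                             female_fraction = 0.51,
                             bmi_mean = 29, bmi_sd = 5,
                             fjs_pre_mean = 12, fjs_pre_sd = 6,
                             misclassification_rate = 0,
                             dropout_rate = 0,
                             inject_outliers = FALSE,
                             outlier_rate = 0.5,
                             seed = 1L) {
  groups <- names(n_per_group)
  if (is.null(groups) || any(!nzchar(groups)))
    stop("n_per_group must be a named vector (one entry per group)")
  if (!setequal(groups, names(recovery_timescale)))
    stop("recovery_timescale must be named by the same groups as n_per_group")
  if (is.null(plateau_gain)) {
    if (!setequal(groups, names(crossing_days)))
      stop("crossing_days must be named by group")
    plateau_gain <- vapply(groups, function(g)
      calibrate_gain(crossing_days[[g]], postop_drop,
                     recovery_timescale[[g]]), numeric(1L))
  } else if (!setequal(groups, names(plateau_gain))) {
    stop("plateau_gain must be named by group")
  }
  if (length(surgery_type) == 1L)
    surgery_type <- setNames(rep(surgery_type, length(groups)), groups)
  if (!setequal(groups, names(surgery_type)))
    stop("surgery_type must be length 1 or named by group")
  p <- list(n_per_group = n_per_group, groups = groups, joint = joint,
            surgery_type = surgery_type, preop_days = as.integer(preop_days),
            followup_days = as.integer(followup_days),
            surgery_date = data.table::as.IDate(surgery_date),
            cadence_target = cadence_target, burst_ratio = burst_ratio,
            n_bursts = as.integer(n_bursts), bout_rate = bout_rate,
            bout_duration_mean = bout_duration_mean,
            cadence_sd_within_bout = cadence_sd_within_bout,
            incidental_minutes = incidental_minutes,
            steps_noise_cv = steps_noise_cv,
            cadence_noise_cv = cadence_noise_cv,
            patient_level_cv = patient_level_cv,
            recovery_on = match.arg(recovery_on),
            postop_drop = postop_drop,
            recovery_timescale = recovery_timescale[groups],
            plateau_gain = plateau_gain[groups],
            age_mean = age_mean, age_sd = age_sd,
            female_fraction = female_fraction,
            bmi_mean = bmi_mean, bmi_sd = bmi_sd,
            fjs_pre_mean = fjs_pre_mean, fjs_pre_sd = fjs_pre_sd,
            misclassification_rate = misclassification_rate,
            dropout_rate = dropout_rate,
            inject_outliers = isTRUE(inject_outliers),
            outlier_rate = outlier_rate, seed = as.integer(seed))
  with(p, {
    stopifnot(all(n_per_group >= 1L), joint %in% VALID_JOINTS,
              all(surgery_type %in% VALID_SURGERY_TYPES),
              preop_days >= 0L, followup_days >= 1L,
              cadence_target > 0, burst_ratio >= 1, n_bursts >= 0L,
              bout_rate > 0, bout_duration_mean >= 1,
              cadence_sd_within_bout >= 0, incidental_minutes >= 0,
              steps_noise_cv >= 0, cadence_noise_cv >= 0,
              patient_level_cv >= 0,
              postop_drop > 0, postop_drop < 1,
              all(recovery_timescale > 0), all(plateau_gain > -1),
              female_fraction >= 0, female_fraction <= 1,
              misclassification_rate >= 0, misclassification_rate <= 1,
              dropout_rate >= 0, dropout_rate < 1, outlier_rate >= 0)
  })
  structure(p, class = "generator_params")
}

#' Ground truth implied by generator parameters
#'
#' Deterministic function of the parameters (no simulation): per-group
#' recovery-curve parameters and true baseline-crossing day (the outcome
#' trajectories all scale with the same level curve, so they share it), the
#' expected pre-operative value of each outcome, and the between-group mean
#' slope difference of each outcome over the post-operative day range.
#'
#' @param params A [generator_params()] object.
#' @return A list with `groups` (a `data.table`), `preop_expected`, and
#'   `slope_diff` (first group minus second, when two groups exist).
#' @export
truth_report <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  g <- params$groups
  d <- params$postop_drop
  gain <- params$plateau_gain
  tau <- params$recovery_timescale
  frac <- (1 - d) / (1 + gain - d)
  # smallest integer t with level(t) >= 1; the 1e-9 slack keeps a curve
  # calibrated to hit baseline exactly at an integer day from rounding up
  cross <- ifelse(frac < 1, ceiling(-tau * log(1 - frac) - 1e-9), Inf)
  groups <- data.table::data.table(group = g, drop = d, gain = unname(gain),
                                   tau = unname(tau),
                                   crossing_day = as.numeric(cross))
  preop <- list(
    steps = params$bout_rate * params$bout_duration_mean * params$cadence_target +
      params$n_bursts * params$burst_ratio * params$cadence_target +
      params$incidental_minutes * 4,
    p6mc = params$cadence_target,
    p1m = params$burst_ratio * params$cadence_target)
  slope_diff <- NULL
  if (length(g) >= 2L) {
    days <- seq_len(params$followup_days)
    dm <- function(i) (1 + gain[[i]] - d) / tau[[i]] * exp(-days / tau[[i]])
    m <- function(i) recovery_level(days, d, gain[[i]], tau[[i]])
    gap_level <- mean(dm(1L) - dm(2L))
    # daily steps scale with level^e, e = 2 when recovery acts on volume
    # and cadence together, 1 when on a single channel
    e_steps <- if (params$recovery_on == "both") 2 else 1
    gap_steps <- if (e_steps == 2)
      mean(2 * m(1L) * dm(1L) - 2 * m(2L) * dm(2L)) else gap_level
    cad_on <- params$recovery_on %in% c("both", "cadence")
    slope_diff <- list(level = gap_level,
                       steps = preop$steps * gap_steps,
                       p6mc = preop$p6mc * (if (cad_on) gap_level else 0),
                       p1m = preop$p1m * (if (cad_on) gap_level else 0))
  }
  list(groups = groups, preop_expected = preop, slope_diff = slope_diff)
}

# lognormal multiplier with median 1 and coefficient of variation cv
rlnorm_med1 <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  exp(stats::rnorm(n, 0, sqrt(log1p(cv^2))))
}

# truncated-normal draws via inverse CDF (vectorized)
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd); pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + stats::runif(n) * (pu - pl), mean, sd)
}

#' Simulate a rehabilitation cohort with known ground truth
#'
#' Generates minute-level step streams and patient metadata under
#' [generator_params()]; reproducible to the byte under a fixed seed.
#' See the package vignette for the generative model and what it does and
#' does not emulate.
#'
#' @param params A [generator_params()] object.
#' @return A list with `streams` (minute records), `meta` (patient
#'   metadata), `truth` (see [truth_report()]), `params`, and — when
#'   outlier injection is on — `injected_outliers`.
#' @export
simulate_cohort <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed)
  p <- params

  # ---- patients -----------------------------------------------------------
  n_tot <- sum(p$n_per_group)
  group <- rep(p$groups, p$n_per_group)
  pid <- sprintf("P%04d", seq_len(n_tot))
  thr <- mcid_threshold(rep(p$joint, n_tot), p$surgery_type[group])
  if (anyNA(thr) && p$misclassification_rate == 0 &&
      all(p$groups %in% c("MCID_plus", "MCID_minus")))
    stop("surgery_type without an MCID threshold cannot carry recovery groups")
  fjs_pre <- pmin(pmax(round(stats::rnorm(n_tot, p$fjs_pre_mean, p$fjs_pre_sd)), 0), 40)
  flip <- stats::runif(n_tot) < p$misclassification_rate
  eff_group <- ifelse(xor(group == "MCID_plus", flip), "MCID_plus", "MCID_minus")
  delta <- numeric(n_tot)
  is_plus <- eff_group == "MCID_plus"
  thr_fill <- data.table::fifelse(is.na(thr), 17.5, thr)
  delta[is_plus] <- rtruncnorm(sum(is_plus), 30, 8, lower = thr_fill[is_plus])
  delta[!is_plus] <- rtruncnorm(sum(!is_plus), 8, 5, upper = thr_fill[!is_plus] - 0.1)
  fjs_3m <- pmin(pmax(round(fjs_pre + delta, 1), 0), 100)
  meta <- data.table::data.table(
    patient_id = pid, joint = p$joint,
    surgery_type = unname(p$surgery_type[group]),
    surgery_date = p$surgery_date,
    age = round(stats::rnorm(n_tot, p$age_mean, p$age_sd), 1),
    gender = ifelse(stats::runif(n_tot) < p$female_fraction, "female", "male"),
    bmi = round(stats::rnorm(n_tot, p$bmi_mean, p$bmi_sd), 1),
    fjs_pre = fjs_pre, fjs_3m = fjs_3m)
  meta[age < 18, age := 18]
  truth_groups <- data.table::data.table(patient_id = pid, group = group)
  pat_mult <- rlnorm_med1(n_tot, p$patient_level_cv)   # persistent level

  # ---- day grid -----------------------------------------------------------
  dpo <- c(seq.int(-p$preop_days, -1L), seq_len(p$followup_days))
  if (p$preop_days == 0L) dpo <- seq_len(p$followup_days)
  days <- data.table::CJ(patient_id = pid, day_post_op = dpo)
  days <- merge(days, truth_groups, by = "patient_id")
  if (p$dropout_rate > 0)
    days <- days[stats::runif(.N) >= p$dropout_rate]
  days[, date := p$surgery_date + day_post_op]
  lvl <- rep(1, nrow(days))
  post <- days$day_post_op >= 1L
  gi <- match(days$group, p$groups)
  lvl[post] <- recovery_level(days$day_post_op[post], p$postop_drop,
                              p$plateau_gain[gi[post]],
                              p$recovery_timescale[gi[post]])
  pm <- pat_mult[match(days$patient_id, pid)]
  lvl_vol <- if (p$recovery_on %in% c("both", "volume")) lvl else rep(1, nrow(days))
  lvl_cad <- if (p$recovery_on %in% c("both", "cadence")) lvl else rep(1, nrow(days))
  # cadence is physiologically constrained: half the patient-level spread
  # (on the log scale) of day volume
  days[, `:=`(vol_mult = pm * lvl_vol * rlnorm_med1(.N, p$steps_noise_cv),
              cad_mult = sqrt(pm) * lvl_cad * rlnorm_med1(.N, p$cadence_noise_cv))]
  days[, c_day := p$cadence_target * cad_mult]
  days[, day_id := .I]

  clip_steps <- function(x) pmin(pmax(as.integer(round(x)), 0L), 150L)

  # ---- walking bouts ------------------------------------------------------
  n_bouts <- stats::rpois(nrow(days), p$bout_rate * days$vol_mult)
  bouts <- days[rep(seq_len(.N), n_bouts),
                .(day_id, patient_id, date, c_day)]
  if (nrow(bouts)) {
    dur <- 1L + stats::rgeom(nrow(bouts), 1 / p$bout_duration_mean)
    dur <- pmin(dur, 120L)
    start <- 420L + floor(stats::runif(nrow(bouts)) * (1320L - 420L - dur))
    mins <- bouts[rep(seq_len(.N), dur), .(day_id, patient_id, date, c_day)]
    mins[, minute_of_day := as.integer(rep(start, dur) + (sequence(dur) - 1L))]
    mins[, steps := clip_steps(stats::rnorm(.N, c_day, p$cadence_sd_within_bout))]
    bout_minutes <- mins[, .(day_id, patient_id, date, minute_of_day, steps)]
  } else {
    bout_minutes <- days[0L, .(day_id, patient_id, date,
                               minute_of_day = integer(0), steps = integer(0))]
  }

  # ---- single-minute cadence bursts (P1M signal) --------------------------
  if (p$n_bursts > 0L) {
    bursts <- days[rep(seq_len(.N), each = p$n_bursts),
                   .(day_id, patient_id, date, c_day)]
    bursts[, minute_of_day := as.integer(420L + floor(stats::runif(.N) * 900L))]
    bursts[, steps := clip_steps(stats::rnorm(.N, c_day * p$burst_ratio,
                                              p$cadence_sd_within_bout))]
    bursts <- bursts[, .(day_id, patient_id, date, minute_of_day, steps)]
  } else bursts <- bout_minutes[0L]

  # ---- incidental movement minutes (< 20 steps) ---------------------------
  n_inc <- stats::rpois(nrow(days), p$incidental_minutes * pmin(days$vol_mult, 3))
  inc <- days[rep(seq_len(.N), n_inc), .(day_id, patient_id, date)]
  if (nrow(inc)) {
    inc[, minute_of_day := as.integer(floor(stats::runif(.N) * 1440))]
    inc[, steps := pmin(1L + stats::rpois(.N, 3), 19L)]
  } else inc[, `:=`(minute_of_day = integer(0), steps = integer(0))]

  stream <- data.table::rbindlist(list(bout_minutes, bursts, inc),
                                  use.names = TRUE)

  # ---- optional device-artefact injection ---------------------------------
  injected <- NULL
  if (p$inject_outliers) {
    n_out <- stats::rpois(nrow(days), p$outlier_rate)
    out <- days[rep(seq_len(.N), n_out), .(day_id, patient_id, date)]
    if (nrow(out)) {
      out[, minute_of_day := as.integer(floor(stats::runif(.N) * 1440))]
      out[, steps := 151L + stats::rpois(.N, 40)]
      out <- unique(out, by = c("day_id", "minute_of_day"))
      injected <- out[, .(patient_id, date, minute_of_day)]
      stream <- data.table::rbindlist(list(stream, out), use.names = TRUE)
    }
  }

  # collisions: a minute can be claimed twice (overlapping bouts, bursts,
  # incidental); the most intense activity wins
  stream <- stream[, .(steps = max(steps)),
                   by = .(patient_id, date, minute_of_day)]
  data.table::setkeyv(stream, c("patient_id", "date", "minute_of_day"))

  out <- list(streams = stream[], meta = validate_metadata(meta),
              truth = c(truth_report(p),
                        list(patient_groups = truth_groups)),
              params = p)
  if (!is.null(injected)) out$injected_outliers <- injected
  out
}
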
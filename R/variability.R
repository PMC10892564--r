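# Intraweek variability of the daily biomarkers.
#
# A stable biomarker should read similarly from one day of a week to the
# next. Variability is quantified per patient and post-operative week as
# the coefficient of variation (sd/mean) across the days of that week,
# then aggregated across the cohort as median [p25; p75] — the skew-aware
# reporting style used for these metrics.

#' Intraweek coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean of up
#' to 7 daily values. Undefined (`NA`) when fewer than `min_days` finite
#' values are available or the mean is not positive. Scale-invariant:
#' multiplying all values by a positive constant leaves the CV unchanged.
#'
#' @param values Numeric vector of daily values for one patient-week.
#' @param min_days Minimum number of finite values required (default 4).
#' @return The CV (dimensionless), or `NA_real_` when undefined.
#' @export
intraweek_cv <- function(values, min_days = 4L) {
  v <- values[is.finite(values)]
  if (length(v) < min_days) return(NA_real_)
  m <- mean(v)
  if (m <= 0) return(NA_real_)
  stats::sd(v) / m
}

#' Per-patient weekly CVs of the daily biomarkers
#'
#' @param day_summaries Day summaries with `day_post_op` (post-operative
#'   days only are used; weeks are surgery-anchored 7-day bins as in
#'   [weekly_intensity()]).
#' @param metrics Which day-summary columns to assess.
#' @param min_days Passed to [intraweek_cv()].
#' @return A `data.table` with `patient_id`, `week_index`, `metric`, `cv`,
#'   `n_days`; rows with undefined CV are dropped.
#' @export
patient_week_cv <- function(day_summaries,
                            metrics = c("steps", "p1m", "p6mc"),
                            min_days = 4L) {
  dt <- data.table::as.data.table(day_summaries)
  stopifnot(all(metrics %in% names(dt)))
  dt <- dt[day_post_op >= 1L]
  dt[, week_index := postop_week(day_post_op)]
  dt[, (metrics) := lapply(.SD, as.numeric), .SDcols = metrics]
  long <- data.table::melt(
    dt[, c("patient_id", "week_index", metrics), with = FALSE],
    id.vars = c("patient_id", "week_index"),
    variable.name = "metric", value.name = "value",
    variable.factor = FALSE)
  out <- long[, .(cv = intraweek_cv(value, min_days),
                  n_days = sum(is.finite(value))),
              by = .(patient_id, week_index, metric)]
  out[!is.na(cv)]
}

#' Cohort intraweek-variability profile
#'
#' Median and interquartile range, across patients, of the per-patient
#' intraweek CV of each biomarker, by post-operative week. This is the
#' per-patient-then-median aggregation (CVs are computed within patient
#' first, never by pooling days across patients).
#'
#' @inheritParams patient_week_cv
#' @return A `data.table` with `metric`, `week_index`, `median_cv`,
#'   `p25_cv`, `p75_cv`, `n_patients`.
#' @export
cohort_cv_profile <- function(day_summaries,
                              metrics = c("steps", "p1m", "p6mc"),
                              min_days = 4L) {
  per <- patient_week_cv(day_summaries, metrics, min_days)
  if (nrow(per) == 0L)
    stop("no patient-week has enough days for a CV")
  out <- per[, .(median_cv = stats::median(cv),
                 p25_cv = unname(stats::quantile(cv, 0.25)),
                 p75_cv = unname(stats::quantile(cv, 0.75)),
                 n_patients = .N),
             by = .(metric, week_index)]
  data.table::setorderv(out, c("metric", "week_index"))
  out[]
}
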
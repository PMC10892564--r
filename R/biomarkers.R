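# Per-day digital biomarkers from a cleaned minute stream.
#
# All metrics share one cleaned substrate: minutes whose step count exceeds
# the outlier cutoff (default 150 steps/min, implausible for an arthroplasty
# rehabilitation population) are removed first. Minutes absent from the
# stream count as 0 steps inside P6MC windows (inactivity), but minutes
# removed as outliers invalidate any window containing them — a measurement
# error must not masquerade as rest.

#' Cadence thresholds for intensity bands and outlier removal
#'
#' Cadence is a proxy of ambulatory intensity: moderate intensity
#' (>= 3 METs) corresponds to about 100 steps/min, incidental movement below
#' 20 steps/min is counted as sedentary behaviour. Bands are half-open:
#' sedentary `[0, 20)`, light `[20, 100)`, moderate `[100, 130)`, vigorous
#' `[130, outlier_cutoff]`, so a minute at exactly 100 steps/min is
#' moderate and one at exactly 130 is vigorous.
#'
#' @param sedentary_upper Upper bound (exclusive) of the sedentary band,
#'   steps/min. Default 20.
#' @param moderate_lower Lower bound (inclusive) of the moderate band,
#'   steps/min. Default 100.
#' @param vigorous_lower Lower bound (inclusive) of the vigorous band,
#'   steps/min. Default 130.
#' @param outlier_cutoff Step-per-minute values strictly above this are
#'   treated as device artefacts and removed. Default 150.
#' @return An object of class `intensity_thresholds`.
#' @export
intensity_thresholds <- function(sedentary_upper = 20, moderate_lower = 100,
                                 vigorous_lower = 130, outlier_cutoff = 150) {
  th <- list(sedentary_upper = sedentary_upper,
             moderate_lower = moderate_lower,
             vigorous_lower = vigorous_lower,
             outlier_cutoff = outlier_cutoff)
  if (!(0 < sedentary_upper && sedentary_upper < moderate_lower &&
        moderate_lower < vigorous_lower && vigorous_lower <= outlier_cutoff))
    stop("thresholds must satisfy 0 < sedentary_upper < moderate_lower < ",
         "vigorous_lower <= outlier_cutoff")
  structure(th, class = "intensity_thresholds")
}

#' Remove outlier minutes from one patient-day of minute records
#'
#' Minutes whose step count strictly exceeds `thresholds$outlier_cutoff`
#' are removed and recorded; all other minutes are unchanged. Idempotent.
#'
#' @param stream One patient-day of minute records: a data.frame with
#'   `minute_of_day` and `steps`, or an existing `cleaned_day`.
#' @param thresholds An [intensity_thresholds()] object.
#' @return A `cleaned_day` object: a list with `minutes` (a `data.table`
#'   sorted by `minute_of_day`) and `removed` (integer vector of removed
#'   `minute_of_day` values).
#' @export
remove_outliers <- function(stream, thresholds = intensity_thresholds()) {
  if (inherits(stream, "cleaned_day")) {
    prev <- stream$removed
    stream <- stream$minutes
  } else {
    prev <- integer(0)
  }
  dt <- data.table::as.data.table(stream)
  stopifnot(all(c("minute_of_day", "steps") %in% names(dt)))
  data.table::setorderv(dt, "minute_of_day")
  out <- dt$steps > thresholds$outlier_cutoff
  structure(list(minutes = dt[!out],
                 removed = sort(unique(c(prev, dt$minute_of_day[out])))),
            class = "cleaned_day")
}

as_cleaned_day <- function(stream, thresholds = intensity_thresholds()) {
  if (inherits(stream, "cleaned_day")) stream else remove_outliers(stream, thresholds)
}

#' Total steps accumulated in a day
#'
#' Sum of steps over retained minutes of the cleaned stream (0 for an
#' empty stream). Computed from the minute stream after outlier removal,
#' not from a device daily counter, so all metrics share one substrate.
#'
#' @param stream A `cleaned_day` (or raw minute table, cleaned on the fly).
#' @param thresholds An [intensity_thresholds()] object.
#' @return A non-negative integer.
#' @export
daily_steps <- function(stream, thresholds = intensity_thresholds()) {
  cd <- as_cleaned_day(stream, thresholds)
  sum(cd$minutes$steps)
}

#' Peak 1-minute cadence (P1M)
#'
#' The highest step count within any single minute of the day — the
#' free-living walking cadence of which the patient is capable, an
#' indicator of maximal exertion bursts.
#'
#' @inheritParams daily_steps
#' @return Steps/min, or `NA` for an empty (fully removed) day.
#' @export
peak_1min <- function(stream, thresholds = intensity_thresholds()) {
  cd <- as_cleaned_day(stream, thresholds)
  if (nrow(cd$minutes) == 0L) return(NA_real_)
  as.numeric(max(cd$minutes$steps))
}

#' Peak 6-minute consecutive cadence (P6MC)
#'
#' The highest mean cadence over any 6 consecutive minutes of the day,
#' computed with a sliding 6-minute window advancing one minute at a time
#' over every start minute `j`, `0 <= j <= 1434`. The result is a mean
#' cadence in steps/min, so P6MC <= P1M always. Minutes absent from the
#' stream count as 0 steps inside a window; windows containing an
#' outlier-removed minute are invalid.
#'
#' @inheritParams daily_steps
#' @return Steps/min, or `NA` when no valid 6-minute window exists.
#' @export
peak_6min_consecutive <- function(stream, thresholds = intensity_thresholds()) {
  cd <- as_cleaned_day(stream, thresholds)
  if (nrow(cd$minutes) == 0L) return(NA_real_)   # no data at all is not rest
  x <- numeric(1440L)
  x[cd$minutes$minute_of_day + 1L] <- cd$minutes$steps
  x[cd$removed + 1L] <- NA_real_
  ws <- data.table::frollsum(x, 6L, align = "left")[seq_len(1435L)]
  if (all(is.na(ws))) return(NA_real_)
  max(ws, na.rm = TRUE) / 6
}

#' Minutes spent in each cadence intensity band
#'
#' Each retained minute is assigned to exactly one band (see
#' [intensity_thresholds()] for the boundary conventions); the four counts
#' always sum to the number of retained minutes.
#'
#' @inheritParams daily_steps
#' @return A named integer vector `(sedentary, light, moderate, vigorous)`.
#' @export
intensity_minutes <- function(stream, thresholds = intensity_thresholds()) {
  cd <- as_cleaned_day(stream, thresholds)
  s <- cd$minutes$steps
  c(sedentary = sum(s < thresholds$sedentary_upper),
    light = sum(s >= thresholds$sedentary_upper & s < thresholds$moderate_lower),
    moderate = sum(s >= thresholds$moderate_lower & s < thresholds$vigorous_lower),
    vigorous = sum(s >= thresholds$vigorous_lower))
}

#' Summarize one patient-day of minute records
#'
#' Applies [remove_outliers()] and then every biomarker; QC counts record
#' how many minutes were retained and removed. For a fully removed day the
#' cadence metrics are `NA` sentinels (the day is excluded downstream).
#'
#' @param stream One patient-day of minute records (optionally with
#'   `patient_id`, `date`, `day_post_op` columns, which are carried over).
#' @param thresholds An [intensity_thresholds()] object.
#' @return A one-row `data.table` with the day-summary columns.
#' @export
summarize_day <- function(stream, thresholds = intensity_thresholds()) {
  raw <- data.table::as.data.table(stream)
  cd <- as_cleaned_day(raw, thresholds)
  bands <- intensity_minutes(cd, thresholds)
  one <- function(col, default) if (col %in% names(raw) && nrow(raw)) raw[[col]][1L] else default
  data.table::data.table(
    patient_id = as.character(one("patient_id", NA_character_)),
    date = data.table::as.IDate(one("date", NA)),
    day_post_op = as.integer(one("day_post_op", NA_integer_)),
    steps = daily_steps(cd, thresholds),
    p1m = peak_1min(cd, thresholds),
    p6mc = peak_6min_consecutive(cd, thresholds),
    min_sedentary = as.integer(bands[["sedentary"]]),
    min_light = as.integer(bands[["light"]]),
    min_moderate = as.integer(bands[["moderate"]]),
    min_vigorous = as.integer(bands[["vigorous"]]),
    n_minutes_recorded = nrow(cd$minutes),
    n_outliers_removed = length(cd$removed))
}

#' Summarize every patient-day of a cohort minute stream
#'
#' Vectorized equivalent of applying [summarize_day()] to each patient-day
#' (the equivalence is a tested property). The P6MC window scan runs on a
#' padded day-major layout so windows never cross midnight.
#'
#' @param records Minute records (as from [read_minute_csv()]); must carry
#'   `day_post_op` (see [align_to_surgery()]) unless `meta` is supplied.
#' @param meta Optional patient metadata used to align records to surgery.
#' @param thresholds An [intensity_thresholds()] object.
#' @return A day-summary `data.table`, one row per patient-day present in
#'   `records`, keyed by patient and date.
#' @export
summarize_days <- function(records, meta = NULL,
                           thresholds = intensity_thresholds()) {
  dt <- data.table::as.data.table(records)
  if (!"day_post_op" %in% names(dt)) {
    if (is.null(meta))
      stop("records lack day_post_op and no metadata was supplied")
    dt <- align_to_surgery(dt, meta)
  }
  if (nrow(dt) == 0L) stop("no minute records to summarize")
  dt <- data.table::copy(dt)
  data.table::setorderv(dt, c("patient_id", "date", "minute_of_day"))
  dt[, day_id := .GRP, by = .(patient_id, date)]
  n_days <- dt[.N, day_id]
  th <- thresholds
  retained <- dt$steps <= th$outlier_cutoff

  per_day <- dt[, {
    ret <- steps <= th$outlier_cutoff
    s <- steps[ret]
    .(day_post_op = day_post_op[1L],
      steps = sum(s),
      p1m = if (length(s)) as.numeric(max(s)) else NA_real_,
      min_sedentary = sum(s < th$sedentary_upper),
      min_light = sum(s >= th$sedentary_upper & s < th$moderate_lower),
      min_moderate = sum(s >= th$moderate_lower & s < th$vigorous_lower),
      min_vigorous = sum(s >= th$vigorous_lower),
      n_minutes_recorded = length(s),
      n_outliers_removed = sum(!ret))
  }, by = .(patient_id, date, day_id)]

  # P6MC: day-major vector with 5 pad slots after each day so no window
  # spans two days. Pads and outlier minutes get a large negative sentinel
  # (not NA, which would force frollsum off its fast path): any window
  # touching one sums far below zero and can never win the max.
  width <- 1445L
  poison <- -1e9
  x <- numeric(n_days * width)
  pad <- rep((seq_len(n_days) - 1L) * width, each = 5L) +
    rep(1441:1445, times = n_days)
  x[pad] <- poison
  pos <- (dt$day_id - 1L) * width + dt$minute_of_day + 1L
  x[pos[retained]] <- dt$steps[retained]
  x[pos[!retained]] <- poison
  ws <- data.table::frollsum(x, 6L, align = "left")
  ws[(length(ws) - 4L):length(ws)] <- poison   # trailing incomplete windows
  m <- matrix(ws, nrow = width)
  idx <- max.col(t(m), ties.method = "first")
  best <- m[cbind(idx, seq_len(n_days))]
  p6 <- ifelse(best > poison / 2, best / 6, NA_real_)

  per_day[, p6mc := p6[day_id]]
  per_day[n_minutes_recorded == 0L, p6mc := NA_real_]  # fully removed day
  per_day[, day_id := NULL]
  data.table::setcolorder(per_day, DAY_SUMMARY_COLS)
  data.table::setkeyv(per_day, c("patient_id", "date"))
  per_day[]
}

#' Post-operative week index of a post-operative day
#'
#' Week `k` covers days `7k - 6 .. 7k` after surgery (`k >= 1`); day 0 and
#' pre-operative days map to `NA`.
#'
#' @param day_post_op Integer vector of surgery-relative days.
#' @return Integer week indices.
#' @export
postop_week <- function(day_post_op) {
  w <- (as.integer(day_post_op) + 6L) %/% 7L
  w[day_post_op < 1L] <- NA_integer_
  w
}

#' Weekly intensity minutes per patient
#'
#' Aggregates daily intensity-band minutes into minutes per post-operative
#' week (the scale on which physical-activity recommendations are stated).
#' Weeks with fewer than 7 recorded days are flagged incomplete; weeks with
#' no recorded days are absent.
#'
#' @param day_summaries Day summaries annotated with `day_post_op`.
#' @return A `data.table` with `patient_id`, `week_index`, summed
#'   `min_light`, `min_moderate`, `min_vigorous`, `n_days`, and a logical
#'   `complete` flag.
#' @export
weekly_intensity <- function(day_summaries) {
  dt <- data.table::as.data.table(day_summaries)
  dt <- dt[day_post_op >= 1L]
  dt[, week_index := postop_week(day_post_op)]
  out <- dt[, .(min_light = sum(min_light),
                min_moderate = sum(min_moderate),
                min_vigorous = sum(min_vigorous),
                n_days = .N),
            by = .(patient_id, week_index)]
  out[, complete := n_days == 7L]
  data.table::setorderv(out, c("patient_id", "week_index"))
  out[]
}
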
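# Fixture builders (all fixtures are constructed in code).

day_stream <- function(minute_of_day, steps, patient_id = "P1",
                       date = as.Date("2023-03-10")) {
  data.table::data.table(patient_id = patient_id,
                         date = data.table::as.IDate(date),
                         minute_of_day = as.integer(minute_of_day),
                         steps = as.integer(steps))
}

# a day with one constant-cadence bout and otherwise explicit zeros
bout_day <- function(cadence, start = 600, len = 30, fill_zero = FALSE) {
  mins <- start:(start + len - 1)
  st <- rep(cadence, len)
  if (fill_zero) {
    rest <- setdiff(0:1439, mins)
    mins <- c(mins, rest); st <- c(st, rep(0, length(rest)))
    o <- order(mins); mins <- mins[o]; st <- st[o]
  }
  day_stream(mins, st)
}

random_stream <- function(seed, n = 1440, max_steps = 170) {
  set.seed(seed)
  mins <- if (n >= 1440) 0:1439 else sort(sample(0:1439, n))
  # right-skewed: mostly small counts, occasional walking and artefacts
  steps <- pmin(rpois(length(mins), 8) +
                  rbinom(length(mins), 1, 0.15) * sample(40:max_steps,
                                                         length(mins),
                                                         replace = TRUE),
                max_steps)
  day_stream(mins, steps)
}

tiny_meta <- function(patient_id = "P1", joint = "hip",
                      surgery_type = "total",
                      surgery_date = as.Date("2023-03-15"),
                      age = 62, gender = "female", bmi = 29,
                      fjs_pre = 10, fjs_3m = 30) {
  data.table::data.table(patient_id = patient_id, joint = joint,
                         surgery_type = surgery_type,
                         surgery_date = data.table::as.IDate(surgery_date),
                         age = age, gender = gender, bmi = bmi,
                         fjs_pre = fjs_pre, fjs_3m = fjs_3m)
}

# small calibrated cohort for pipeline-level tests
small_cohort <- function(seed, n = 10L, followup = 40L, ...) {
  simulate_cohort(generator_params(
    n_per_group = c(MCID_plus = n, MCID_minus = n),
    followup_days = followup, seed = seed, ...))
}
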
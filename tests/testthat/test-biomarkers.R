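test_that("outlier removal retains 150, removes above, and is idempotent", {
  st <- day_stream(c(600, 601, 602, 603), c(80, 160, 90, 150))
  cd <- remove_outliers(st)
  expect_equal(cd$minutes$minute_of_day, c(600, 602, 603))
  expect_equal(cd$removed, 601L)            # 150 itself is retained
  cd2 <- remove_outliers(cd)
  expect_identical(cd2$minutes, cd$minutes)
  expect_identical(cd2$removed, cd$removed)
})

test_that("daily steps sums retained minutes, 0 for empty", {
  expect_equal(daily_steps(day_stream(c(0, 1), c(10, 20))), 30)
  expect_equal(daily_steps(day_stream(integer(0), integer(0))), 0)
  expect_equal(daily_steps(day_stream(0:1439, rep(3, 1440))), 4320)
  # outlier minutes do not count
  expect_equal(daily_steps(day_stream(c(1, 2), c(10, 200))), 10)
})

test_that("P1M is the maximum retained minute; NA sentinel when empty", {
  expect_equal(peak_1min(day_stream(0:2, c(10, 120, 80))), 120)
  expect_equal(peak_1min(day_stream(0:9, rep(60, 10))), 60)
  expect_true(is.na(peak_1min(day_stream(5, 200))))
  s <- random_stream(1)
  cd <- remove_outliers(s)
  expect_equal(peak_1min(s), max(cd$minutes$steps))
})

test_that("P6MC matches hand-enumerated windows", {
  # plateau of six 120s surrounded by zeros
  expect_equal(peak_6min_consecutive(bout_day(120, len = 6, fill_zero = TRUE)),
               120)
  # all-zero day
  expect_equal(peak_6min_consecutive(day_stream(0:1439, rep(0, 1440))), 0)
  # [100 x6, 40, zeros...]: the pure plateau window wins over any shifted one
  st <- day_stream(0:6, c(rep(100, 6), 40))
  expect_equal(peak_6min_consecutive(st), 100)
  # missing minutes count as zero: isolated burst of 90 gives 90/6
  expect_equal(peak_6min_consecutive(day_stream(700, 90)), 15)
  # a removed outlier invalidates windows containing it
  st <- day_stream(0:6, c(rep(100, 6), 200))
  cd <- remove_outliers(st)
  expect_equal(peak_6min_consecutive(cd), 100)   # window 0..5 still valid
  # day where every window touches an outlier -> sentinel
  st <- day_stream(seq(0, 1439, by = 3), rep(200, 480))
  expect_true(is.na(peak_6min_consecutive(st)))
})

test_that("P6MC equals the exhaustive window-scan oracle on random streams", {
  for (seed in 1:10) {
    s <- random_stream(seed)
    cd <- remove_outliers(s)
    expect_identical(peak_6min_consecutive(cd),
                     oracle_p6mc(cd$minutes, cd$removed),
                     info = paste("seed", seed))
  }
  # sparse streams with missing minutes
  for (seed in 11:15) {
    s <- random_stream(seed, n = 300)
    cd <- remove_outliers(s)
    expect_identical(peak_6min_consecutive(cd),
                     oracle_p6mc(cd$minutes, cd$removed),
                     info = paste("seed", seed))
  }
})

test_that("intensity bands partition retained minutes with the documented boundaries", {
  expect_equal(intensity_minutes(day_stream(0:3, c(5, 50, 110, 140))),
               c(sedentary = 1, light = 1, moderate = 1, vigorous = 1))
  # boundary conventions: 20 is light, 100 is moderate, 130 is vigorous
  expect_equal(intensity_minutes(day_stream(0:4, c(19, 20, 99, 100, 130))),
               c(sedentary = 1, light = 2, moderate = 1, vigorous = 1))
  expect_equal(intensity_minutes(day_stream(integer(0), integer(0))),
               c(sedentary = 0, light = 0, moderate = 0, vigorous = 0))
  # partition property on random streams
  for (seed in 1:5) {
    cd <- remove_outliers(random_stream(seed, n = 500))
    expect_equal(sum(intensity_minutes(cd)), nrow(cd$minutes))
  }
})

test_that("custom thresholds shift band boundaries", {
  th <- intensity_thresholds(sedentary_upper = 10, moderate_lower = 90,
                             vigorous_lower = 120, outlier_cutoff = 140)
  expect_equal(intensity_minutes(day_stream(0:3, c(9, 10, 90, 120)), th),
               c(sedentary = 1, light = 1, moderate = 1, vigorous = 1))
  expect_error(intensity_thresholds(moderate_lower = 10), "thresholds")
})

test_that("summarize_day composes the biomarkers with QC counts", {
  zeros <- day_stream(0:1439, rep(0, 1440))
  s <- summarize_day(zeros)
  expect_equal(s$steps, 0); expect_equal(s$p1m, 0); expect_equal(s$p6mc, 0)
  expect_equal(s$min_sedentary, 1440L)

  bout <- bout_day(110, len = 30, fill_zero = TRUE)
  s <- summarize_day(bout)
  expect_equal(s$p6mc, 110)
  expect_equal(s$p1m, 110)
  expect_equal(s$min_moderate, 30L)
  expect_equal(s$steps, 110 * 30)

  allout <- day_stream(0:99, rep(160, 100))
  s <- summarize_day(allout)
  expect_equal(s$n_outliers_removed, 100L)
  expect_equal(s$n_minutes_recorded, 0L)
  expect_true(is.na(s$p1m) && is.na(s$p6mc))
  expect_equal(s$steps, 0)
})

test_that("vectorized cohort path equals the per-day path", {
  sim <- small_cohort(seed = 3, n = 3L, followup = 12L,
                      inject_outliers = TRUE, outlier_rate = 2)
  rec <- align_to_surgery(sim$streams, sim$meta)
  fast <- summarize_days(rec)
  slow <- data.table::rbindlist(
    lapply(split(rec, by = c("patient_id", "date")), summarize_day))
  data.table::setkeyv(slow, c("patient_id", "date"))
  expect_equal(as.data.frame(fast), as.data.frame(slow))
})

test_that("biomarker invariants hold on generated days", {
  sim <- small_cohort(seed = 5, n = 4L, followup = 15L)
  ds <- summarize_days(sim$streams, sim$meta)
  ok <- !is.na(ds$p1m)
  expect_true(all(ds$p1m[ok] >= ds$p6mc[ok]))
  expect_equal(ds$min_sedentary + ds$min_light + ds$min_moderate +
                 ds$min_vigorous, ds$n_minutes_recorded)
})

test_that("adding steps uniformly never decreases the summary metrics", {
  for (seed in 1:5) {
    s <- random_stream(seed, n = 400, max_steps = 120)
    cd <- remove_outliers(s)
    k <- 17L
    bumped <- data.table::copy(s)[, steps := pmin(steps + k, 150L)]
    cdb <- remove_outliers(bumped)
    expect_gte(daily_steps(cdb), daily_steps(cd))
    expect_gte(peak_1min(cdb), peak_1min(cd))
    expect_gte(peak_6min_consecutive(cdb), peak_6min_consecutive(cd))
  }
})

test_that("weekly intensity uses surgery-anchored 7-day bins", {
  ds <- data.table::data.table(
    patient_id = "P1", day_post_op = 1:12,
    min_light = rep(10L, 12), min_moderate = rep(2L, 12),
    min_vigorous = rep(0L, 12))
  wk <- weekly_intensity(ds)
  expect_equal(wk$week_index, c(1L, 2L))
  expect_equal(wk$min_light, c(70L, 50L))
  expect_equal(wk$complete, c(TRUE, FALSE))
  # pre-op days are excluded; empty weeks absent
  ds2 <- data.table::data.table(
    patient_id = "P1", day_post_op = c(-3:0, 15:19),
    min_light = 10L, min_moderate = 0L, min_vigorous = 0L)
  wk2 <- weekly_intensity(ds2)
  expect_equal(wk2$week_index, 3L)
  expect_equal(wk2$n_days, 5L)
  expect_false(wk2$complete)
})

test_that("postop_week maps day 1..7 to week 1 and rejects day <= 0", {
  expect_equal(postop_week(c(1, 7, 8, 14, 15)), c(1L, 1L, 2L, 2L, 3L))
  expect_true(all(is.na(postop_week(c(-5, 0)))))
})
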
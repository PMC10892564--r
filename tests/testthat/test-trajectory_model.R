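test_that("normalize_baseline subtracts group first-session means", {
  d <- data.table::data.table(
    group = c("g1", "g1", "g1"), day_post_op = c(1, 1, 2),
    y = c(10, 20, 25))
  nb <- normalize_baseline(d, "y", "group")
  expect_equal(nb$data$outcome_norm, c(-5, 5, 10))
  expect_equal(nb$baseline$baseline_mean, 15)
  expect_equal(nb$first_day, 1)

  const <- data.table::data.table(group = "g", day_post_op = 1:5, y = 7)
  expect_equal(normalize_baseline(const, "y", "group")$data$outcome_norm,
               rep(0, 5))

  two <- data.table::data.table(
    group = rep(c("a", "b"), each = 3), day_post_op = rep(1:3, 2),
    y = c(10, 12, 14, 100, 120, 140))
  nb2 <- normalize_baseline(two, "y", "group")
  first <- nb2$data[day_post_op == 1]
  expect_equal(first$outcome_norm, c(0, 0))

  gap <- data.table::data.table(
    group = rep(c("a", "b"), each = 2), day_post_op = c(1, 2, 2, 3),
    y = 1:4)
  expect_error(normalize_baseline(gap, "y", "group"), "group\\(s\\): b")
})

test_that("noiseless data recovers beta exactly (<= 1e-6 relative)", {
  set.seed(21)
  id <- rep(1:6, each = 8)
  day <- rep(1:8, 6)
  g <- as.numeric(id > 3)
  X <- cbind("(Intercept)" = 1, day = day, group = g, "day:group" = day * g)
  beta_true <- c(2.5, 1.25, -3, 0.5)
  y <- drop(X %*% beta_true)                     # alpha_i = 0, eps = 0
  expect_warning(fit <- fit_random_intercept_ml(y, X, id), "noiseless")
  expect_lt(max(abs(fit$beta - beta_true) / abs(beta_true)), 1e-6)
  expect_equal(fit$mu2, 0)
})

test_that("with zero variance components the MLE equals least squares", {
  set.seed(22)
  id <- rep(1:5, each = 6)
  X <- cbind(1, rnorm(30), rnorm(30))
  beta_true <- c(1, 2, -1)
  y <- drop(X %*% beta_true)
  expect_warning(fit <- fit_random_intercept_ml(y, X, id))
  ls <- qr.solve(X, y)
  expect_equal(unname(fit$beta), unname(ls), tolerance = 1e-9)
})

test_that("maximized log-likelihood matches the direct MVN density oracle", {
  set.seed(33)
  id <- rep(1:3, each = 4)
  day <- rep(1:4, 3)
  X <- cbind("(Intercept)" = 1, day = day)
  y <- 5 + 0.8 * day + rep(rnorm(3, 0, 2), each = 4) + rnorm(12, 0, 1)
  fit <- fit_random_intercept_ml(y, X, id)
  direct <- oracle_mvn_loglik(y, X, id, fit$beta, fit$sigma2, fit$mu2)
  expect_equal(fit$loglik, direct, tolerance = 1e-6)
})

test_that("fitted parameters are a local optimum of the direct density", {
  set.seed(34)
  id <- rep(1:4, each = 5)
  day <- rep(1:5, 4)
  X <- cbind("(Intercept)" = 1, day = day)
  y <- 2 + 0.5 * day + rep(rnorm(4, 0, 1.5), each = 5) + rnorm(20, 0, 1)
  fit <- fit_random_intercept_ml(y, X, id)
  for (i in 1:25) {
    beta_p <- fit$beta * (1 + runif(2, -0.2, 0.2))
    s2_p <- fit$sigma2 * exp(runif(1, -0.3, 0.3))
    m2_p <- max(fit$mu2 * exp(runif(1, -0.3, 0.3)), 1e-8)
    expect_gte(fit$loglik + 1e-8,
               oracle_mvn_loglik(y, X, id, beta_p, s2_p, m2_p))
  }
})

test_that("estimates agree with lme4 maximum likelihood", {
  set.seed(44)
  n_pat <- 30; n_day <- 10
  id <- rep(seq_len(n_pat), each = n_day)
  day <- rep(seq_len(n_day), n_pat)
  g <- as.numeric(id > n_pat / 2)
  X <- cbind("(Intercept)" = 1, day = day, group = g, "day:group" = day * g)
  y <- drop(X %*% c(10, 2, 3, 0.5)) + rep(rnorm(n_pat, 0, 4), each = n_day) +
    rnorm(n_pat * n_day, 0, 3)
  fit <- fit_random_intercept_ml(y, X, id)
  df <- data.frame(y = y, day = day, g = g, id = id)
  lfit <- lme4::lmer(y ~ day + g + day:g + (1 | id), data = df, REML = FALSE)
  expect_equal(unname(fit$beta), unname(lme4::fixef(lfit)), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lfit)), tolerance = 1e-5)
  expect_equal(fit$sigma2, lme4::getME(lfit, "sigma")^2, tolerance = 1e-3)
  expect_equal(unname(sqrt(diag(fit$vcov))),
               unname(sqrt(diag(as.matrix(stats::vcov(lfit))))),
               tolerance = 1e-3)
})

test_that("residual diagnostics: zeros when noiseless, sane under Gaussian noise", {
  id <- rep(1:4, each = 6); day <- rep(1:6, 4)
  X <- cbind("(Intercept)" = 1, day = day)
  y0 <- drop(X %*% c(3, 1))
  expect_warning(fit0 <- fit_random_intercept_ml(y0, X, id))
  d0 <- residual_diagnostics(fit0)
  expect_true(all(abs(d0$residuals) < 1e-10))

  set.seed(55)
  id <- rep(1:40, each = 10); day <- rep(1:10, 40)
  X <- cbind("(Intercept)" = 1, day = day)
  y <- drop(X %*% c(3, 1)) + rep(rnorm(40, 0, 2), each = 10) + rnorm(400)
  fit <- fit_random_intercept_ml(y, X, id)
  d <- residual_diagnostics(fit)
  expect_lt(abs(d$slope), 2 * d$slope_se)
  qq_gauss <- d$qq_dev

  yh <- drop(X %*% c(3, 1)) + rep(rnorm(40, 0, 2), each = 10) +
    rt(400, df = 2) # heavy tails inflate the QQ deviation
  fith <- fit_random_intercept_ml(yh, X, id)
  expect_gt(residual_diagnostics(fith)$qq_dev, qq_gauss)
})

test_that("return day has the closed form for affine trajectories", {
  # build a fit-like object by hand: pred(t) = b * t, baseline offset 0,
  # reference B  =>  return day = ceil(B / b)
  nm <- c("(Intercept)", "day", "group", "day:group")
  V <- diag(1e-12, 4); dimnames(V) <- list(nm, nm)
  fake <- structure(list(
    beta = c("(Intercept)" = 0, day = 2.5, group = 0, "day:group" = 0),
    vcov = V,
    group_factor = "recovery_label",
    group_levels = c("MCID_plus", "MCID_minus"),
    day_range = c(1L, 60L),
    baseline = data.table::data.table(group = c("MCID_plus", "MCID_minus"),
                                      baseline_mean = c(0, 0))),
    class = "cadence_lmm")
  pr <- data.frame(group = c("MCID_plus", "MCID_minus"), mean = c(41, 1e6))
  r <- time_to_preop_return(fake, pr, "MCID_plus", n_boot = 50, seed = 1)
  expect_equal(r$return_day, ceiling(41 / 2.5))   # 17
  r2 <- time_to_preop_return(fake, pr, "MCID_minus", n_boot = 50, seed = 1)
  expect_true(is.na(r2$return_day)); expect_false(r2$reached)
})

test_that("separation day: null case, analytic agreement, monotonicity", {
  dr <- c(1L, 90L)
  expect_true(is.na(separation_day_from_contrast(0, 0, 1, 0, 0.01, dr)))
  set.seed(66)
  for (i in 1:15) {
    b2 <- rnorm(1, 0, 2); b3 <- rnorm(1, 0.1, 0.2)
    a <- matrix(rnorm(4), 2); V <- crossprod(a) * 0.05
    got <- separation_day_from_contrast(b2, b3, V[1, 1], V[1, 2], V[2, 2], dr)
    want <- oracle_separation_quadratic(b2, b3, V[1, 1], V[1, 2], V[2, 2], dr)
    expect_identical(got, want, info = paste("instance", i))
  }
  # doubling beta3 never delays separation (same-sign effects: with
  # opposite signs a larger interaction can first cancel the main effect)
  for (i in 1:10) {
    b2 <- abs(rnorm(1)); b3 <- abs(rnorm(1, 0.05, 0.1))
    a <- matrix(rnorm(4), 2); V <- crossprod(a) * 0.02
    s1 <- separation_day_from_contrast(b2, b3, V[1, 1], V[1, 2], V[2, 2], dr)
    s2 <- separation_day_from_contrast(b2, 2 * b3, V[1, 1], V[1, 2], V[2, 2], dr)
    s1 <- if (is.na(s1)) Inf else s1
    s2 <- if (is.na(s2)) Inf else s2
    expect_lte(s2, s1)
  }
})

test_that("fit_mixed_model wires groups, covariates and normalization", {
  sim <- small_cohort(seed = 12, n = 6L, followup = 30L)
  ds <- summarize_days(sim$streams, sim$meta)
  fit <- fit_mixed_model(ds, sim$meta, outcome = "p6mc",
                         day_range = c(1L, 30L))
  expect_s3_class(fit, "cadence_lmm")
  expect_named(fit$beta, c("(Intercept)", "day", "group", "day:group",
                           "age_c", "gender_c"))
  expect_true(fit$sigma2 > 0)
  expect_true(isSymmetric(unname(fit$vcov), tol = 1e-8))
  expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-8))
  # group trajectories both start at mean ~0 on the normalized scale
  day1 <- fit$data[day_post_op == fit$first_day]
  means <- day1[, mean(outcome_norm), by = group]$V1
  expect_equal(means, c(0, 0), tolerance = 1e-10)
  # bootstrap CIs are seed-reproducible
  s1 <- group_separation_day(fit, n_boot = 100, seed = 3)
  s2 <- group_separation_day(fit, n_boot = 100, seed = 3)
  expect_identical(s1, s2)
  expect_error(fit_mixed_model(ds, sim$meta, outcome = "steps",
                               group_factor = "surgery_type",
                               day_range = c(1L, 30L)),
               ">= 2 groups")
})

test_that("predict_trajectory returns the un-normalized group curve", {
  sim <- small_cohort(seed = 13, n = 5L, followup = 20L)
  ds <- summarize_days(sim$streams, sim$meta)
  fit <- fit_mixed_model(ds, sim$meta, outcome = "steps",
                         day_range = c(1L, 20L))
  pr <- predict_trajectory(fit, "MCID_plus", days = c(1, 10, 20))
  off <- fit$baseline[group == "MCID_plus"]$baseline_mean
  expect_equal(pr$pred, off + fit$beta[["(Intercept)"]] +
                 fit$beta[["day"]] * c(1, 10, 20))
  expect_true(all(pr$lower <= pr$pred & pr$pred <= pr$upper))
})
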
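# Random-intercept linear mixed model for recovery trajectories.
#
# Daily biomarker values are repeated measures per patient. The model is
#
#   outcome[i,t] = alpha + b1*day + b2*group + b3*(day x group)
#                  + b4*age_c + b5*gender_c + a_i + eps[i,t]
#
# with a_i ~ N(0, mu2) one random intercept per patient and independent
# residuals eps ~ N(0, sigma2). Fitting is full maximum likelihood with the
# variance ratio lambda = mu2/sigma2 profiled out: given lambda, beta is the
# GLS solution and sigma2 has a closed form, leaving a one-dimensional
# optimization. For a block V_i = sigma2 (I + lambda J), Woodbury gives
# V_i^{-1} = (1/sigma2) (I - c_i J) with c_i = lambda / (1 + n_i lambda),
# so everything reduces to per-patient sums — no matrix bigger than p x p.

#' Fit a random-intercept linear model by maximum likelihood
#'
#' Low-level fitter: `y = X beta + a_id + eps`, one random intercept per
#' level of `id`. Profiles the variance ratio and maximizes the marginal
#' (ML, not REML) likelihood.
#'
#' @param y Numeric response vector.
#' @param X Design matrix (including an intercept column if wanted).
#' @param id Grouping vector (one random intercept per level).
#' @param lambda_max Upper bound of the profiled variance-ratio search.
#' @return A list with `beta` (named), `vcov` (of the fixed effects),
#'   `sigma2`, `mu2`, `lambda`, `loglik`, `n_obs`, `n_groups`, `fitted_fe`
#'   (fixed-effect fitted values) and `id`.
#' @export
fit_random_intercept_ml <- function(y, X, id, lambda_max = 1e6) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(id) == length(y))
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X")
  id <- as.factor(id)
  N <- length(y); p <- ncol(X)
  ni <- as.vector(table(id))
  Sx <- rowsum(X, id)                 # per-group column sums of X
  Sy <- as.vector(rowsum(y, id))
  A0 <- crossprod(X); b0 <- crossprod(X, y); yy <- sum(y * y)

  profile <- function(lambda) {
    ci <- lambda / (1 + ni * lambda)
    A <- A0 - crossprod(Sx * sqrt(ci))
    b <- b0 - crossprod(Sx, ci * Sy)
    beta <- solve(A, b)
    rss <- yy - sum(ci * Sy^2) - sum(b * beta)
    rss <- max(rss, 0)
    sigma2 <- rss / N
    dev <- if (sigma2 > 0)
      N * (log(2 * pi * sigma2) + 1) + sum(log1p(ni * lambda))
    else -Inf
    list(beta = beta, A = A, sigma2 = sigma2, dev = dev)
  }

  dev_of <- function(u) profile(exp(u))$dev
  # boundary (lambda = 0) vs interior optimum on a log scale
  at0 <- profile(0)
  degenerate <- at0$sigma2 < 1e-12 * (yy / N + 1)
  if (degenerate) {
    warning("residual variance is numerically zero (noiseless data); ",
            "returning the least-squares solution with mu2 = 0")
    lambda_hat <- 0
  } else {
    opt <- stats::optimize(dev_of, interval = c(log(1e-8), log(lambda_max)),
                           tol = 1e-10)
    lambda_hat <- if (opt$objective < at0$dev) exp(opt$minimum) else 0
    if (lambda_hat < 1e-6)
      warning("singular fit: random-intercept variance estimated at ~0")
  }
  fit <- profile(lambda_hat)
  beta <- drop(fit$beta)
  names(beta) <- colnames(X)
  sigma2 <- fit$sigma2
  vcov <- if (sigma2 > 0) sigma2 * solve(fit$A) else 0 * solve(fit$A)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  loglik <- if (is.finite(fit$dev)) -0.5 * fit$dev else Inf
  list(beta = beta, vcov = vcov, sigma2 = sigma2,
       mu2 = lambda_hat * sigma2, lambda = lambda_hat, loglik = loglik,
       n_obs = N, n_groups = nlevels(id),
       fitted_fe = drop(X %*% beta), id = id, y = y)
}

#' Normalize outcomes to a common group baseline
#'
#' Subtracts, within each group, the group's mean outcome at the first
#' modelled session (the smallest day with any data across groups) from
#' all of that group's values, so every group's trajectory starts at mean
#' zero and the group contrast measures divergence after the first session.
#'
#' @param data A table with the outcome, a group column and a day column.
#' @param outcome Name of the outcome column.
#' @param group_col Name of the group column.
#' @param day_col Name of the day column (default `"day_post_op"`).
#' @return A list with `data` (a copy carrying the extra column
#'   `outcome_norm`), `first_day`, and `baseline` (a `data.table` of
#'   per-group first-session means).
#' @export
normalize_baseline <- function(data, outcome, group_col,
                               day_col = "day_post_op") {
  dt <- data.table::as.data.table(data)
  stopifnot(all(c(outcome, group_col, day_col) %in% names(dt)))
  dt <- dt[!is.na(dt[[outcome]])]
  first_day <- min(dt[[day_col]])
  base <- dt[dt[[day_col]] == first_day,
             .(baseline_mean = mean(.SD[[1L]])),
             by = c(group_col), .SDcols = outcome]
  missing_groups <- setdiff(unique(dt[[group_col]]), base[[group_col]])
  if (length(missing_groups))
    stop("no first-session (day ", first_day, ") data for group(s): ",
         paste(missing_groups, collapse = ", "))
  dt <- merge(dt, base, by = group_col, sort = FALSE)
  dt[, outcome_norm := .SD[[1L]] - baseline_mean, .SDcols = outcome]
  dt[, baseline_mean := NULL]
  list(data = dt[], first_day = first_day, baseline = base[])
}

#' Fit the recovery-trajectory mixed model
#'
#' Assembles the analysis table (day summaries within the modelled day
#' range, merged with the grouping factor and covariates), normalizes each
#' group to its first-session mean, and fits the random-intercept model by
#' maximum likelihood. Day enters as a continuous covariate; age and the
#' male indicator are mean-centered so the intercept refers to the
#' reference group at the cohort-average covariates.
#'
#' @param day_summaries Day summaries (see [summarize_days()]) with
#'   `day_post_op`.
#' @param meta Patient metadata.
#' @param outcome One of `"steps"`, `"p1m"`, `"p6mc"`, `"min_light"`,
#'   `"min_moderate"`.
#' @param group_factor `"recovery_label"` (MCID+/MCID-, reference MCID+),
#'   `"surgery_type"` (knee total vs unicondylar, reference total), or
#'   `NULL` for a single-group model without group terms.
#' @param day_range Inclusive integer interval of modelled post-operative
#'   days, e.g. `c(1, 60)` for hip and `c(1, 90)` for knee.
#' @param covariates Character subset of `c("age", "gender")`.
#' @return An object of class `cadence_lmm`; see
#'   [fit_random_intercept_ml()] for the estimation fields, plus the
#'   grouping/normalization metadata needed by [predict_trajectory()],
#'   [time_to_preop_return()] and [group_separation_day()].
#' @export
fit_mixed_model <- function(day_summaries, meta, outcome = "steps",
                            group_factor = "recovery_label",
                            day_range = c(1L, 60L),
                            covariates = c("age", "gender")) {
  stopifnot(length(day_range) == 2L, day_range[1] >= 1L,
            day_range[1] <= day_range[2])
  ds <- data.table::as.data.table(day_summaries)
  meta <- data.table::as.data.table(meta)
  stopifnot(outcome %in% names(ds))

  if (is.null(group_factor)) {
    groups <- meta[, .(patient_id)]
    groups[, group := "all"]
    group_levels <- "all"
  } else if (group_factor == "recovery_label") {
    lab <- label_recovery(meta)
    groups <- lab[label %in% c("MCID_plus", "MCID_minus"),
                  .(patient_id, group = label)]
    group_levels <- c("MCID_plus", "MCID_minus")   # MCID+ is the reference
  } else if (group_factor == "surgery_type") {
    groups <- meta[surgery_type %in% c("total", "unicondylar"),
                   .(patient_id, group = surgery_type)]
    group_levels <- c("total", "unicondylar")      # total is the reference
  } else stop("unknown group_factor: ", group_factor)

  dat <- ds[day_post_op >= day_range[1] & day_post_op <= day_range[2]]
  dat <- merge(dat, groups, by = "patient_id")
  dat <- merge(dat, meta[, .(patient_id, age, gender)], by = "patient_id")
  dat <- dat[!is.na(dat[[outcome]])]
  if (nrow(dat) == 0L) stop("no data in the modelled day range")
  present <- intersect(group_levels, unique(dat$group))
  if (!is.null(group_factor) && length(present) < 2L)
    stop("need >= 2 groups to fit a group model; present: ",
         paste(present, collapse = ", "))
  if (any(dat[, .(n = data.table::uniqueN(patient_id)), by = group]$n < 2L))
    stop("each group needs >= 2 patients")

  nb <- normalize_baseline(dat, outcome, "group")
  dat <- nb$data
  dat[, group := factor(group, levels = group_levels)]

  age_mean <- mean(dat$age)
  male_mean <- mean(dat$gender == "male")
  X <- cbind("(Intercept)" = 1, day = as.numeric(dat$day_post_op))
  if (!is.null(group_factor)) {
    g01 <- as.numeric(dat$group == group_levels[2L])
    X <- cbind(X, group = g01, "day:group" = X[, "day"] * g01)
  }
  if ("age" %in% covariates) X <- cbind(X, age_c = dat$age - age_mean)
  if ("gender" %in% covariates)
    X <- cbind(X, gender_c = as.numeric(dat$gender == "male") - male_mean)

  fit <- fit_random_intercept_ml(dat$outcome_norm, X, dat$patient_id)
  structure(c(fit, list(
    outcome = outcome, group_factor = group_factor,
    group_levels = group_levels, day_range = as.integer(day_range),
    baseline = nb$baseline, first_day = nb$first_day,
    age_mean = age_mean, male_mean = male_mean,
    covariates = covariates, y = dat$outcome_norm, X = X,
    data = dat)), class = "cadence_lmm")
}

#' @export
print.cadence_lmm <- function(x, ...) {
  cat("Random-intercept recovery model (ML)\n")
  cat("  outcome:", x$outcome, " groups:",
      paste(x$group_levels, collapse = " vs "),
      " days:", paste(x$day_range, collapse = ".."), "\n")
  se <- sqrt(diag(x$vcov))
  tab <- data.frame(estimate = x$beta, se = se)
  print(round(tab, 4))
  cat(sprintf("  sigma2 = %.4g, mu2 = %.4g, logLik = %.4f, n = %d obs / %d patients\n",
              x$sigma2, x$mu2, x$loglik, x$n_obs, x$n_groups))
  invisible(x)
}

#' Residual diagnostics for a fitted trajectory model
#'
#' Conditional residuals use the empirical best linear unbiased predictors
#' of the patient intercepts, `b_i = (n_i lambda / (1 + n_i lambda)) *
#' mean(marginal residual_i)`. Returns the material for QQ and
#' residual-vs-fitted checks plus two scalar statistics: the slope of a
#' residuals-on-fitted regression (should be ~0) and the mean absolute
#' deviation between standardized residual quantiles and normal quantiles.
#'
#' @param fit A `cadence_lmm` or [fit_random_intercept_ml()] result.
#' @return A list with `residuals`, `fitted`, `blups`, `qq`
#'   (a `data.table` of theoretical and sample quantiles), `slope`,
#'   `slope_se`, `qq_dev`.
#' @export
residual_diagnostics <- function(fit) {
  y <- if (!is.null(fit$y)) fit$y else stop("fit carries no data")
  r_marg <- y - fit$fitted_fe
  id <- fit$id
  ni <- as.vector(table(id))
  shrink <- ni * fit$lambda / (1 + ni * fit$lambda)
  blups <- shrink * as.vector(rowsum(r_marg, id)) / ni
  fitted <- fit$fitted_fe + blups[as.integer(id)]
  res <- y - fitted
  s <- stats::sd(res)
  std <- if (s > 0) (res - mean(res)) / s else res * 0
  qq <- data.table::data.table(
    theoretical = stats::qnorm(stats::ppoints(length(res))),
    sample = sort(std))
  sl <- stats::lm(res ~ fitted)
  cf <- summary(sl)$coefficients
  slope <- unname(cf["fitted", "Estimate"])
  slope_se <- unname(cf["fitted", "Std. Error"])
  list(residuals = res, fitted = fitted, blups = blups, qq = qq,
       slope = slope, slope_se = slope_se,
       qq_dev = mean(abs(qq$sample - qq$theoretical)))
}

#' Pre-operative reference level per group
#'
#' Equal patient weighting: the group mean of per-patient means over
#' pre-operative days (`day_post_op < 0`), with a t-based 95% CI.
#'
#' @param day_summaries Day summaries with `day_post_op`.
#' @param groups A table with `patient_id` and `group` (e.g. derived from
#'   [label_recovery()]).
#' @param outcome Day-summary column to summarize.
#' @param level Confidence level (default 0.95).
#' @return A `data.table` with `group`, `mean`, `lower`, `upper`,
#'   `n_patients`.
#' @export
preop_reference <- function(day_summaries, groups, outcome = "steps",
                            level = 0.95) {
  ds <- data.table::as.data.table(day_summaries)
  pre <- ds[day_post_op < 0L & !is.na(ds[[outcome]])]
  if (nrow(pre) == 0L) stop("no pre-operative days available")
  per_pat <- pre[, .(value = mean(.SD[[1L]])), by = patient_id,
                 .SDcols = outcome]
  per_pat <- merge(per_pat, data.table::as.data.table(groups),
                   by = "patient_id")
  missing_groups <- setdiff(unique(groups$group), per_pat$group)
  if (length(missing_groups))
    stop("no pre-operative data for group(s): ",
         paste(missing_groups, collapse = ", "))
  alpha <- 1 - level
  per_pat[, .(mean = mean(value),
              lower = mean(value) - stats::qt(1 - alpha / 2, .N - 1L) *
                stats::sd(value) / sqrt(.N),
              upper = mean(value) + stats::qt(1 - alpha / 2, .N - 1L) *
                stats::sd(value) / sqrt(.N),
              n_patients = .N),
          by = group]
}

# design row for a group trajectory at covariate means (centered covariates
# contribute zero)
baseline_offset <- function(fit, group_level) {
  i <- which(fit$baseline$group == group_level)
  if (length(i) != 1L) stop("no baseline mean for group ", group_level)
  fit$baseline$baseline_mean[i]
}

trajectory_design <- function(fit, group, days) {
  p <- length(fit$beta)
  D <- matrix(0, length(days), p, dimnames = list(NULL, names(fit$beta)))
  D[, "(Intercept)"] <- 1
  D[, "day"] <- days
  if (!is.null(fit$group_factor)) {
    g <- as.numeric(group == fit$group_levels[2L])
    D[, "group"] <- g
    D[, "day:group"] <- days * g
  }
  D
}

#' Predicted group trajectory with pointwise 95% CI
#'
#' Predictions are population-level (random intercept at 0, centered
#' covariates at their means) and are reported both on the normalized scale
#' and on the original outcome scale (adding back the group's first-session
#' mean).
#'
#' @param fit A `cadence_lmm`.
#' @param group Group level to predict for.
#' @param days Integer days (default the fitted day range).
#' @param level Confidence level.
#' @return A `data.table` with `day`, `pred_norm`, `pred`, `lower`, `upper`.
#' @export
predict_trajectory <- function(fit, group, days = NULL, level = 0.95) {
  if (is.null(days)) days <- seq(fit$day_range[1], fit$day_range[2])
  stopifnot(group %in% fit$group_levels)
  D <- trajectory_design(fit, group, days)
  pred_norm <- drop(D %*% fit$beta)
  se <- sqrt(rowSums((D %*% fit$vcov) * D))
  z <- stats::qnorm(1 - (1 - level) / 2)
  offset <- baseline_offset(fit, group)
  data.table::data.table(day = days, pred_norm = pred_norm,
                         pred = offset + pred_norm,
                         lower = offset + pred_norm - z * se,
                         upper = offset + pred_norm + z * se)
}

first_true <- function(mask) {
  i <- which(mask)
  if (length(i)) i[1L] else NA_integer_
}

#' Time to return to the pre-operative level
#'
#' The smallest integer day in the modelled range at which the group's
#' predicted trajectory, on the original outcome scale, reaches the group's
#' pre-operative reference mean. The 95% CI comes from a parametric
#' bootstrap of the fixed effects (draws from `N(beta, vcov)`); draws whose
#' trajectory never reaches the reference count as "not reached" (+Inf) in
#' the day quantiles.
#'
#' @param fit A `cadence_lmm`.
#' @param preop_ref Output of [preop_reference()] for the same outcome.
#' @param group Group level.
#' @param n_boot Number of bootstrap draws (default 1000).
#' @param seed Optional integer seed for the bootstrap.
#' @param level Confidence level.
#' @return A list with `return_day` (integer, or `NA` when not reached
#'   within the day range), `reached`, `ci` (integer bounds; `NA` where the
#'   quantile is "not reached"), `not_reached_frac`, and `reference`.
#' @export
time_to_preop_return <- function(fit, preop_ref, group, n_boot = 1000L,
                                 seed = NULL, level = 0.95) {
  pr <- as.data.frame(preop_ref)
  i <- which(pr$group == group)
  if (length(i) != 1L) stop("no pre-operative reference for group ", group)
  ref <- pr$mean[i]
  days <- seq(fit$day_range[1], fit$day_range[2])
  D <- trajectory_design(fit, group, days)
  offset <- baseline_offset(fit, group)
  point <- first_true(offset + drop(D %*% fit$beta) >= ref)
  return_day <- if (is.na(point)) NA_integer_ else days[point]

  if (!is.null(seed)) set.seed(seed)
  L <- chol_psd(fit$vcov)
  Z <- matrix(stats::rnorm(n_boot * length(fit$beta)), ncol = n_boot)
  B <- fit$beta + t(L) %*% Z                      # p x n_boot
  preds <- offset + D %*% B                       # days x n_boot
  idx <- apply(preds >= ref, 2L, first_true)
  boot_days <- rep(Inf, n_boot)
  boot_days[!is.na(idx)] <- days[idx[!is.na(idx)]]
  alpha <- 1 - level
  qs <- stats::quantile(boot_days, c(alpha / 2, 1 - alpha / 2), type = 1)
  ci <- ifelse(is.finite(qs), qs, NA_integer_)
  list(return_day = return_day, reached = !is.na(return_day),
       ci = as.integer(ci), not_reached_frac = mean(!is.finite(boot_days)),
       reference = ref)
}

# Cholesky tolerant of semi-definite vcov (e.g. noiseless fits)
chol_psd <- function(V) {
  out <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(out)) {
    e <- eigen(V, symmetric = TRUE)
    vals <- pmax(e$values, 0)
    out <- diag(sqrt(vals)) %*% t(e$vectors)
  }
  out
}

#' Earliest day of statistical group separation from contrast estimates
#'
#' Scans integer days `t` in `day_range` for the first at which the Wald
#' interval of the group contrast `b2 + b3 t` excludes zero, i.e.
#' `|b2 + b3 t| > z * sqrt(v22 + 2 t v23 + t^2 v33)`.
#'
#' @param beta2,beta3 Group main effect and day-by-group interaction.
#' @param v22,v23,v33 Elements of their covariance.
#' @param day_range Inclusive integer interval.
#' @param level Confidence level (default 0.95).
#' @return The smallest such integer day, or `NA_integer_` if none.
#' @export
separation_day_from_contrast <- function(beta2, beta3, v22, v23, v33,
                                         day_range, level = 0.95) {
  days <- seq(day_range[1], day_range[2])
  z <- stats::qnorm(1 - (1 - level) / 2)
  contrast <- beta2 + beta3 * days
  se <- sqrt(pmax(v22 + 2 * days * v23 + days^2 * v33, 0))
  i <- first_true(abs(contrast) > z * se)
  if (is.na(i)) NA_integer_ else as.integer(days[i])
}

#' Earliest day at which the fitted groups separate
#'
#' Applies [separation_day_from_contrast()] to a fitted model; the CI is a
#' parametric bootstrap over the fixed-effect estimates (the contrast
#' covariance is held at its estimate).
#'
#' @param fit A `cadence_lmm` fitted with a group factor.
#' @param n_boot Bootstrap draws for the CI (default 1000).
#' @param seed Optional integer seed.
#' @param level Confidence level.
#' @return A list with `separation_day` (integer or `NA`), `reached`,
#'   `ci`, `not_reached_frac`.
#' @export
group_separation_day <- function(fit, n_boot = 1000L, seed = NULL,
                                 level = 0.95) {
  if (is.null(fit$group_factor)) stop("fit has no group factor")
  k <- c("group", "day:group")
  b <- fit$beta[k]; V <- fit$vcov[k, k]
  sep <- separation_day_from_contrast(b[1L], b[2L], V[1L, 1L], V[1L, 2L],
                                      V[2L, 2L], fit$day_range, level)
  if (!is.null(seed)) set.seed(seed)
  L <- chol_psd(V)
  Z <- matrix(stats::rnorm(2L * n_boot), nrow = 2L)
  B <- b + t(L) %*% Z
  boot <- vapply(seq_len(n_boot), function(j)
    separation_day_from_contrast(B[1L, j], B[2L, j], V[1L, 1L], V[1L, 2L],
                                 V[2L, 2L], fit$day_range, level),
    integer(1L))
  bd <- ifelse(is.na(boot), Inf, boot)
  alpha <- 1 - level
  qs <- stats::quantile(bd, c(alpha / 2, 1 - alpha / 2), type = 1)
  ci <- ifelse(is.finite(qs), qs, NA_integer_)
  list(separation_day = sep, reached = !is.na(sep), ci = as.integer(ci),
       not_reached_frac = mean(!is.finite(bd)))
}
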
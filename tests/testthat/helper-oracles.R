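# Independent oracles. These deliberately share no code path with the
# package implementations they check.

# Exhaustive window scan for the peak 6-minute consecutive cadence.
# `minutes` is a data.frame(minute_of_day, steps) of retained minutes,
# `removed` the outlier minutes (which invalidate windows containing them).
oracle_p6mc <- function(minutes, removed = integer(0)) {
  x <- rep(0, 1440)
  x[minutes$minute_of_day + 1] <- minutes$steps
  x[removed + 1] <- NA
  best <- -Inf
  for (j in 1:1435) {
    s <- sum(x[j:(j + 5)])
    if (!is.na(s) && s > best) best <- s
  }
  if (is.infinite(best)) NA_real_ else best / 6
}

# Direct multivariate-normal log-density of a random-intercept model:
# y ~ N(X beta, sigma2 I + mu2 Z Z') with Z the patient indicator matrix.
oracle_mvn_loglik <- function(y, X, id, beta, sigma2, mu2) {
  id <- as.factor(id)
  Z <- outer(id, levels(id), `==`) * 1
  V <- sigma2 * diag(length(y)) + mu2 * tcrossprod(Z)
  r <- y - as.vector(as.matrix(X) %*% beta)
  L <- chol(V)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(L))) +
            sum(backsolve(L, r, transpose = TRUE)^2))
}

# Closed-form smallest integer day with |b2 + b3 t| > z * se(t),
# se(t)^2 = v22 + 2 t v23 + t^2 v33. Solves the quadratic
# (b3^2 - z^2 v33) t^2 + 2 (b2 b3 - z^2 v23) t + (b2^2 - z^2 v22) > 0
# analytically and picks the smallest admissible integer in day_range —
# no grid scan.
oracle_separation_quadratic <- function(b2, b3, v22, v23, v33, day_range,
                                        level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  A <- b3^2 - z^2 * v33
  B <- 2 * (b2 * b3 - z^2 * v23)
  C <- b2^2 - z^2 * v22
  lo <- day_range[1]; hi <- day_range[2]
  sat <- function(t) A * t^2 + B * t + C > 0
  candidates <- integer(0)
  if (abs(A) < 1e-300) {
    if (abs(B) < 1e-300) {
      if (C > 0) candidates <- lo
    } else {
      r <- -C / B
      candidates <- if (B > 0) ceiling(max(lo, floor(r))) else lo
      candidates <- c(candidates, candidates + 1)
    }
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) {
      if (A > 0) candidates <- lo            # always satisfied
    } else {
      r1 <- (-B - sqrt(disc)) / (2 * A)
      r2 <- (-B + sqrt(disc)) / (2 * A)
      rr <- sort(c(r1, r2))
      # boundary integers of each sign region
      candidates <- c(lo, ceiling(rr[1]) + c(-1L, 0L, 1L),
                      ceiling(rr[2]) + c(-1L, 0L, 1L))
    }
  }
  candidates <- sort(unique(pmin(pmax(candidates, lo), hi)))
  for (t in candidates) {
    if (sat(t)) {
      # smallest admissible integer >= lo in this sign region: walk back
      while (t - 1 >= lo && sat(t - 1)) t <- t - 1
      return(as.integer(t))
    }
  }
  NA_integer_
}

# Grid evaluation of the recovery curve's baseline-crossing day.
oracle_crossing_grid <- function(drop, gain, tau, max_day = 1000) {
  lev <- drop + (1 + gain - drop) * (1 - exp(-(1:max_day) / tau))
  i <- which(lev >= 1 - 1e-9)
  if (length(i)) i[1] else Inf
}
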
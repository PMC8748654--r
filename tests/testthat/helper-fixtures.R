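# Shared fixtures, built in code at test time.

# small cohort restricted to the built-in database species, with
# concentrations of comparable magnitude (suitable for spectrum round trips)
make_db_cohort <- function(n = 6, lo = 5, hi = 50, seed = 11) {
  db <- default_lipid_db()
  endo <- db$name[!db$is_internal_standard]
  set.seed(seed)
  vals <- matrix(exp(stats::runif(n * length(endo), log(lo), log(hi))),
                 nrow = n, dimnames = list(sprintf("S%02d", seq_len(n)), endo))
  conc_matrix(vals)
}

# toy single-entry database around a given m/z
make_toy_db <- function(names = "SM 34:1") {
  lipid_db(names)
}

# balanced two-class matrix with a clean separating direction plus noise
make_separable_X <- function(n_per = 20, p = 10, gap = 6, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * p), ncol = p)
  y <- rep(c(0, 1), each = n_per)
  X[, 1] <- X[, 1] + gap * y
  X <- scale(X, center = TRUE, scale = FALSE)
  list(X = X, y = y)
}

# independent single-component PLS1 (closed form): w ~ X'y, t = Xw,
# prediction q*t + mean(y).  Used as the oracle for the zero-orthogonal
# OPLS limit; deliberately independent of the package internals.
pls1_oracle <- function(X, y, X_new = X) {
  yc <- y - mean(y)
  w <- drop(crossprod(X, yc)); w <- w / sqrt(sum(w^2))
  t <- drop(X %*% w)
  q <- sum(yc * t) / sum(t^2)
  drop(X_new %*% w) * q + mean(y)
}

# hand-computed Welch statistic (independent of stats::t.test)
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# hand-computed product-limit estimator at event times
km_oracle <- function(time, event) {
  o <- order(time)
  time <- time[o]; event <- event[o]
  ut <- unique(time[event == 1])
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ut, surv = surv)
}

# hand-computed two-group log-rank chi-square
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  ut <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ut) {
    at1 <- sum(time >= t & g == 1); at2 <- sum(time >= t & g == 2)
    d1 <- sum(time == t & event == 1 & g == 1)
    d2 <- sum(time == t & event == 1 & g == 2)
    d <- d1 + d2; n <- at1 + at2
    if (n < 2) next
    e1 <- d * at1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    v <- v + d * (at1 / n) * (at2 / n) * (n - d) / (n - 1)
  }
  chi2 <- o_minus_e^2 / v
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}
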
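test_that("PCA: perfect line, reconstruction identity, sign convention", {
  t <- seq(-1, 1, length.out = 20)
  X <- cbind(t, 2 * t, -t)
  p <- fit_pca(scale(X, scale = FALSE), n_components = 1)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-12)
  set.seed(10)
  X2 <- scale(matrix(rnorm(200), 20, 10), scale = FALSE)
  expect_warning(p2 <- fit_pca(X2, n_components = 15), "rank")
  recon <- p2$scores %*% t(p2$loadings)
  expect_lt(max(abs(recon - X2)), 1e-8)
  # deterministic sign: largest-magnitude loading entry positive
  for (j in seq_len(ncol(p2$loadings)))
    expect_gt(p2$loadings[which.max(abs(p2$loadings[, j])), j], 0)
})

test_that("OPLS with zero orthogonal components equals the PLS1 oracle", {
  sep <- make_separable_X(n_per = 15, p = 8, gap = 3, seed = 2)
  fit <- opls_da(sep$X, sep$y, n_orthogonal = 0, transform = FALSE,
                 cv_folds = 5)
  expect_lt(max(abs(fit$fitted - pls1_oracle(sep$X, sep$y))), 1e-8)
  set.seed(3)
  Xn <- scale(matrix(rnorm(80), 10, 8), scale = FALSE)
  expect_lt(max(abs(predict(fit, Xn) - pls1_oracle(sep$X, sep$y, Xn))), 1e-8)
})

test_that("orthogonal component captures a constructed nuisance direction", {
  set.seed(5)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  signal <- y - mean(y)
  nuisance <- rnorm(n, sd = 4)
  X <- cbind(sig1 = signal + rnorm(n, sd = 0.2) + 0.8 * nuisance,
             sig2 = signal + rnorm(n, sd = 0.2) - 0.8 * nuisance,
             nu1 = nuisance + rnorm(n, sd = 0.2),
             nu2 = nuisance + rnorm(n, sd = 0.2))
  X <- scale(X, scale = FALSE)
  fit0 <- opls_da(X, y, n_orthogonal = 0, transform = FALSE, cv_folds = 5)
  fit1 <- opls_da(X, y, n_orthogonal = 1, transform = FALSE, cv_folds = 5)
  # orthogonal score follows the nuisance
  expect_gt(abs(cor(fit1$t_o[, 1], nuisance)), 0.9)
  # predictive score cleaner than the PLS1 limit
  expect_gt(cor(fit1$t, y), cor(fit0$t, y))
  # predictive score orthogonal to every orthogonal score
  expect_lt(abs(sum(fit1$t * fit1$t_o[, 1])),
            1e-8 * sqrt(sum(fit1$t^2) * sum(fit1$t_o[, 1]^2)))
})

test_that("well-separated clusters give 100% training accuracy", {
  sep <- make_separable_X(n_per = 20, p = 6, gap = 8, seed = 7)
  fit <- opls_da(sep$X, sep$y, n_orthogonal = 0, transform = FALSE,
                 cv_folds = 5)
  rep <- classification_metrics(sep$y, as.numeric(fitted(fit) > 0.5))
  expect_equal(rep$accuracy, 100)
  expect_error(opls_da(sep$X, rep(1, 40), transform = FALSE), "binary")
  expect_error(opls_da(sep$X, sep$y, n_orthogonal = 50, transform = FALSE,
                       cv_folds = 5), "rank")
})

test_that("prediction: training consistency, duplicates, permutation equivariance", {
  m <- make_db_cohort(n = 24, seed = 15)
  y <- rep(c(0, 1), 12)
  # inject signal so the model is non-trivial
  m$values[y == 1, 1:3] <- m$values[y == 1, 1:3] * 0.5
  fit <- opls_da(m, y, n_orthogonal = 1, cv_folds = 6)
  expect_lt(max(abs(predict(fit, m) - fit$fitted)), 1e-10)
  dup <- m$values[c(3, 3), , drop = FALSE]
  rownames(dup) <- c("a", "b")
  pr <- predict(fit, dup)
  expect_equal(pr[["a"]], fit$fitted[[3]], tolerance = 1e-12)
  perm <- sample(nrow(m$values))
  expect_equal(unname(predict(fit, m$values[perm, ])),
               unname(fit$fitted[perm]), tolerance = 1e-12)
  expect_error(predict(fit, m$values[, -1]), colnames(m$values)[1])
})

test_that("Q2: noiseless limit, null behaviour, and Q2 <= R2Y", {
  # deterministic linear relation, no noise: X is rank-1 along y
  set.seed(21)
  y <- rep(c(0, 1), 21)
  X <- (y - mean(y)) %o% c(1, -2, 3) +
    matrix(rnorm(42 * 3, sd = 1e-8), 42, 3)
  q2 <- crossvalidate_q2(X, y, n_orthogonal = 0, k = 7, transform = FALSE)
  expect_gt(q2, 0.99)
  # null: y independent of X -> Q2 near or below 0
  q2s <- replicate(30, {
    Xn <- scale(matrix(rnorm(30 * 8), 30, 8), scale = FALSE)
    yn <- rep(c(0, 1), length.out = 30)
    crossvalidate_q2(Xn, sample(yn), n_orthogonal = 0, k = 5,
                     transform = FALSE)
  })
  expect_lt(median(q2s), 0.05)
  # Q2 <= R2Y across random datasets
  for (r in 1:5) {
    set.seed(30 + r)
    Xr <- matrix(rlnorm(40 * 6, log(10), 0.4), 40, 6,
                 dimnames = list(paste0("S", 1:40), paste0("sp", 1:6)))
    yr <- rep(c(0, 1), each = 20)
    Xr[yr == 1, 1] <- Xr[yr == 1, 1] * 0.6
    fit <- opls_da(Xr, yr, n_orthogonal = 0, cv_folds = 5)
    expect_lte(fit$Q2, fit$R2Y + 1e-8)
  }
})

test_that("automatic orthogonal selection reacts to nuisance structure", {
  sep <- make_separable_X(n_per = 20, p = 6, gap = 6, seed = 3)
  expect_equal(auto_select_orthogonal(sep$X, sep$y, max_k = 3, k = 5,
                                      transform = FALSE), 0)
  set.seed(6)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  nuisance <- rnorm(n, sd = 6)
  X <- cbind((y - mean(y)) + 0.9 * nuisance + rnorm(n, 0.1),
             (y - mean(y)) - 0.9 * nuisance + rnorm(n, 0.1),
             nuisance + rnorm(n, sd = 0.2), rnorm(n), rnorm(n))
  X <- scale(X, scale = FALSE)
  k_sel <- auto_select_orthogonal(X, y, max_k = 3, k = 5, transform = FALSE)
  expect_gte(k_sel, 1)
  expect_lte(k_sel, 3)
})

test_that("classification boundary: 0.5 is non-cancer, strictly above is cancer", {
  expect_equal(classify_y(c(0.5, 0.51, -0.2, 1.3)),
               c("non-cancer", "cancer", "non-cancer", "cancer"))
})

test_that("classification metrics arithmetic and degenerate cases", {
  truth <- c(rep(1, 10), rep(0, 10))
  pred <- c(rep(1, 9), 0, rep(0, 8), 1, 1)
  r <- classification_metrics(truth, pred)
  expect_equal(r$sensitivity, 90)
  expect_equal(r$specificity, 80)
  expect_equal(r$accuracy, 85)
  expect_equal(r$accuracy, 100 * (r$tp + r$tn) / r$n)
  perfect <- classification_metrics(truth, truth)
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$accuracy),
               c(100, 100, 100))
  allpos <- classification_metrics(truth, rep(1, 20))
  expect_equal(allpos$specificity, 0)
  nopos <- classification_metrics(rep(0, 5), rep(0, 5))
  expect_true(is.na(nopos$sensitivity))
})

test_that("AUC equals exhaustive pairwise counting and handles ties", {
  set.seed(13)
  for (r in 1:10) {
    n <- sample(6:12, 1)
    truth <- c(rep(1, 3), rep(0, n - 3))[sample(n)]
    scores <- round(runif(n), 1)  # provoke ties
    auc <- roc_auc(scores, truth)$auc
    cases <- scores[truth == 1]; ctrls <- scores[truth == 0]
    pairs <- outer(cases, ctrls, function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(auc, mean(pairs), tolerance = 1e-12)
  }
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3))$auc, 1)
  expect_equal(roc_auc(rep(5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("VIP: normalization, algebraic identity, marker ranking", {
  sep <- make_separable_X(n_per = 15, p = 1, gap = 4, seed = 9)
  fit1 <- opls_da(sep$X, sep$y, n_orthogonal = 0, transform = FALSE,
                  cv_folds = 5)
  expect_equal(unname(vip(fit1)), 1, tolerance = 1e-12)
  # mean of squared VIP = 1 on any fitted model
  m <- make_db_cohort(n = 30, seed = 41)
  y <- rep(c(0, 1), 15)
  m$values[y == 1, 1:4] <- m$values[y == 1, 1:4] * 0.5
  for (k in 0:2) {
    fit <- opls_da(m, y, n_orthogonal = k, cv_folds = 5)
    expect_equal(mean(vip(fit)^2), 1, tolerance = 1e-10)
  }
})

test_that("informative markers outrank null species by VIP", {
  markers <- default_marker_panel()
  hits <- 0; reps <- 10
  for (r in seq_len(reps)) {
    cfg <- cohort_config(n_cases = 200, n_controls = 200, n_pancreatitis = 0,
                         n_lipids = 60, seed = 500 + r)
    ch <- generate_cohort(cfg)
    fit <- opls_da(ch$matrix, as.numeric(ch$samples$group == "T"),
                   n_orthogonal = 0, cv_folds = 7)
    top7 <- names(sort(vip(fit), decreasing = TRUE))[1:7]
    if (all(markers$name %in% top7)) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("S-plot coordinates: self-correlation, direction, bounds", {
  m <- make_db_cohort(n = 40, seed = 51)
  y <- rep(c(0, 1), 20)
  down <- colnames(m$values)[1:3]; up <- colnames(m$values)[4]
  m$values[y == 1, down] <- m$values[y == 1, down] * 0.4
  m$values[y == 1, up] <- m$values[y == 1, up] * 2.2
  fit <- opls_da(m, y, n_orthogonal = 0, cv_folds = 5)
  sp <- splot(fit, m)
  expect_true(all(abs(sp$pcorr1) <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(sp$pcorr1[sp$name %in% down] < 0))
  expect_true(all(sp$pcorr1[sp$name %in% up] > 0))
  # a variable equal (proportional) to the score itself has correlation 1
  X <- matrix(y - mean(y) + rnorm(40, sd = 0.3), ncol = 1,
              dimnames = list(NULL, "self"))
  fit2 <- opls_da(X, y, n_orthogonal = 0, transform = FALSE, cv_folds = 5)
  sp2 <- splot(fit2, X)
  expect_equal(sp2$pcorr1[sp2$name == "self"], 1, tolerance = 1e-10)
})

test_that("sample-order permutation leaves the fitted model invariant", {
  m <- make_db_cohort(n = 20, seed = 61)
  y <- rep(c(0, 1), 10)
  m$values[y == 1, 1:3] <- m$values[y == 1, 1:3] * 0.5
  fit <- opls_da(m, y, n_orthogonal = 0, cv_folds = 5)
  perm <- sample(20)
  fit_p <- opls_da(m$values[perm, ], y[perm], n_orthogonal = 0, cv_folds = 5)
  expect_equal(unname(fit_p$w), unname(fit$w), tolerance = 1e-10)
  expect_equal(unname(fit_p$t), unname(fit$t[perm]), tolerance = 1e-10)
})
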
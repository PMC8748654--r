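# Orthogonal projections to latent structures discriminant analysis
# (OPLS-DA), single-response NIPALS formulation: one predictive component
# plus zero or more orthogonal (class-unrelated) components, with
# 7-fold cross-validated Q2, automatic orthogonal-component selection,
# VIP scores and S-plot coordinates.

.norm2 <- function(v) sqrt(sum(v^2))

# core fit on a model-ready (transformed, column-centered) matrix;
# yc is the centered 0/1 response
.opls_core <- function(X, yc, n_orthogonal) {
  p_dim <- ncol(X)
  rank <- qr(X)$rank
  if (n_orthogonal >= rank)
    stop("n_orthogonal (", n_orthogonal, ") must be smaller than the rank of X (",
         rank, ")")
  W_o <- P_o <- matrix(0, p_dim, 0)
  T_o <- matrix(0, nrow(X), 0)
  Xd <- X
  for (k in seq_len(n_orthogonal)) {
    w <- drop(crossprod(Xd, yc))
    w <- w / .norm2(w)
    t_p <- drop(Xd %*% w)
    p_l <- drop(crossprod(Xd, t_p)) / sum(t_p^2)
    w_o <- p_l - drop(crossprod(w, p_l)) * w
    n_wo <- .norm2(w_o)
    if (n_wo < 1e-12)
      stop("no orthogonal variation left at component ", k)
    w_o <- w_o / n_wo
    t_o <- drop(Xd %*% w_o)
    p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
  }
  w <- drop(crossprod(Xd, yc))
  w <- w / .norm2(w)
  t_p <- drop(Xd %*% w)
  p_l <- drop(crossprod(Xd, t_p)) / sum(t_p^2)
  q <- sum(yc * t_p) / sum(t_p^2)
  # orient the predictive score so the case-class mean is positive
  if (mean(t_p[yc > 0]) < 0) {
    w <- -w; t_p <- -t_p; p_l <- -p_l; q <- -q
  }
  list(w = w, t = t_p, p = p_l, q = q, W_o = W_o, P_o = P_o, T_o = T_o,
       Xres = Xd)
}

.as_binary_y <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2) stop("y must have exactly two classes")
    lev <- levels(y)
    list(y = as.numeric(y == lev[2]), levels = lev)
  } else if (is.logical(y)) {
    list(y = as.numeric(y), levels = c("0", "1"))
  } else {
    u <- sort(unique(y))
    if (!all(u %in% c(0, 1)) || length(u) < 2)
      stop("y must be binary 0/1 with both classes present")
    list(y = as.numeric(y), levels = c("0", "1"))
  }
}

#' Fit an OPLS-DA classification model
#'
#' Orthogonal projections to latent structures discriminant analysis for a
#' binary response: a single predictive component plus `n_orthogonal`
#' orthogonal components capturing structured variation unrelated to the
#' class.  With `n_orthogonal = 0` the model is identical to 1-component
#' PLS1.  By default the concentrations are log-transformed, centered and
#' Pareto-scaled inside the fit and the parameters stored, so new samples
#' are transformed with the training parameters at prediction time.
#'
#' The predictive score is oriented so the case-class mean score is
#' positive.  Predicted responses are continuous; [classify_y()] applies
#' the 0.5 cutoff (predicted value > 0.5 means cancer).
#'
#' @param X Samples-by-species matrix or [conc_matrix()].  Raw positive
#'   concentrations when `transform = TRUE`; otherwise already model-ready
#'   (transformed and centered).
#' @param y Binary response: 0/1, logical, or a two-level factor whose
#'   second level is the case class.
#' @param n_orthogonal Number of orthogonal components, or `"auto"` to add
#'   components while 7-fold cross-validated Q2 improves by more than
#'   `q2_tol`.
#' @param max_orthogonal Upper bound for automatic selection.
#' @param transform Apply [transform_scale()] internally (default `TRUE`).
#' @param log,scaling Transformation options (see [transform_scale()]).
#' @param cv_folds,cv_seed Cross-validation folds (default 7) and the seed
#'   of the fold permutation.
#' @param q2_tol Minimum Q2 improvement to accept another orthogonal
#'   component (default 0.01).
#' @return Object of class `opls_da` with predictive weights `w`,
#'   loadings `p`, score `t`, response loading `q`, per-component
#'   orthogonal `w_o`/`p_o`/`t_o`, `R2X`, `R2Y`, `Q2`, `y_mean`, fitted
#'   values, the stored scaling parameters and class labels.
#' @seealso [predict.opls_da()], [vip()], [splot()], [crossvalidate_q2()]
#' @export
opls_da <- function(X, y, n_orthogonal = "auto", max_orthogonal = 5,
                    transform = TRUE, log = transform,
                    scaling = c("Pareto", "UV"),
                    cv_folds = 7, cv_seed = 1L, q2_tol = 0.01) {
  scaling <- match.arg(scaling)
  Xraw <- if (inherits(X, "conc_matrix")) X$values else as.matrix(X)
  if (is.null(colnames(Xraw)))
    colnames(Xraw) <- paste0("V", seq_len(ncol(Xraw)))
  yb <- .as_binary_y(y)
  if (nrow(Xraw) != length(yb$y)) stop("X and y dimensions disagree")

  if (transform) {
    ts <- transform_scale(Xraw, log = log, scaling = scaling)
    Xm <- ts$x
    params <- ts$params
  } else {
    Xm <- Xraw
    params <- NULL
  }

  if (identical(n_orthogonal, "auto")) {
    n_orthogonal <- auto_select_orthogonal(
      Xraw, yb$y, max_k = max_orthogonal, transform = transform, log = log,
      scaling = scaling, k = cv_folds, seed = cv_seed, q2_tol = q2_tol)
  }
  n_orthogonal <- as.integer(n_orthogonal)

  y_mean <- mean(yb$y)
  yc <- yb$y - y_mean
  core <- .opls_core(Xm, yc, n_orthogonal)

  fitted <- core$t * core$q + y_mean
  ss_y <- sum(yc^2)
  R2Y <- 1 - sum((yc - core$t * core$q)^2) / ss_y
  ss_x <- sum(Xm^2)
  expl <- sum((core$t %o% core$p)^2)
  if (ncol(core$T_o) > 0)
    expl <- expl + sum(vapply(seq_len(ncol(core$T_o)), function(k)
      sum((core$T_o[, k] %o% core$P_o[, k])^2), numeric(1)))
  R2X <- expl / ss_x

  model <- structure(list(
    w = stats::setNames(core$w, colnames(Xm)),
    p = stats::setNames(core$p, colnames(Xm)),
    t = stats::setNames(core$t, rownames(Xm)),
    q = core$q,
    w_o = core$W_o, p_o = core$P_o, t_o = core$T_o,
    n_orthogonal = n_orthogonal,
    y_mean = y_mean, y = yb$y, levels = yb$levels,
    R2X = R2X, R2Y = R2Y, Q2 = NA_real_,
    fitted = stats::setNames(fitted, rownames(Xm)),
    scaling_params = params,
    species = colnames(Xm),
    transform = transform,
    cv = list(folds = cv_folds, seed = cv_seed),
    call = match.call()
  ), class = "opls_da")

  model$Q2 <- crossvalidate_q2(Xraw, yb$y, n_orthogonal = n_orthogonal,
                               k = cv_folds, seed = cv_seed,
                               transform = transform, log = log,
                               scaling = scaling)
  model
}

# fold assignment: round-robin over a seeded permutation; redraw once if a
# fold has a single class
.cv_folds <- function(y, k, seed) {
  n <- length(y)
  if (n < k) stop("need at least as many samples as folds")
  for (attempt in 1:2) {
    set.seed(seed + attempt - 1L)
    perm <- sample.int(n)
    fold <- integer(n)
    fold[perm] <- rep_len(seq_len(k), n)
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(y[fold != f])) == 2, logical(1)))
    if (ok) return(fold)
  }
  stop("could not form folds with both classes in every training part")
}

#' Cross-validated Q2 of an OPLS-DA configuration
#'
#' Q2 = 1 - PRESS/SS(y - mean(y)) under k-fold (default 7) cross
#' validation with round-robin fold assignment on a seeded permutation.
#' Every fold is refit from scratch, including the transformation and
#' scaling parameters, and the held-out samples are transformed with the
#' fold's training parameters.
#'
#' @inheritParams opls_da
#' @param n_orthogonal Number of orthogonal components (integer).
#' @param k Number of folds.
#' @param seed Seed of the fold permutation.
#' @return Scalar Q2 (at most 1; can be negative).
#' @export
crossvalidate_q2 <- function(X, y, n_orthogonal = 0, k = 7, seed = 1L,
                             transform = TRUE, log = transform,
                             scaling = c("Pareto", "UV")) {
  scaling <- match.arg(scaling)
  Xraw <- if (inherits(X, "conc_matrix")) X$values else as.matrix(X)
  yb <- .as_binary_y(y)
  fold <- .cv_folds(yb$y, k, seed)
  press <- 0
  for (f in seq_len(k)) {
    tr <- fold != f
    if (transform) {
      ts <- transform_scale(Xraw[tr, , drop = FALSE], log = log,
                            scaling = scaling)
      Xtr <- ts$x
      Xte <- apply_scaling(ts$params, Xraw[!tr, , drop = FALSE])
    } else {
      Xtr <- Xraw[tr, , drop = FALSE]
      Xte <- Xraw[!tr, , drop = FALSE]
    }
    y_mean <- mean(yb$y[tr])
    core <- .opls_core(Xtr, yb$y[tr] - y_mean, n_orthogonal)
    Xte_f <- Xte
    if (ncol(core$W_o) > 0) {
      for (kk in seq_len(ncol(core$W_o))) {
        t_o <- drop(Xte_f %*% core$W_o[, kk])
        Xte_f <- Xte_f - tcrossprod(t_o, core$P_o[, kk])
      }
    }
    pred <- drop(Xte_f %*% core$w) * core$q + y_mean
    press <- press + sum((yb$y[!tr] - pred)^2)
  }
  1 - press / sum((yb$y - mean(yb$y))^2)
}

#' Choose the number of orthogonal components by cross validation
#'
#' Adds orthogonal components while the cross-validated Q2 improves by
#' more than `q2_tol` (default 0.01), up to `max_k`.
#'
#' @inheritParams crossvalidate_q2
#' @param max_k Maximum number of orthogonal components considered.
#' @param q2_tol Minimum improvement to accept another component.
#' @return Integer count of orthogonal components.
#' @export
auto_select_orthogonal <- function(X, y, max_k = 5, k = 7, seed = 1L,
                                   transform = TRUE, log = transform,
                                   scaling = c("Pareto", "UV"),
                                   q2_tol = 0.01) {
  stopifnot(max_k >= 0)
  scaling <- match.arg(scaling)
  best_k <- 0L
  q2 <- crossvalidate_q2(X, y, n_orthogonal = 0, k = k, seed = seed,
                         transform = transform, log = log, scaling = scaling)
  while (best_k < max_k) {
    q2_next <- tryCatch(
      crossvalidate_q2(X, y, n_orthogonal = best_k + 1L, k = k, seed = seed,
                       transform = transform, log = log, scaling = scaling),
      error = function(e) -Inf)
    if (q2_next - q2 > q2_tol) {
      best_k <- best_k + 1L
      q2 <- q2_next
    } else break
  }
  best_k
}

#' Predict continuous response values from an OPLS-DA model
#'
#' Removes the orthogonal variation from the new samples with the model's
#' orthogonal weights, then projects onto the predictive component:
#' `y_hat = t_pred * q + y_mean`.  When the model stores transformation
#' parameters, `newdata` is raw concentrations and is transformed with the
#' training parameters first.
#'
#' @param object An [opls_da()] model.
#' @param newdata Matrix or [conc_matrix()] with at least the model's
#'   species; missing species are an error naming them.
#' @param type `"response"` (continuous predicted Y), `"class"` (labels
#'   via [classify_y()]), or `"scores"` (predictive score).
#' @param ... Unused.
#' @return Numeric vector, or character labels for `type = "class"`.
#' @export
predict.opls_da <- function(object, newdata,
                            type = c("response", "class", "scores"), ...) {
  type <- match.arg(type)
  Xn <- if (inherits(newdata, "conc_matrix")) newdata$values
        else as.matrix(newdata)
  if (is.null(colnames(Xn))) {
    if (ncol(Xn) != length(object$species))
      stop("newdata has no column names and the wrong number of columns")
    colnames(Xn) <- object$species
  }
  if (object$transform) {
    Xn <- apply_scaling(object$scaling_params, Xn)
  } else {
    missing_sp <- setdiff(object$species, colnames(Xn))
    if (length(missing_sp))
      stop("species missing from new data: ",
           paste(missing_sp, collapse = ", "))
    Xn <- Xn[, object$species, drop = FALSE]
  }
  if (ncol(object$w_o) > 0) {
    for (k in seq_len(ncol(object$w_o))) {
      t_o <- drop(Xn %*% object$w_o[, k])
      Xn <- Xn - tcrossprod(t_o, object$p_o[, k])
    }
  }
  t_pred <- drop(Xn %*% object$w)
  if (type == "scores") return(t_pred)
  y_hat <- t_pred * object$q + object$y_mean
  if (type == "class") return(classify_y(y_hat, labels = object$levels))
  y_hat
}

#' @export
fitted.opls_da <- function(object, ...) object$fitted

#' @export
residuals.opls_da <- function(object, ...) object$y - object$fitted

#' Predictive-component regression coefficients
#'
#' The linear map from model-ready (transformed, centered) variables to
#' the predicted response, folding the orthogonal filtering and the
#' predictive projection into one coefficient vector; the intercept (the
#' training-class mean) is attached as an attribute.
#'
#' @param object An [opls_da()] model.
#' @param ... Unused.
#' @return Named numeric vector with attribute `"intercept"`.
#' @export
coef.opls_da <- function(object, ...) {
  b <- object$w
  if (ncol(object$w_o) > 0) {
    M <- diag(length(b))
    for (k in seq_len(ncol(object$w_o)))
      M <- M %*% (diag(length(b)) - tcrossprod(object$w_o[, k], object$p_o[, k]))
    b <- drop(M %*% object$w)
  }
  b <- b * object$q
  names(b) <- object$species
  attr(b, "intercept") <- object$y_mean
  b
}

#' @export
print.opls_da <- function(x, ...) {
  cat("OPLS-DA model: 1 predictive +", x$n_orthogonal,
      "orthogonal component(s)\n")
  cat(sprintf("n = %d (%d cases), %d species\n", length(x$y), sum(x$y == 1),
              length(x$species)))
  cat(sprintf("R2X = %.3f  R2Y = %.3f  Q2(%d-fold CV) = %.3f\n",
              x$R2X, x$R2Y, x$cv$folds, x$Q2))
  invisible(x)
}

#' @export
summary.opls_da <- function(object, ...) {
  v <- vip(object)
  rep <- classification_metrics(object$y,
                                as.numeric(object$fitted > 0.5))
  structure(list(model = object, vip_top = sort(v, decreasing = TRUE)[1:min(10, length(v))],
                 training_metrics = rep), class = "summary.opls_da")
}

#' @export
print.summary.opls_da <- function(x, ...) {
  print(x$model)
  cat("\nTraining classification (0.5 cutoff):\n")
  print(x$training_metrics)
  cat("\nTop VIP species:\n")
  print(round(x$vip_top, 2))
  invisible(x)
}

#' @export
plot.opls_da <- function(x, ...) {
  t_o1 <- if (ncol(x$t_o) > 0) x$t_o[, 1] else stats::rnorm(length(x$t), 0, 1e-6)
  graphics::plot(x$t, t_o1, col = ifelse(x$y == 1, "red", "blue"),
                 pch = 19, xlab = "predictive score t",
                 ylab = if (ncol(x$t_o) > 0) "orthogonal score t_o1" else "(jitter)",
                 main = "OPLS-DA scores", ...)
  graphics::legend("topright", legend = rev(x$levels), col = c("red", "blue"),
                   pch = 19, bty = "n")
  invisible(x)
}

#' Variable importance in projection
#'
#' VIP of every species over the predictive and orthogonal components,
#' weighted by each component's share of explained response variation:
#' `VIP_j = sqrt(J * sum_a SSY_a (w_aj/||w_a||)^2 / sum_a SSY_a)`.
#' Orthogonal components explain essentially no response variation by
#' construction, so the result is numerically close to predictive-only
#' VIP.  The mean of squared VIP over species is exactly 1.
#'
#' @param model An [opls_da()] model.
#' @return Named numeric vector of VIP values.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "opls_da"))
  J <- length(model$w)
  yc <- model$y - model$y_mean
  comps <- list(list(w = model$w, t = model$t))
  if (ncol(model$w_o) > 0)
    for (k in seq_len(ncol(model$w_o)))
      comps <- c(comps, list(list(w = model$w_o[, k], t = model$t_o[, k])))
  ssy <- vapply(comps, function(cp) {
    qa <- sum(yc * cp$t) / sum(cp$t^2)
    qa^2 * sum(cp$t^2)
  }, numeric(1))
  wnorm2 <- vapply(comps, function(cp) sum(cp$w^2), numeric(1))
  acc <- rep(0, J)
  for (a in seq_along(comps))
    acc <- acc + ssy[a] * comps[[a]]$w^2 / wnorm2[a]
  stats::setNames(sqrt(J * acc / sum(ssy)), model$species)
}

#' S-plot coordinates
#'
#' For every species, the covariance (`p1`) and Pearson correlation
#' (`pcorr1`) of the predictive score with the species column of the
#' training data, on the model-ready scale.  Species downregulated in
#' cases appear with negative coordinates, upregulated with positive.
#'
#' @param model An [opls_da()] model.
#' @param X Training data; raw concentrations when the model stores
#'   transformation parameters, else the model-ready matrix.
#' @return Data frame with columns `name`, `p1`, `pcorr1` (zero-variance
#'   species get `NA` correlation).
#' @export
splot <- function(model, X) {
  stopifnot(inherits(model, "opls_da"))
  Xm <- if (inherits(X, "conc_matrix")) X$values else as.matrix(X)
  if (model$transform) Xm <- apply_scaling(model$scaling_params, Xm)
  else Xm <- Xm[, model$species, drop = FALSE]
  t_p <- model$t
  n <- length(t_p)
  p1 <- drop(crossprod(Xm - matrix(colMeans(Xm), n, ncol(Xm), byrow = TRUE),
                       t_p - mean(t_p))) / (n - 1)
  sds <- apply(Xm, 2, stats::sd)
  pcorr1 <- ifelse(sds > 0, p1 / (sds * stats::sd(t_p)), NA_real_)
  data.frame(name = model$species, p1 = p1, pcorr1 = pcorr1,
             row.names = NULL, stringsAsFactors = FALSE)
}
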
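# Classification of continuous predicted responses, diagnostic metrics
# and ROC/AUC.

#' Classify predicted response values at the 0.5 cutoff
#'
#' A sample is called cancer iff its predicted response is strictly
#' greater than the cutoff; a predicted value exactly at the cutoff is
#' non-cancer.
#'
#' @param y_hat Numeric predicted response values.
#' @param cutoff Decision boundary (default 0.5).
#' @param labels Length-2 character vector `c(non-cancer, cancer)`.
#' @return Character vector of class labels.
#' @export
classify_y <- function(y_hat, cutoff = 0.5, labels = c("non-cancer", "cancer")) {
  stopifnot(length(labels) == 2)
  ifelse(y_hat > cutoff, labels[2], labels[1])
}

#' Diagnostic classification metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and accuracy
#' `(TP+TN)/n`, reported as percentages, with the confusion counts.
#' With no positive samples, sensitivity is reported as missing (and
#' correspondingly for specificity).
#'
#' @param truth,predicted Binary vectors (0/1, logical, or two-level
#'   factors with the case class as second level) of equal length.
#' @param set Optional label (`"training"` / `"validation"`) carried in
#'   the report.
#' @return Object of class `classification_report` with fields
#'   `sensitivity`, `specificity`, `accuracy` (percent), `tp`, `fn`,
#'   `tn`, `fp`, `n`, `set`.
#' @export
classification_metrics <- function(truth, predicted, set = NA_character_) {
  to01 <- function(v) {
    if (is.factor(v)) as.numeric(v == levels(v)[2])
    else if (is.character(v)) stop("character labels need factors")
    else as.numeric(v)
  }
  truth <- to01(truth); predicted <- to01(predicted)
  stopifnot(length(truth) == length(predicted),
            all(truth %in% 0:1), all(predicted %in% 0:1))
  tp <- sum(truth == 1 & predicted == 1)
  fn <- sum(truth == 1 & predicted == 0)
  tn <- sum(truth == 0 & predicted == 0)
  fp <- sum(truth == 0 & predicted == 1)
  n <- length(truth)
  structure(list(
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    accuracy = 100 * (tp + tn) / n,
    tp = tp, fn = fn, tn = tn, fp = fp, n = n, set = set
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  lab <- if (!is.na(x$set)) paste0(" (", x$set, ")") else ""
  cat(sprintf(
    "sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%%s [TP=%d FN=%d TN=%d FP=%d]\n",
    x$sensitivity, x$specificity, x$accuracy, lab, x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the observed scores; the AUC is computed with the
#' rank (Mann-Whitney) formulation, so ties contribute one half:
#' `AUC = P(score_case > score_control) + 0.5 * P(tie)`; this equals the
#' trapezoid-rule area under the tie-aware ROC curve.
#'
#' @param scores Numeric classifier scores (higher = more case-like).
#' @param truth Binary ground truth (case = 1).
#' @return List of class `roc_curve` with `roc` (data frame of
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- if (is.factor(truth)) as.numeric(truth == levels(truth)[2])
           else as.numeric(truth)
  stopifnot(length(scores) == length(truth), all(truth %in% 0:1))
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for a ROC curve")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(th) {
    pred <- scores >= th
    c(fpr = sum(pred & truth == 0) / n0, tpr = sum(pred & truth == 1) / n1)
  }, numeric(2)))
  structure(list(roc = data.frame(threshold = thr, fpr = pts[, "fpr"],
                                  tpr = pts[, "tpr"]),
                 auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", nrow(x$roc), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "s", xlab = "1 - specificity",
                 ylab = "sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}
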
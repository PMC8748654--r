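# Prognostic analysis: median dichotomization of lipid concentrations,
# Kaplan-Meier estimation, log-rank testing and Cox proportional-hazards
# modelling with hazard-ratio confidence intervals.

#' Median-dichotomize a concentration vector
#'
#' The median is computed over all samples; code 1 for concentrations
#' strictly above the median and 0 otherwise (values exactly at the
#' median get code 0 by default; `ties = "high"` assigns them 1).
#'
#' @param values Numeric vector (at least two values).
#' @param ties Code for values equal to the median: `"low"` (0, default)
#'   or `"high"` (1).
#' @return List with `code` (integer 0/1 vector) and `median`.
#' @export
dichotomize_by_median <- function(values, ties = c("low", "high")) {
  ties <- match.arg(ties)
  stopifnot(length(values) >= 2)
  med <- stats::median(values, na.rm = TRUE)
  code <- if (ties == "low") as.integer(values > med)
          else as.integer(values >= med)
  code[is.na(values)] <- NA_integer_
  list(code = code, median = med)
}

.surv_check <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (any(time < 0, na.rm = TRUE)) stop("negative survival times")
  if (!all(stats::na.omit(event) %in% 0:1)) stop("event must be 0/1")
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator of the survival function for each level of
#' `group`, with right censoring.
#'
#' @param time Survival times (months).
#' @param event Event indicator (1 = death observed, 0 = censored).
#' @param group Grouping vector (e.g. the median-dichotomized binary
#'   code); every group must be non-empty.
#' @return A `survival::survfit` object.
#' @export
km_fit <- function(time, event, group) {
  .surv_check(time, event)
  if (any(table(factor(group)) == 0) || anyNA(group))
    stop("every group must contain at least one record")
  d <- data.frame(time = time, event = event, group = factor(group))
  survival::survfit(survival::Surv(time, event) ~ group, data = d)
}

#' Two-sided log-rank test between two groups
#'
#' @inheritParams km_fit
#' @return List with `chi2` (1-df chi-square statistic) and `p`.
#' @export
logrank_test <- function(time, event, group) {
  .surv_check(time, event)
  g <- factor(group)
  if (nlevels(g) != 2) stop("log-rank test requires exactly two groups")
  if (sum(event, na.rm = TRUE) == 0) stop("no events observed")
  d <- data.frame(time = time, event = event, group = g)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  chi2 <- sd$chisq
  list(chi2 = unname(chi2), p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization (Newton-Raphson, Breslow tie handling
#' by default) for one or more covariates, typically median-dichotomized
#' binary lipid codes.  Hazard ratios above 1 indicate poorer survival for
#' code 1.  Confidence intervals are `exp(beta +/- 1.96 * SE)` from the
#' inverse observed information.
#'
#' @param time,event Survival outcome (see [km_fit()]).
#' @param covariates Data frame or matrix of covariates (constant columns
#'   and duplicated/collinear columns are an error).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return Object of class `cox_fit`: data frame with one row per
#'   covariate (`name`, `beta`, `se`, `hr`, `ci_low`, `ci_high`, `p`)
#'   plus the underlying `survival::coxph` fit as attribute `"fit"`.
#' @export
cox_fit <- function(time, event, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  .surv_check(time, event)
  if (sum(event, na.rm = TRUE) == 0) stop("no events observed")
  cv <- as.data.frame(covariates)
  if (!ncol(cv)) stop("at least one covariate required")
  if (any(vapply(cv, function(x) stats::var(as.numeric(x)) == 0, logical(1))))
    stop("constant covariate")
  d <- cbind(data.frame(time = time, event = event), cv)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(sprintf("`%s`", names(cv)),
                                       collapse = " + ")))
  fit <- survival::coxph(fml, data = d, ties = ties,
                         control = survival::coxph.control(iter.max = 100))
  if (anyNA(stats::coef(fit)))
    stop("singular information matrix (collinear covariates); fit refused")
  if (any(abs(stats::coef(fit)) > 15))
    stop("separation detected (diverging coefficient)")
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  res <- data.frame(
    name = names(beta), beta = unname(beta), se = unname(se),
    hr = exp(unname(beta)),
    ci_low = exp(unname(beta) - 1.96 * unname(se)),
    ci_high = exp(unname(beta) + 1.96 * unname(se)),
    p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  class(res) <- c("cox_fit", "data.frame")
  attr(res, "fit") <- fit
  res
}

#' Forest-plot table from Cox fits
#'
#' One row per covariate across a list of fits, in input order, ready for
#' export.
#'
#' @param fits A [cox_fit()] or list of them.
#' @return Data frame with columns `name`, `hr`, `ci_low`, `ci_high`,
#'   `p`.
#' @export
forest_table <- function(fits) {
  if (inherits(fits, "cox_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1)
  rows <- lapply(fits, function(f) {
    stopifnot(inherits(f, "cox_fit"))
    f[, c("name", "hr", "ci_low", "ci_high", "p")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a Kaplan-Meier fit as a step-function table
#'
#' @param fit A `survfit` object from [km_fit()].
#' @return Data frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `surv`.
#' @export
km_table <- function(fit) {
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) "all" else sub("^group=", "", as.character(s$strata))
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, surv = s$surv, stringsAsFactors = FALSE)
}
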
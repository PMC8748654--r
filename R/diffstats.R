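# Univariate dysregulation statistics: Welch test, Bonferroni correction,
# symmetric fold-change screening, relevance selection, cross-method
# agreement (RSD), and box-plot summaries.

#' Welch two-sample t-test
#'
#' Two-sided two-sample t-test assuming unequal variances
#' (Welch-Satterthwaite degrees of freedom).
#'
#' @param a,b Numeric vectors (each with at least two values).
#' @return List with `t`, `df`, `p`.
#' @export
welch_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least two values")
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Bonferroni multiple-testing correction
#'
#' `p_adj = min(1, m * p)` with `m` the number of tests.
#'
#' @param p Numeric p-values.
#' @param m Number of tests (defaults to `length(p)`; must be at least
#'   that).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(m >= length(p))
  pmin(1, m * p)
}

#' Fold change between group means
#'
#' Ratio of case over control means, with the symmetric percent change
#' `(max(r, 1/r) - 1) * 100` so down- and upregulation are screened alike;
#' the 20% boundary is inclusive (a ratio of exactly 1.20 or 1/1.20
#' passes).
#'
#' @param mean_t,mean_n Group means (both > 0).
#' @return List with `ratio`, `percent_change`, `direction`
#'   (`"up"`/`"down"`).
#' @export
fold_change <- function(mean_t, mean_n) {
  if (any(c(mean_t, mean_n) <= 0)) stop("group means must be positive")
  r <- mean_t / mean_n
  list(ratio = r,
       percent_change = (max(r, 1 / r) - 1) * 100,
       direction = if (r < 1) "down" else "up")
}

#' Per-species dysregulation table
#'
#' For every species: group mean concentrations, fold change cases over
#' controls, direction, Welch test statistic/df/p-value, Bonferroni-
#' adjusted p-value, and (when supplied) the VIP value from the matching
#' OPLS-DA model.  Run [select_relevant()] on the result to flag the
#' statistically relevant species.
#'
#' @param m A [conc_matrix()] or matrix (imputed, positive values).
#' @param group Vector with case samples coded `"T"` and controls `"N"`
#'   (other codes are ignored).
#' @param vip Optional named VIP vector (see [vip()]).
#' @param m_tests Number of tests for the Bonferroni correction; defaults
#'   to the number of species in the table.
#' @return Data frame of class `diff_table`.
#' @export
diff_table <- function(m, group, vip = NULL, m_tests = NULL) {
  x <- if (inherits(m, "conc_matrix")) m$values else as.matrix(m)
  stopifnot(nrow(x) == length(group))
  ti <- group == "T"; ni <- group == "N"
  if (sum(ti) < 2 || sum(ni) < 2)
    stop("need at least two cases and two controls")
  species <- colnames(x)
  if (is.null(m_tests)) m_tests <- length(species)
  rows <- lapply(species, function(sp) {
    a <- x[ti, sp]; b <- x[ni, sp]
    w <- welch_test(a, b)
    fc <- fold_change(mean(a), mean(b))
    data.frame(name = sp, mean_T = mean(a), mean_N = mean(b),
               fold_change = fc$ratio, percent_change = fc$percent_change,
               direction = fc$direction, t_stat = w$t, df_welch = w$df,
               p_value = w$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni(out$p_value, m_tests)
  out$vip <- if (is.null(vip)) NA_real_ else unname(vip[out$name])
  class(out) <- c("diff_table", "data.frame")
  out
}

#' Flag statistically relevant species
#'
#' A species is relevant when all three criteria hold: Welch p-value
#' strictly below `alpha`, VIP strictly above `vip_min`, and symmetric
#' fold change at least `fc_min_percent` percent (inclusive boundary).
#' Species passing the Bonferroni-adjusted p-value threshold are
#' additionally flagged as especially significant.  Species without a VIP
#' value are marked not evaluable with a warning.
#'
#' @param diff A [diff_table()].
#' @param alpha Welch p-value threshold (default 0.05, strict).
#' @param vip_min VIP threshold (default 1, strict).
#' @param fc_min_percent Fold-change threshold in percent (default 20,
#'   inclusive).
#' @return The table with logical columns `relevant`,
#'   `especially_significant` and `evaluable` added.
#' @export
select_relevant <- function(diff, alpha = 0.05, vip_min = 1,
                            fc_min_percent = 20) {
  stopifnot(inherits(diff, "data.frame"))
  evaluable <- !is.na(diff$vip)
  if (any(!evaluable))
    warning("species without VIP are not evaluable: ",
            paste(diff$name[!evaluable], collapse = ", "))
  diff$evaluable <- evaluable
  diff$relevant <- evaluable &
    diff$p_value < alpha &
    diff$vip > vip_min &
    diff$percent_change >= fc_min_percent
  diff$relevant[is.na(diff$relevant)] <- FALSE
  diff$especially_significant <- diff$relevant & diff$p_bonferroni < alpha
  diff
}

#' Cross-method relative standard deviation per sample and species
#'
#' For each sample and species, the RSD (sd/mean * 100) of the
#' concentrations reported by the different methods (after NIST
#' normalization).  Samples present in fewer than two methods get a
#' missing value.
#'
#' @param matrices Named list of [conc_matrix()] objects, one per method.
#' @param species Character vector of species to evaluate.
#' @return Data frame with columns `sample_id`, `name`, `n_methods`,
#'   `rsd`.
#' @export
rsd_across_methods <- function(matrices, species) {
  stopifnot(is.list(matrices), length(matrices) >= 2)
  ids <- sort(unique(unlist(lapply(matrices, function(m) rownames(m$values)))))
  out <- list()
  for (sp in species) {
    vals <- vapply(matrices, function(m) {
      v <- rep(NA_real_, length(ids))
      if (sp %in% colnames(m$values)) {
        hit <- match(rownames(m$values), ids)
        v[hit] <- m$values[, sp]
      }
      v
    }, numeric(length(ids)))
    vals <- matrix(vals, nrow = length(ids))
    n_methods <- rowSums(!is.na(vals))
    rsd <- apply(vals, 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2 || mean(v) == 0) return(NA_real_)
      stats::sd(v) / mean(v) * 100
    })
    out[[sp]] <- data.frame(sample_id = ids, name = sp,
                            n_methods = n_methods, rsd = rsd,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Box-plot summary statistics
#'
#' Median, 1st and 3rd quartile (type-7 linear interpolation), and
#' whisker bounds per group.  By convention the whiskers span 1.5 times
#' the inter-quartile range from the median (clipped to the data range);
#' `from = "quartile"` switches to the common Tukey convention (1.5 IQR
#' from the quartiles).  Points outside the whiskers are outliers.
#'
#' @param values Numeric vector.
#' @param group Grouping vector of the same length.
#' @param from Whisker anchor: `"median"` (default) or `"quartile"`.
#' @return Data frame with one row per group: `group`, `n`, `median`,
#'   `q1`, `q3`, `whisker_low`, `whisker_high`, `n_outliers`.
#' @export
boxplot_summary <- function(values, group, from = c("median", "quartile")) {
  from <- match.arg(from)
  stopifnot(length(values) == length(group))
  groups <- unique(group)
  rows <- lapply(groups, function(g) {
    v <- values[group == g & !is.na(values)]
    if (!length(v)) stop("empty group: ", g)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    anchor_lo <- if (from == "median") q[2] else q[1]
    anchor_hi <- if (from == "median") q[2] else q[3]
    lo <- max(min(v), anchor_lo - 1.5 * iqr)
    hi <- min(max(v), anchor_hi + 1.5 * iqr)
    data.frame(group = g, n = length(v), median = q[2], q1 = q[1], q3 = q[3],
               whisker_low = lo, whisker_high = hi,
               n_outliers = sum(v < lo | v > hi),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
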
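# Run configuration with the frozen analysis thresholds, CA 19-9
# operations, QC monitoring, model serialization and end-to-end pipeline
# orchestration.

#' Pipeline run configuration
#'
#' Bundles every tunable threshold of the analysis with its standard
#' default: 3000-count extraction threshold, 5 mDa matching tolerance,
#' 25% presence filter, 80%-of-minimum imputation, 0.5 predicted-response
#' cutoff, 0.05 significance level, VIP > 1, 20% fold change, 37 U/mL
#' CA 19-9 cutoff, 7-fold cross validation, every-6th validation split,
#' QC injection after every 40 samples.
#'
#' @param min_intensity Peak extraction threshold (counts).
#' @param tolerance Mass-matching tolerance (mDa).
#' @param min_presence Species presence fraction for retention.
#' @param impute_factor Fraction of the species minimum used to replace
#'   zeros.
#' @param y_cutoff Predicted-response classification boundary.
#' @param alpha Welch significance level.
#' @param vip_min VIP threshold (strict).
#' @param fc_min_percent Fold-change threshold (percent, inclusive).
#' @param ca199_cutoff CA 19-9 clinical cutoff (U/mL, strict).
#' @param scaling `"Pareto"` or `"UV"`.
#' @param cv_folds Cross-validation folds.
#' @param split_every Every n-th sample to validation.
#' @param qc_every QC cadence (samples between QC injections).
#' @param max_orthogonal Cap for automatic orthogonal-component selection.
#' @param seed Master seed (splitting and cross validation).
#' @return Object of class `run_config`.
#' @export
run_config <- function(min_intensity = 3000, tolerance = 5,
                       min_presence = 0.25, impute_factor = 0.8,
                       y_cutoff = 0.5, alpha = 0.05, vip_min = 1,
                       fc_min_percent = 20, ca199_cutoff = 37,
                       scaling = c("Pareto", "UV"), cv_folds = 7,
                       split_every = 6, qc_every = 40,
                       max_orthogonal = 5, seed = 1L) {
  scaling <- match.arg(scaling)
  cfg <- list(min_intensity = min_intensity, tolerance = tolerance,
              min_presence = min_presence, impute_factor = impute_factor,
              y_cutoff = y_cutoff, alpha = alpha, vip_min = vip_min,
              fc_min_percent = fc_min_percent, ca199_cutoff = ca199_cutoff,
              scaling = scaling, cv_folds = cv_folds,
              split_every = split_every, qc_every = qc_every,
              max_orthogonal = max_orthogonal, seed = as.integer(seed))
  if (any(vapply(cfg[c("min_intensity", "tolerance", "min_presence",
                       "impute_factor", "y_cutoff", "alpha", "vip_min",
                       "fc_min_percent", "ca199_cutoff")],
                 function(v) !is.numeric(v) || v < 0, logical(1))))
    stop("thresholds must be non-negative numbers")
  structure(cfg, class = "run_config")
}

#' Classify CA 19-9 values at the clinical cutoff
#'
#' Values strictly over the cutoff (37 U/mL) are classified PDAC; a value
#' exactly at the cutoff is negative.  Missing values give a missing
#' classification.
#'
#' @param value CA 19-9 concentrations (U/mL, >= 0).
#' @param cutoff Clinical cutoff (default 37).
#' @return Character vector `"PDAC"` / `"negative"` (NA where missing).
#' @export
classify_ca199 <- function(value, cutoff = 37) {
  if (any(value < 0, na.rm = TRUE)) stop("CA 19-9 values must be >= 0")
  ifelse(is.na(value), NA_character_,
         ifelse(value > cutoff, "PDAC", "negative"))
}

#' Append CA 19-9 as an additional model variable
#'
#' Adds log-transformed CA 19-9 as one extra column to a concentration
#' matrix so a combined lipidomics + CA 19-9 model can be trained with the
#' same transformation scheme.  Samples with missing CA 19-9 are dropped
#' with a warning.  A constant CA 19-9 column is dropped again (it carries
#' no information and would break unit-variance scaling), in which case
#' the result equals the lipid-only matrix.
#'
#' @param m A [conc_matrix()] or matrix.
#' @param ca199 CA 19-9 values (U/mL) aligned with the rows of `m`.
#' @param column Name of the appended column.
#' @return List with `matrix` (a [conc_matrix()]) and `kept` (logical row
#'   mask of retained samples).
#' @export
combine_with_ca199 <- function(m, ca199, column = "CA19-9") {
  x <- if (inherits(m, "conc_matrix")) m$values else as.matrix(m)
  stopifnot(nrow(x) == length(ca199))
  if (all(is.na(ca199))) stop("all CA 19-9 values are missing")
  keep <- !is.na(ca199)
  if (any(!keep))
    warning(sum(!keep), " sample(s) dropped for missing CA 19-9")
  x <- x[keep, , drop = FALSE]
  v <- ca199[keep]
  if (stats::var(v) > 0) {
    # stored on the concentration scale; the model log-transforms with the
    # same scheme as the lipid species
    x <- cbind(x, matrix(v, ncol = 1, dimnames = list(rownames(x), column)))
  }
  list(matrix = conc_matrix(x), kept = keep)
}

# Theil-Sen slope/intercept: median of pairwise slopes
.theil_sen <- function(x, y) {
  n <- length(x)
  slopes <- numeric(0)
  for (i in seq_len(n - 1)) {
    dx <- x[(i + 1):n] - x[i]
    dy <- y[(i + 1):n] - y[i]
    ok <- dx != 0
    slopes <- c(slopes, dy[ok] / dx[ok])
  }
  b <- stats::median(slopes)
  a <- stats::median(y - b * x)
  c(intercept = a, slope = b)
}

#' Monitor signal drift over the injection sequence
#'
#' Fits a robust (Theil-Sen) linear trend of intensity against injection
#' order for each monitored species, flags injections deviating more than
#' `k` median absolute deviations from the trend, and reports the RSD of
#' the QC injections.
#'
#' @param intensities Numeric matrix, injections in rows (in measurement
#'   order), monitored species in columns; at least 10 injections.
#' @param qc_positions Integer positions of the QC injections (may be
#'   empty).
#' @param k MAD multiplier for flagging (default 4).
#' @return List of class `qc_drift_report` with per-species `trend`
#'   (intercept, slope, relative slope %/injection), `flagged`
#'   (data frame of species, injection, residual), and `qc_rsd` (percent,
#'   per species; NA without QC positions).
#' @export
qc_drift_monitor <- function(intensities, qc_positions = integer(0), k = 4) {
  x <- as.matrix(intensities)
  if (nrow(x) < 10) stop("need at least 10 injections")
  if (is.null(colnames(x))) colnames(x) <- paste0("species", seq_len(ncol(x)))
  ord <- seq_len(nrow(x))
  trend <- list(); flagged <- list(); qc_rsd <- numeric(0)
  for (sp in colnames(x)) {
    fit <- .theil_sen(ord, x[, sp])
    pred <- fit["intercept"] + fit["slope"] * ord
    resid <- x[, sp] - pred
    mad_r <- stats::mad(resid)
    hit <- if (mad_r > 0) which(abs(resid) > k * mad_r) else integer(0)
    trend[[sp]] <- c(fit,
                     rel_slope_pct = unname(100 * fit["slope"] / mean(x[, sp])))
    if (length(hit))
      flagged[[sp]] <- data.frame(name = sp, injection = hit,
                                  residual = resid[hit],
                                  stringsAsFactors = FALSE)
    qc_rsd[sp] <- if (length(qc_positions) >= 2) {
      v <- x[qc_positions, sp]
      stats::sd(v) / mean(v) * 100
    } else NA_real_
  }
  flagged <- if (length(flagged)) do.call(rbind, c(flagged, make.row.names = FALSE))
             else data.frame(name = character(0), injection = integer(0),
                             residual = numeric(0))
  structure(list(trend = trend, flagged = flagged, qc_rsd = qc_rsd),
            class = "qc_drift_report")
}

#' @export
print.qc_drift_report <- function(x, ...) {
  cat("QC drift report:", length(x$trend), "species,",
      nrow(x$flagged), "flagged injection(s)\n")
  invisible(x)
}

#' Serialize / restore an OPLS-DA model as JSON
#'
#' Writes all weights, loadings, scores, scaling parameters and component
#' counts to a documented JSON file; `read_opls_model` restores a model
#' whose predictions are identical.
#'
#' @param model An [opls_da()] model.
#' @param path File path.
#' @return `read_opls_model` returns an `opls_da` object.
#' @export
write_opls_model <- function(model, path) {
  stopifnot(inherits(model, "opls_da"))
  obj <- model
  obj$call <- NULL
  obj$w_o <- as.data.frame(obj$w_o)
  obj$p_o <- as.data.frame(obj$p_o)
  obj$t_o <- as.data.frame(obj$t_o)
  jsonlite::write_json(unclass(obj), path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_opls_model
#' @export
read_opls_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("w_o", "p_o", "t_o")) {
    m <- as.matrix(as.data.frame(obj[[f]]))
    if (!length(m)) m <- matrix(0, length(obj$w), 0)
    dimnames(m) <- NULL
    obj[[f]] <- m
  }
  for (f in c("w", "p")) obj[[f]] <- stats::setNames(as.numeric(obj[[f]]),
                                                     obj$species)
  obj$scaling_params$center <- stats::setNames(
    as.numeric(obj$scaling_params$center), obj$species)
  obj$scaling_params$scale <- stats::setNames(
    as.numeric(obj$scaling_params$scale), obj$species)
  structure(obj, class = "opls_da")
}

#' Run the full screening pipeline on a cohort
#'
#' Orchestrates the cohort-level analysis from a concentration matrix and
#' sample metadata: presence filtering, imputation, every-6th
#' train/validation split, gender-separated OPLS-DA with automatic
#' orthogonal-component selection, classification metrics and ROC for
#' training and validation sets, per-gender dysregulation tables, CA 19-9
#' comparison/combination, and (when survival data are present) per-lipid
#' Cox fits.  All report files are written under `out_dir` together with
#' a manifest of seeds and thresholds.
#'
#' @param matrix A [conc_matrix()] (cases and controls; other groups are
#'   dropped with a message).
#' @param samples Matching metadata (see [generate_cohort()]).
#' @param config A [run_config()].
#' @param out_dir Output directory (created); `NULL` disables file
#'   output.
#' @param survival_species Species for the survival analysis (default:
#'   species flagged relevant in either gender, capped at 8).
#' @return List of class `pipeline_result` with per-gender model, metrics
#'   and dysregulation tables, pooled validation metrics, CA 19-9
#'   comparison, and survival results.
#' @export
run_pipeline <- function(matrix, samples, config = run_config(),
                         out_dir = NULL, survival_species = NULL) {
  stopifnot(inherits(matrix, "conc_matrix"), inherits(config, "run_config"))
  if (!identical(rownames(matrix$values), samples$sample_id))
    stop("matrix rows and sample table disagree")
  keep <- samples$group %in% c("T", "N")
  if (any(!keep)) {
    message("dropping ", sum(!keep), " non-T/N sample(s) from classification")
    matrix <- conc_matrix(matrix$values[keep, , drop = FALSE],
                          matrix$provenance[keep, , drop = FALSE])
    samples <- samples[keep, , drop = FALSE]
  }

  filtered <- filter_by_presence(matrix, config$min_presence)
  imputed <- impute_zeros(filtered, config$impute_factor)
  split <- split_train_validation(samples, seed = config$seed,
                                  every = config$split_every)
  strata <- stratify_by_gender(imputed, samples)

  genders <- list()
  pooled_truth <- numeric(0); pooled_pred <- numeric(0)
  pooled_scores <- numeric(0)
  for (g in c("male", "female")) {
    part <- strata[[g]]
    if (!nrow(part$samples)) next
    sset <- split$set[match(part$samples$sample_id, split$sample_id)]
    tr <- sset == "training"
    y <- as.numeric(part$samples$group == "T")
    if (length(unique(y[tr])) < 2) {
      message("skipping ", g, " stratum: one class only in training set")
      next
    }
    model <- opls_da(part$matrix$values[tr, , drop = FALSE], y[tr],
                     n_orthogonal = "auto",
                     max_orthogonal = config$max_orthogonal,
                     scaling = config$scaling, cv_folds = config$cv_folds,
                     cv_seed = config$seed)
    y_hat_tr <- model$fitted
    metrics_tr <- classification_metrics(y[tr],
                                         as.numeric(y_hat_tr > config$y_cutoff),
                                         set = "training")
    res <- list(model = model, split = sset,
                metrics_training = metrics_tr,
                roc_training = roc_auc(y_hat_tr, y[tr]))
    if (any(!tr)) {
      y_hat_va <- predict(model, part$matrix$values[!tr, , drop = FALSE])
      res$metrics_validation <- classification_metrics(
        y[!tr], as.numeric(y_hat_va > config$y_cutoff), set = "validation")
      if (length(unique(y[!tr])) == 2)
        res$roc_validation <- roc_auc(y_hat_va, y[!tr])
      pooled_truth <- c(pooled_truth, y[!tr])
      pooled_pred <- c(pooled_pred, as.numeric(y_hat_va > config$y_cutoff))
      pooled_scores <- c(pooled_scores, y_hat_va)
    }
    dt <- diff_table(part$matrix, part$samples$group, vip = vip(model))
    res$diff <- select_relevant(dt, alpha = config$alpha,
                                vip_min = config$vip_min,
                                fc_min_percent = config$fc_min_percent)
    res$splot <- splot(model, part$matrix$values[tr, , drop = FALSE])
    genders[[g]] <- res
  }
  if (!length(genders)) stop("no gender stratum could be modelled")

  result <- list(genders = genders, split = split, config = config)
  if (length(pooled_truth) && length(unique(pooled_truth)) == 2) {
    result$validation_pooled <- classification_metrics(
      pooled_truth, pooled_pred, set = "validation")
    result$roc_validation_pooled <- roc_auc(pooled_scores, pooled_truth)
  }

  # CA 19-9 comparison (both genders, cutoff rule) and combination
  if ("ca199" %in% names(samples) && any(!is.na(samples$ca199))) {
    truth <- as.numeric(samples$group == "T")
    ca_call <- classify_ca199(samples$ca199, config$ca199_cutoff)
    ok <- !is.na(ca_call)
    result$ca199 <- list(
      metrics = classification_metrics(truth[ok],
                                       as.numeric(ca_call[ok] == "PDAC")),
      roc = roc_auc(log(samples$ca199[ok] + 1), truth[ok])
    )
  }

  # survival on cases (univariate Cox per species, median-dichotomized)
  if (all(c("time", "event") %in% names(samples)) &&
      any(!is.na(samples$time))) {
    if (is.null(survival_species)) {
      rel <- unique(unlist(lapply(genders, function(r)
        r$diff$name[r$diff$relevant])))
      survival_species <- utils::head(rel, 8)
    }
    cases <- !is.na(samples$time)
    fits <- list()
    for (sp in survival_species) {
      z <- dichotomize_by_median(imputed$values[, sp])$code
      if (length(unique(z[cases])) < 2) next
      fits[[sp]] <- tryCatch({
        f <- cox_fit(samples$time[cases], samples$event[cases],
                     stats::setNames(data.frame(z[cases]), sp))
        f
      }, error = function(e) NULL)
    }
    fits <- Filter(Negate(is.null), fits)
    if (length(fits)) result$survival <- list(forest = forest_table(fits))
  }

  class(result) <- "pipeline_result"
  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Screening pipeline result\n")
  for (g in names(x$genders)) {
    cat("\n[", g, "]\n", sep = "")
    print(x$genders[[g]]$model)
    print(x$genders[[g]]$metrics_training)
    if (!is.null(x$genders[[g]]$metrics_validation))
      print(x$genders[[g]]$metrics_validation)
  }
  if (!is.null(x$validation_pooled)) {
    cat("\npooled validation: ")
    print(x$validation_pooled)
  }
  invisible(x)
}

.write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  for (g in names(result$genders)) {
    r <- result$genders[[g]]
    w(r$diff, paste0("diff_", g, ".tsv"))
    w(r$splot, paste0("splot_", g, ".tsv"))
    w(r$roc_training$roc, paste0("roc_training_", g, ".tsv"))
    write_opls_model(r$model, file.path(out_dir, paste0("model_", g, ".json")))
  }
  w(result$split, "split.tsv")
  if (!is.null(result$survival)) w(result$survival$forest, "forest.tsv")
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    config = unclass(result$config),
    genders = names(result$genders),
    files = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
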
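# Cohort-level preparation: presence filtering, zero imputation,
# reference-plasma (NIST SRM 1950) normalization across methods, log
# transformation with UV or Pareto scaling, stratified train/validation
# splitting, and gender stratification.

#' Exclude species present in too few samples
#'
#' A species is retained iff its presence fraction (measured, non-missing,
#' positive cells over all samples) is at least `min_presence`; species
#' present in less than that fraction of the samples are excluded.  The
#' boundary is retained (exactly 25% presence passes the default filter).
#'
#' @param m A [conc_matrix()].
#' @param min_presence Minimum presence fraction (default 0.25).
#' @return Filtered [conc_matrix()] with an `"exclusion_report"` attribute
#'   (data frame of species name, presence fraction, retained flag).
#' @export
filter_by_presence <- function(m, min_presence = 0.25) {
  stopifnot(inherits(m, "conc_matrix"), nrow(m$values) > 0,
            ncol(m$values) > 0)
  present <- m$provenance == "measured" & !is.na(m$values) & m$values > 0
  presence <- colMeans(present)
  keep <- presence >= min_presence
  if (!any(keep))
    stop("all species excluded at presence threshold ", min_presence,
         "; review the threshold or the input data")
  report <- data.frame(name = colnames(m$values), presence = presence,
                       retained = keep, row.names = NULL,
                       stringsAsFactors = FALSE)
  out <- conc_matrix(m$values[, keep, drop = FALSE],
                     m$provenance[, keep, drop = FALSE])
  attr(out, "exclusion_report") <- report
  out
}

#' Replace zero and missing values by a fraction of the species minimum
#'
#' Per species, every zero or missing cell is set to `factor` times the
#' minimum positive value of that species across all samples (default 80%
#' of the minimum), and its provenance flag is set to `"imputed"`.
#'
#' @param m A [conc_matrix()] (presence-filtered).
#' @param factor Fraction of the species minimum (default 0.8).
#' @return Imputed [conc_matrix()]; every retained cell is positive.
#' @export
impute_zeros <- function(m, factor = 0.8) {
  stopifnot(inherits(m, "conc_matrix"), factor > 0)
  values <- m$values
  prov <- m$provenance
  for (j in seq_len(ncol(values))) {
    col <- values[, j]
    fill <- is.na(col) | col == 0
    if (!any(fill)) next
    pos <- col[!is.na(col) & col > 0]
    if (!length(pos))
      stop("species ", colnames(values)[j],
           " has no positive value to impute from")
    values[fill, j] <- factor * min(pos)
    prov[fill, j] <- "imputed"
  }
  conc_matrix(values, prov)
}

#' Harmonize concentrations across methods using NIST SRM 1950
#'
#' Normalizes per-method concentration matrices to a common scale using
#' the reference-plasma concentration each method reported for each
#' species: `value * mean(NIST across methods) / NIST(method)`.  Anchoring
#' to the cross-method mean preserves the nmol/mL scale.  Species without
#' NIST coverage in a method, or with non-positive NIST values, are passed
#' through unchanged with a warning.
#'
#' @param matrices Named list of [conc_matrix()] objects, one per method.
#' @param nist Numeric matrix of NIST SRM 1950 concentrations, methods in
#'   rows (names matching `matrices`), species in columns.
#' @return Named list of normalized [conc_matrix()] objects.
#' @export
normalize_to_nist <- function(matrices, nist) {
  stopifnot(is.list(matrices), length(matrices) >= 1, is.matrix(nist))
  methods <- names(matrices)
  if (is.null(methods) || !all(methods %in% rownames(nist)))
    stop("every method in 'matrices' needs a row in 'nist'")
  nist_ok <- nist
  nist_ok[!is.finite(nist_ok) | nist_ok <= 0] <- NA
  anchor <- colMeans(nist_ok[methods, , drop = FALSE], na.rm = TRUE)

  lapply(stats::setNames(methods, methods), function(meth) {
    m <- matrices[[meth]]
    stopifnot(inherits(m, "conc_matrix"))
    values <- m$values
    for (sp in colnames(values)) {
      if (!sp %in% colnames(nist_ok) || is.na(nist_ok[meth, sp]) ||
          is.na(anchor[sp])) {
        warning("no usable NIST value for ", sp, " in method ", meth,
                "; passed through")
        next
      }
      values[, sp] <- values[, sp] * anchor[sp] / nist_ok[meth, sp]
    }
    conc_matrix(values, m$provenance)
  })
}

#' Log-transform, center and scale a concentration matrix
#'
#' Applies the model-ready transformation: natural-log transform, column
#' centering, and unit-variance (`"UV"`, divide by the standard deviation)
#' or Pareto (`"Pareto"`, divide by the square root of the standard
#' deviation) scaling.  The training-set parameters are stored so that
#' validation samples can be transformed identically with
#' [apply_scaling()].
#'
#' @param m A [conc_matrix()] or numeric matrix; all values must be
#'   positive when `log = TRUE`.
#' @param log Apply the natural-log transform first (default `TRUE`).
#' @param scaling `"UV"` or `"Pareto"`.
#' @return List of class `lipid_scaling` with elements `x` (transformed
#'   matrix) and `params` (log flag, scaling, per-species center and
#'   scale).
#' @export
transform_scale <- function(m, log = TRUE, scaling = c("Pareto", "UV")) {
  scaling <- match.arg(scaling)
  x <- if (inherits(m, "conc_matrix")) m$values else as.matrix(m)
  if (log) {
    if (any(!is.finite(x)) || any(x <= 0))
      stop("log transform requires strictly positive, complete values; ",
           "impute first")
    x <- base::log(x)
  }
  center <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  zero_var <- !is.finite(s) | s == 0
  if (any(zero_var)) {
    warning("zero-variance species scaled by 1: ",
            paste(colnames(x)[zero_var], collapse = ", "))
    s[zero_var] <- 1
  }
  scale_vec <- if (scaling == "UV") s else sqrt(s)
  scale_vec[zero_var] <- 1
  params <- list(log = log, scaling = scaling, center = center,
                 scale = scale_vec)
  x <- sweep(sweep(x, 2, center, `-`), 2, scale_vec, `/`)
  structure(list(x = x, params = params), class = "lipid_scaling")
}

#' Apply stored scaling parameters to new samples
#'
#' Transforms validation (or any new) samples with the training-set
#' parameters: no re-centering or re-scaling on the new data.
#'
#' @param params The `params` element of a [transform_scale()] result (or
#'   the result itself).
#' @param m A [conc_matrix()] or numeric matrix with the same species.
#' @return Transformed numeric matrix.
#' @export
apply_scaling <- function(params, m) {
  if (inherits(params, "lipid_scaling")) params <- params$params
  x <- if (inherits(m, "conc_matrix")) m$values else as.matrix(m)
  need <- names(params$center)
  missing_sp <- setdiff(need, colnames(x))
  if (length(missing_sp))
    stop("species missing from new data: ", paste(missing_sp, collapse = ", "))
  x <- x[, need, drop = FALSE]
  if (params$log) {
    if (any(!is.finite(x)) || any(x <= 0))
      stop("log transform requires strictly positive, complete values")
    x <- base::log(x)
  }
  sweep(sweep(x, 2, params$center, `-`), 2, params$scale, `/`)
}

#' Assign samples to training and validation sets by the every-6th rule
#'
#' Within each group-by-gender stratum, samples are put in a seeded random
#' order and every 6th sample (positions 6, 12, 18, ... of the permuted
#' order) is assigned to the validation set; the rest constitute the
#' training set.  Deterministic for a fixed seed.
#'
#' @param samples Sample metadata with columns `sample_id`, `group`,
#'   `gender`.
#' @param seed Integer seed for the within-stratum permutation.
#' @param every Assign every `every`-th sample to validation (default 6).
#' @return Data frame with columns `sample_id`, `set` (`"training"` or
#'   `"validation"`), in the input sample order.
#' @export
split_train_validation <- function(samples, seed = 1L, every = 6L) {
  stopifnot(all(c("sample_id", "group", "gender") %in% names(samples)),
            every >= 2)
  set.seed(seed)
  set <- rep("training", nrow(samples))
  strata <- interaction(samples$group, samples$gender, drop = TRUE)
  for (s in levels(strata)) {
    idx <- which(strata == s)
    perm <- idx[sample.int(length(idx))]
    val_pos <- seq_len(length(perm)) %% every == 0
    set[perm[val_pos]] <- "validation"
  }
  data.frame(sample_id = samples$sample_id, set = set,
             stringsAsFactors = FALSE)
}

#' Split a cohort by gender
#'
#' Partitions the matrix and metadata into male and female parts; the
#' species universe is unchanged in each part.  Unknown or missing gender
#' codes are an error listing the offending samples.
#'
#' @param m A [conc_matrix()].
#' @param samples Matching metadata with columns `sample_id`, `gender`
#'   (codes `"M"` / `"F"`).
#' @return List with elements `male` and `female`, each a list of
#'   `matrix` and `samples`; empty strata are flagged with a message.
#' @export
stratify_by_gender <- function(m, samples) {
  stopifnot(inherits(m, "conc_matrix"),
            all(c("sample_id", "gender") %in% names(samples)),
            identical(rownames(m$values), samples$sample_id))
  bad <- is.na(samples$gender) | !samples$gender %in% c("M", "F")
  if (any(bad))
    stop("unknown gender code for samples: ",
         paste(samples$sample_id[bad], collapse = ", "))
  out <- lapply(c(male = "M", female = "F"), function(g) {
    idx <- samples$gender == g
    list(matrix = conc_matrix(m$values[idx, , drop = FALSE],
                              m$provenance[idx, , drop = FALSE]),
         samples = samples[idx, , drop = FALSE])
  })
  if (!nrow(out$male$samples)) message("note: male stratum is empty")
  if (!nrow(out$female$samples)) message("note: female stratum is empty")
  out
}
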
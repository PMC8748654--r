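# Synthetic cohort generator: lognormal serum lipid concentrations with
# configurable case/control fold changes, clinical metadata, CA 19-9 and
# proportional-hazards survival times.  Emulates the statistical structure
# of a case/control serum-lipidomics screening study so the downstream
# pipeline can be exercised and validated without patient data.

#' Cohort generator configuration
#'
#' Defines the statistical structure of a synthetic screening cohort:
#' group sizes, lipid panel size, which species carry case/control signal
#' and how strong, biological within-group variation, gender and age
#' structure, CA 19-9 distributions, and survival parameters.
#'
#' Concentrations are lognormal per species; a case/control effect acts
#' multiplicatively on the geometric mean, so `fold_change` is the
#' geometric-mean ratio cases/controls (values < 1 mean downregulation in
#' cases).  Default marker panel: the seven species SM 41:1, SM 42:1,
#' SM 39:1, Cer 41:1, Cer 42:1, LPC 18:2 and PC O-36:3, all downregulated
#' in cases with geometric-mean ratios between 0.45 and 0.65.  Pancreatitis
#' samples are drawn from the control distribution.
#'
#' @param n_cases,n_controls,n_pancreatitis Group sizes.
#' @param n_lipids Total number of lipid species (markers + null species).
#' @param informative_lipids Data frame with columns `name` and
#'   `fold_change` (geometric-mean ratio cases/controls, > 0).
#' @param within_group_cv Lognormal coefficient of variation of a species
#'   within a group.
#' @param gender_fraction Fraction of female samples in every group.
#' @param gender_effect Multiplicative offset on female geometric means
#'   (scalar or named per-species vector); default 1 (no gender signal).
#' @param age_ranges Named list of `c(min, max)` ages in years per group
#'   (`T`, `N`, `Pan`).
#' @param ca199_params Named list per group of `c(meanlog, sdlog)` for the
#'   lognormal CA 19-9 distribution (U/mL).
#' @param survival_params List with `baseline_hazard` (events/month for a
#'   case with all binary lipid codes 0), `betas` (named per-species
#'   log-hazard coefficients of the median-dichotomized codes) and
#'   `horizon` (administrative censoring, months).
#' @param n_qc Number of pooled-serum QC replicate samples to append
#'   (group `"QC"`, low technical CV), default 0.
#' @param qc_cv Technical coefficient of variation of QC replicates.
#' @param seed Integer seed; a fixed seed gives bit-identical cohorts.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 546, n_controls = 262, n_pancreatitis = 22,
                          n_lipids = 157,
                          informative_lipids = default_marker_panel(),
                          within_group_cv = 0.30,
                          gender_fraction = 0.5,
                          gender_effect = 1.0,
                          age_ranges = list(T = c(40, 85), N = c(35, 80),
                                            Pan = c(30, 75)),
                          ca199_params = list(T = c(meanlog = log(100), sdlog = 1.5),
                                              N = c(meanlog = log(8), sdlog = 1.0),
                                              Pan = c(meanlog = log(15), sdlog = 1.0)),
                          survival_params = list(baseline_hazard = 0.04,
                                                 betas = c(`LPC 18:2` = -0.7),
                                                 horizon = 60),
                          n_qc = 0, qc_cv = 0.05,
                          seed = 1L) {
  stopifnot(n_cases >= 0, n_controls >= 0, n_pancreatitis >= 0, n_qc >= 0,
            n_lipids >= 0, within_group_cv > 0,
            gender_fraction >= 0, gender_fraction <= 1)
  if (!is.data.frame(informative_lipids) ||
      !all(c("name", "fold_change") %in% names(informative_lipids)))
    stop("informative_lipids must have columns 'name' and 'fold_change'")
  if (any(informative_lipids$fold_change <= 0))
    stop("fold-change ratios must be > 0")
  if (nrow(informative_lipids) > n_lipids)
    stop("more informative lipids than n_lipids")
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_pancreatitis = as.integer(n_pancreatitis),
    n_lipids = as.integer(n_lipids),
    informative_lipids = informative_lipids,
    within_group_cv = within_group_cv,
    gender_fraction = gender_fraction,
    gender_effect = gender_effect,
    age_ranges = age_ranges,
    ca199_params = ca199_params,
    survival_params = survival_params,
    n_qc = as.integer(n_qc), qc_cv = qc_cv,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Default marker panel
#'
#' The seven lipid species used as the informative markers of the default
#' synthetic cohort, all downregulated in cases, with geometric-mean
#' case/control ratios between 0.45 and 0.65.
#'
#' @return Data frame with columns `name`, `fold_change`, `direction`.
#' @export
default_marker_panel <- function() {
  data.frame(
    name = c("SM 41:1", "SM 42:1", "SM 39:1", "Cer 41:1", "Cer 42:1",
             "LPC 18:2", "PC O-36:3"),
    fold_change = c(0.45, 0.50, 0.55, 0.50, 0.55, 0.60, 0.65),
    direction = "down",
    stringsAsFactors = FALSE
  )
}

# species name pool: marker names first, then the built-in database
# species, then programmatic class/carbon/double-bond combinations
.species_pool <- function(n, informative_names) {
  pool <- informative_names
  db <- default_lipid_db()
  pool <- c(pool, setdiff(db$name[!db$is_internal_standard], pool))
  classes <- c("SM", "Cer", "PC", "PC O-", "LPC", "PE", "LPE", "TG", "DG",
               "CE", "HexCer")
  for (d in 0:6) {
    for (cls in classes) {
      for (cb in seq(30, 44, by = 2)) {
        cand <- sprintf("%s %d:%d", cls, cb, d)
        if (length(pool) >= n) return(pool[seq_len(n)])
        if (!cand %in% pool) pool <- c(pool, cand)
      }
    }
  }
  if (length(pool) < n) stop("species name pool exhausted")
  pool[seq_len(n)]
}

#' Generate a synthetic screening cohort
#'
#' Draws a samples-by-species concentration matrix and the matching sample
#' metadata table.  Per species, concentrations are lognormal around a
#' species-specific geometric mean; informative species have their
#' case geometric mean multiplied by the configured fold change;
#' pancreatitis samples are drawn from the control distribution.  Metadata
#' includes gender, age, tumor stage (cases only), collection site,
#' diabetes flag and CA 19-9 (U/mL).
#'
#' @param config A [cohort_config()].
#' @return List with elements `matrix` (a [conc_matrix()]) and `samples`
#'   (data frame with columns `sample_id`, `group`, `gender`, `age`,
#'   `stage`, `site`, `diabetes`, `ca199`, `time`, `event`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_cases + config$n_controls + config$n_pancreatitis
  if (n == 0L) stop("cohort has zero samples")
  if (config$n_lipids == 0L) stop("cohort has zero lipid species")
  set.seed(config$seed)

  species <- .species_pool(config$n_lipids, config$informative_lipids$name)
  # species baseline geometric means (nmol/mL), spanning the dynamic range
  # typical of quantified serum lipids (~0.05 to ~500 nmol/mL)
  base_gm <- exp(stats::runif(length(species), log(0.05), log(500)))
  names(base_gm) <- species
  sdlog <- sqrt(log(1 + config$within_group_cv^2))

  group <- c(rep("T", config$n_cases), rep("N", config$n_controls),
             rep("Pan", config$n_pancreatitis))
  ids <- sprintf("S%04d", seq_len(n))
  gender <- ifelse(stats::runif(n) < config$gender_fraction, "F", "M")

  lfc <- stats::setNames(rep(0, length(species)), species)
  lfc[config$informative_lipids$name] <- log(config$informative_lipids$fold_change)
  gef <- config$gender_effect
  lgender <- stats::setNames(rep(0, length(species)), species)
  if (!is.null(names(gef))) {
    lgender[names(gef)] <- log(gef)
  } else {
    lgender[] <- log(gef)
  }

  mu <- matrix(rep(log(base_gm), each = n), nrow = n,
               dimnames = list(ids, species))
  mu[group == "T", ] <- sweep(mu[group == "T", , drop = FALSE], 2, lfc, `+`)
  mu[gender == "F", ] <- sweep(mu[gender == "F", , drop = FALSE], 2, lgender, `+`)
  values <- exp(mu + matrix(stats::rnorm(n * length(species), sd = sdlog),
                            nrow = n))

  age <- numeric(n)
  for (g in c("T", "N", "Pan")) {
    r <- config$age_ranges[[g]]
    idx <- group == g
    age[idx] <- round(stats::runif(sum(idx), r[1], r[2]))
  }
  stage <- rep(NA_character_, n)
  stage[group == "T"] <- sample(c("T1", "T2", "T3", "T4"), config$n_cases,
                                replace = TRUE, prob = c(0.08, 0.12, 0.45, 0.35))
  site <- sample(paste0("site", 1:4), n, replace = TRUE,
                 prob = c(0.65, 0.18, 0.05, 0.12))
  diabetes <- stats::runif(n) < ifelse(group == "T", 0.3, 0.1)
  ca199 <- numeric(n)
  for (g in c("T", "N", "Pan")) {
    p <- config$ca199_params[[g]]
    idx <- group == g
    ca199[idx] <- stats::rlnorm(sum(idx), p[["meanlog"]], p[["sdlog"]])
  }

  samples <- data.frame(
    sample_id = ids, group = group, gender = gender, age = age,
    stage = stage, site = site, diabetes = diabetes,
    ca199 = round(ca199, 1), time = NA_real_, event = NA_integer_,
    stringsAsFactors = FALSE
  )

  if (config$n_qc > 0L) {
    qc_mu <- colMeans(mu)
    qc_sdlog <- sqrt(log(1 + config$qc_cv^2))
    qc_vals <- exp(matrix(rep(qc_mu, each = config$n_qc), nrow = config$n_qc) +
                   matrix(stats::rnorm(config$n_qc * length(species),
                                       sd = qc_sdlog), nrow = config$n_qc))
    qc_ids <- sprintf("QC%03d", seq_len(config$n_qc))
    rownames(qc_vals) <- qc_ids
    values <- rbind(values, qc_vals)
    samples <- rbind(samples, data.frame(
      sample_id = qc_ids, group = "QC", gender = NA_character_,
      age = NA_real_, stage = NA_character_, site = NA_character_,
      diabetes = NA, ca199 = NA_real_, time = NA_real_, event = NA_integer_,
      stringsAsFactors = FALSE
    ))
  }

  list(matrix = conc_matrix(values), samples = samples)
}

#' Attach survival outcomes to the cases of a synthetic cohort
#'
#' Draws, for every case, a survival time from an exponential
#' proportional-hazards model: hazard `h0 * exp(sum(beta_j * z_j))` where
#' `z_j` is the median-dichotomized binary code (1 if concentration above
#' the cohort-wide median) of lipid `j`, with administrative censoring at
#' the configured horizon.  Controls and pancreatitis samples keep missing
#' survival fields.
#'
#' @param samples Sample metadata table from [generate_cohort()].
#' @param matrix The matching [conc_matrix()].
#' @param config The [cohort_config()] (uses `survival_params` and `seed`).
#' @return The sample table with `time` (months) and `event`
#'   (1 = death observed, 0 = censored) filled in for cases.
#' @export
generate_survival <- function(samples, matrix, config) {
  stopifnot(inherits(config, "cohort_config"), inherits(matrix, "conc_matrix"))
  sp <- config$survival_params
  if (sp$baseline_hazard < 0) stop("negative baseline hazard")
  if (sp$horizon <= 0) stop("censoring horizon must be > 0")
  cases <- which(samples$group == "T")
  if (!length(cases)) stop("no case samples present")
  set.seed(config$seed + 1L)

  lp <- rep(0, length(cases))
  betas <- sp$betas
  if (length(betas)) {
    missing_sp <- setdiff(names(betas), colnames(matrix$values))
    if (length(missing_sp))
      stop("survival betas refer to unknown species: ",
           paste(missing_sp, collapse = ", "))
    for (nm in names(betas)) {
      z <- dichotomize_by_median(matrix$values[, nm])$code
      lp <- lp + betas[[nm]] * z[cases]
    }
  }
  hazard <- sp$baseline_hazard * exp(lp)
  t_event <- stats::rexp(length(cases), rate = pmax(hazard, .Machine$double.eps))
  samples$time[cases] <- pmin(t_event, sp$horizon)
  samples$event[cases] <- as.integer(t_event <= sp$horizon)
  samples
}
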
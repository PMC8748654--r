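# Quantitation of centroided peak lists: intensity thresholding,
# accurate-mass database matching within a mDa tolerance, type I/II
# isotope correction, and molar quantitation against the class internal
# standard.

#' Extract peaks above an intensity threshold
#'
#' Keeps only centroids with intensity strictly greater than
#' `min_intensity` (default 3000 counts), preserving order.
#'
#' @param pl A [peak_list()].
#' @param min_intensity Threshold in counts (>= 0).
#' @return A filtered [peak_list()].
#' @export
threshold_peaks <- function(pl, min_intensity = 3000) {
  stopifnot(inherits(pl, "peak_list"), min_intensity >= 0)
  keep <- pl$peaks$intensity > min_intensity
  peak_list(pl$sample_id, pl$class_window,
            pl$peaks$mz[keep], pl$peaks$intensity[keep])
}

#' Match peaks against the lipid database
#'
#' Assigns peaks to database species of the peak list's class window when
#' the measured m/z lies within `tolerance` mDa of the theoretical m/z
#' (inclusive boundary).  Each peak is assigned to at most one species
#' (nearest m/z; exact ties go to the lower theoretical m/z) and each
#' species takes the most intense qualifying peak.  Database entries of
#' the window closer together than twice the tolerance trigger a warning.
#'
#' @param pl A [peak_list()].
#' @param db A [lipid_db()].
#' @param tolerance Mass tolerance in mDa (default 5).
#' @return Data frame of assignments with columns `name`, `lipid_class`,
#'   `mz`, `intensity`, `delta_mz` (mDa) and `corrected_intensity`
#'   (initialised to the raw intensity).
#' @export
match_peaks <- function(pl, db, tolerance = 5) {
  stopifnot(inherits(pl, "peak_list"), inherits(db, "lipid_db"),
            tolerance > 0)
  win <- db[db$lipid_class == pl$class_window, , drop = FALSE]
  if (!nrow(win)) stop("database has no species for class window ",
                       pl$class_window)
  tol_th <- tolerance / 1000
  mzs <- sort(win$exact_mz)
  if (any(diff(mzs) < 2 * tol_th))
    warning("database entries in window ", pl$class_window,
            " closer than twice the tolerance; nearest-wins applied")

  empty <- data.frame(name = character(0), lipid_class = character(0),
                      mz = numeric(0), intensity = numeric(0),
                      delta_mz = numeric(0), corrected_intensity = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(pl$peaks)) return(empty)

  # nearest qualifying species per peak
  hits <- lapply(seq_len(nrow(pl$peaks)), function(i) {
    d <- abs(pl$peaks$mz[i] - win$exact_mz)
    ok <- which(d <= tol_th)
    if (!length(ok)) return(NULL)
    best <- ok[order(d[ok], win$exact_mz[ok])][1]
    data.frame(name = win$name[best], lipid_class = win$lipid_class[best],
               mz = pl$peaks$mz[i], intensity = pl$peaks$intensity[i],
               delta_mz = (pl$peaks$mz[i] - win$exact_mz[best]) * 1000,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) return(empty)
  # most intense qualifying peak per species
  hits <- hits[order(hits$name, -hits$intensity, hits$mz), ]
  hits <- hits[!duplicated(hits$name), ]
  hits <- hits[order(hits$mz), ]
  hits$corrected_intensity <- hits$intensity
  rownames(hits) <- NULL
  hits
}

#' Isotope-correct assigned intensities
#'
#' Two-stage correction computed from molecular formulas.  Type II: within
#' a lipid class, the M+2 isotopologue of the species with one more double
#' bond (same carbon number) overlaps the monoisotopic peak of its
#' neighbour; its estimated contribution is subtracted first.  Type I: each
#' intensity is then divided by the monoisotopic fraction of the species'
#' isotope envelope, converting the M+0 intensity into the full-envelope
#' intensity.  Corrected intensities are floored at zero.
#'
#' @param assignments Assignment data frame from [match_peaks()].
#' @param db A [lipid_db()] providing formulas.
#' @param type2,type1 Logical switches for the two stages.
#' @return The assignment data frame with `corrected_intensity` updated.
#' @export
isotope_correct <- function(assignments, db, type2 = TRUE, type1 = TRUE) {
  stopifnot(inherits(db, "lipid_db"))
  if (!nrow(assignments)) return(assignments)
  idx <- match(assignments$name, db$name)
  if (anyNA(idx))
    stop("no database formula for species: ",
         paste(assignments$name[is.na(idx)], collapse = ", "))
  info <- db[idx, ]
  corrected <- assignments$intensity

  if (type2) {
    envs <- lapply(info$formula, isotope_envelope)
    for (i in seq_along(corrected)) {
      j <- which(info$lipid_class == info$lipid_class[i] &
                 info$carbons == info$carbons[i] &
                 info$double_bonds == info$double_bonds[i] + 1L)
      if (length(j) == 1L) {
        env_j <- envs[[j]]
        overlap <- assignments$intensity[j] * env_j[["M2"]] / env_j[["M0"]]
        corrected[i] <- max(corrected[i] - overlap, 0)
      }
    }
  }
  if (type1) {
    p0 <- vapply(info$formula, monoisotopic_fraction, numeric(1))
    corrected <- corrected / p0
  }
  assignments$corrected_intensity <- pmax(corrected, 0)
  assignments
}

#' Quantify assigned species against the class internal standard
#'
#' Converts corrected intensities into molar concentrations:
#' `concentration = intensity(lipid) / intensity(class IS) * spiked IS
#' concentration` (nmol/mL).  If the internal standard of a class is
#' absent or has zero corrected intensity, all species of that class are
#' reported as missing (not zero) with a warning.
#'
#' @param assignments Assignment data frame (after [isotope_correct()]).
#' @param is_table Data frame with columns `lipid_class`, `is_name`,
#'   `concentration` (see [default_is_table()]).
#' @return Data frame with columns `name`, `lipid_class`,
#'   `concentration` for all quantified (non-IS) species.
#' @export
quantify_peaks <- function(assignments, is_table = default_is_table()) {
  out <- list()
  for (cls in unique(assignments$lipid_class)) {
    rows <- assignments[assignments$lipid_class == cls, , drop = FALSE]
    is_row <- is_table[is_table$lipid_class == cls, , drop = FALSE]
    if (!nrow(is_row)) {
      warning("no internal standard configured for class ", cls,
              "; species reported missing")
      next
    }
    is_row <- is_row[1, ]
    is_int <- rows$corrected_intensity[rows$name == is_row$is_name]
    if (!length(is_int) || is_int[1] <= 0) {
      warning("internal standard ", is_row$is_name, " absent or zero in class ",
              cls, "; species reported missing")
      next
    }
    lip <- rows[rows$name != is_row$is_name, , drop = FALSE]
    if (!nrow(lip)) next
    out[[cls]] <- data.frame(
      name = lip$name, lipid_class = lip$lipid_class,
      concentration = lip$corrected_intensity / is_int[1] * is_row$concentration,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out))
    return(data.frame(name = character(0), lipid_class = character(0),
                      concentration = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Quantify one sample from its per-class peak lists
#'
#' Full quantitation chain for a single sample: intensity thresholding,
#' database matching, isotope correction, and internal-standard ratioing,
#' per class window.
#'
#' @param windows Named list (class window) of [peak_list()] objects for
#'   one sample.
#' @param db A [lipid_db()].
#' @param is_table Internal-standard table.
#' @param min_intensity Extraction threshold in counts.
#' @param tolerance Matching tolerance in mDa.
#' @param isotope_correction Apply [isotope_correct()] (default `TRUE`).
#' @return Data frame with columns `name`, `lipid_class`, `concentration`.
#' @export
lipidquant_sample <- function(windows, db, is_table = default_is_table(),
                              min_intensity = 3000, tolerance = 5,
                              isotope_correction = TRUE) {
  parts <- lapply(windows, function(pl) {
    a <- match_peaks(threshold_peaks(pl, min_intensity), db, tolerance)
    if (isotope_correction) a <- isotope_correct(a, db)
    a
  })
  assignments <- do.call(rbind, parts)
  rownames(assignments) <- NULL
  quantify_peaks(assignments, is_table)
}

#' Quantify a whole cohort of peak lists
#'
#' @param peaklists Nested list as produced by [generate_peaklists()]:
#'   sample id -> class window -> [peak_list()].
#' @inheritParams lipidquant_sample
#' @return A [conc_matrix()] over the union of quantified species.
#' @export
lipidquant_cohort <- function(peaklists, db, is_table = default_is_table(),
                              min_intensity = 3000, tolerance = 5,
                              isotope_correction = TRUE) {
  per_sample <- lapply(peaklists, lipidquant_sample, db = db,
                       is_table = is_table, min_intensity = min_intensity,
                       tolerance = tolerance,
                       isotope_correction = isotope_correction)
  build_matrix(per_sample)
}
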
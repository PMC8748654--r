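# Synthetic centroided spectra: per-sample, per-lipid-class peak lists
# with internal-standard peaks, optional isotope envelopes computed from
# molecular formulas, m/z jitter and additive noise.  Provides the input
# surface for validating the quantitation stage by round trip.

#' Centroided peak list for one sample and one lipid-class window
#'
#' @param sample_id Sample identifier.
#' @param class_window Lipid-class label of the combined scan window.
#' @param mz,intensity Numeric vectors of equal length (Th, counts).
#' @return Object of class `peak_list` with peaks sorted by m/z.
#' @export
peak_list <- function(sample_id, class_window, mz, intensity) {
  stopifnot(length(mz) == length(intensity))
  if (any(mz <= 0)) stop("m/z must be strictly positive")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  o <- order(mz)
  structure(list(sample_id = sample_id, class_window = class_window,
                 peaks = data.frame(mz = mz[o], intensity = intensity[o])),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat("Peak list:", x$sample_id, "/", x$class_window, "-",
      nrow(x$peaks), "peaks\n")
  invisible(x)
}

#' Spectrum generator configuration
#'
#' @param is_concentrations Data frame mapping `lipid_class` to `is_name`
#'   and spiked `concentration` (nmol/mL); default [default_is_table()].
#' @param noise_floor Noise level in counts; random noise peaks are drawn
#'   with intensities below `3 * noise_floor` (0 disables noise).
#' @param n_noise_peaks Mean number of noise peaks per class window.
#' @param response_factor Instrument response in counts per nmol/mL,
#'   scalar or named per lipid class.
#' @param mz_jitter_sd Mass-measurement jitter standard deviation in mDa;
#'   jitter is truncated at 3 standard deviations.
#' @param include_isotopes If `TRUE`, M+0, M+1 and M+2 isotopologue peaks
#'   are generated with abundances computed from the molecular formula;
#'   otherwise the full species intensity is placed in one peak.
#' @param merge_width Centroids closer than this (Th) are merged into one
#'   peak (intensity-weighted m/z, summed intensity), emulating unresolved
#'   isotopologue overlap between species differing by one double bond.
#' @param seed Integer seed.
#' @return Object of class `spectrum_config`.
#' @export
spectrum_config <- function(is_concentrations = default_is_table(),
                            noise_floor = 0, n_noise_peaks = 20,
                            response_factor = 5e4,
                            mz_jitter_sd = 0.5,
                            include_isotopes = FALSE,
                            merge_width = 0.010,
                            seed = 1L) {
  stopifnot(all(response_factor > 0), mz_jitter_sd >= 0, noise_floor >= 0,
            merge_width >= 0)
  structure(list(is_concentrations = is_concentrations,
                 noise_floor = noise_floor, n_noise_peaks = n_noise_peaks,
                 response_factor = response_factor,
                 mz_jitter_sd = mz_jitter_sd,
                 include_isotopes = include_isotopes,
                 merge_width = merge_width, seed = as.integer(seed)),
            class = "spectrum_config")
}

.C13_SPACING <- 1.0033548378

.class_response <- function(response_factor, cls) {
  if (!is.null(names(response_factor))) {
    if (!cls %in% names(response_factor))
      stop("no response factor for class ", cls)
    response_factor[[cls]]
  } else response_factor
}

# truncated-normal jitter in Th from an sd given in mDa
.mz_jitter <- function(n, sd_mda) {
  if (sd_mda == 0) return(rep(0, n))
  j <- stats::rnorm(n, 0, sd_mda)
  j <- pmin(pmax(j, -3 * sd_mda), 3 * sd_mda)
  j / 1000
}

#' Generate synthetic peak lists from a concentration matrix
#'
#' For every sample and every lipid class, emits a centroided peak list
#' with one peak per species at the database m/z (plus jitter) and
#' intensity `concentration * response_factor`, internal-standard peaks at
#' the configured spike concentration, optional M+1/M+2 isotopologues from
#' the molecular formula, and additive noise peaks below
#' `3 * noise_floor`.  Centroids closer than `merge_width` are merged, so
#' the M+2 isotopologue of a species with one more double bond overlaps
#' the monoisotopic peak of its neighbour, as in real class windows.
#'
#' @param matrix A [conc_matrix()]; every column must exist in `db` with a
#'   formula.
#' @param db A [lipid_db()] containing all matrix species and one internal
#'   standard per class.
#' @param scfg A [spectrum_config()].
#' @return Named list (sample id) of named lists (class window) of
#'   [peak_list()] objects.
#' @export
generate_peaklists <- function(matrix, db, scfg = spectrum_config()) {
  stopifnot(inherits(matrix, "conc_matrix"), inherits(db, "lipid_db"),
            inherits(scfg, "spectrum_config"))
  species <- colnames(matrix$values)
  missing_sp <- setdiff(species, db$name)
  if (length(missing_sp))
    stop("matrix species absent from database: ",
         paste(missing_sp, collapse = ", "))
  sp_info <- db[match(species, db$name), ]
  classes <- sort(unique(sp_info$lipid_class))
  ist <- scfg$is_concentrations
  for (cls in classes) {
    row <- ist[ist$lipid_class == cls, ]
    if (!nrow(row) || !row$is_name[1] %in% db$name)
      stop("no internal standard defined for class ", cls)
  }
  set.seed(scfg$seed)

  envs <- lapply(stats::setNames(db$formula, db$name), isotope_envelope)

  out <- list()
  for (sid in rownames(matrix$values)) {
    out[[sid]] <- list()
    for (cls in classes) {
      rf <- .class_response(scfg$response_factor, cls)
      cls_species <- species[sp_info$lipid_class == cls]
      is_row <- ist[ist$lipid_class == cls, ][1, ]
      mz <- numeric(0); intensity <- numeric(0)

      emit <- function(name, conc) {
        if (is.na(conc) || conc <= 0) return(invisible(NULL))
        exact <- db$exact_mz[db$name == name]
        total <- conc * rf
        if (scfg$include_isotopes) {
          env <- envs[[name]]
          k <- 0:2
          mz <<- c(mz, exact + k * .C13_SPACING + .mz_jitter(3, scfg$mz_jitter_sd))
          intensity <<- c(intensity, total * env)
        } else {
          mz <<- c(mz, exact + .mz_jitter(1, scfg$mz_jitter_sd))
          intensity <<- c(intensity, total)
        }
        invisible(NULL)
      }

      for (nm in cls_species) emit(nm, matrix$values[sid, nm])
      emit(is_row$is_name, is_row$concentration)

      if (scfg$noise_floor > 0 && length(mz)) {
        n_noise <- stats::rpois(1, scfg$n_noise_peaks)
        if (n_noise > 0) {
          lo <- min(mz) - 2; hi <- max(mz) + 2
          mz <- c(mz, stats::runif(n_noise, lo, hi))
          intensity <- c(intensity, stats::runif(n_noise, 0, 3 * scfg$noise_floor))
        }
      }

      # merge unresolved centroids (intensity-weighted m/z)
      if (length(mz) && scfg$merge_width > 0) {
        o <- order(mz)
        mz <- mz[o]; intensity <- intensity[o]
        grp <- cumsum(c(1, diff(mz) > scfg$merge_width))
        mz <- as.numeric(tapply(mz * intensity, grp, sum) /
                         tapply(intensity, grp, sum))
        intensity <- as.numeric(tapply(intensity, grp, sum))
        keep <- is.finite(mz)
        mz <- mz[keep]; intensity <- intensity[keep]
      }

      out[[sid]][[cls]] <- peak_list(sid, cls, mz, intensity)
    }
  }
  out
}

#' Read / write a peak list as tab-separated text
#'
#' Two columns, `mz` and `intensity`, one row per centroid.
#'
#' @param pl A [peak_list()].
#' @param path File path.
#' @param sample_id,class_window Identity attached on read.
#' @return `read_peak_list` returns a [peak_list()].
#' @export
write_peak_list <- function(pl, path) {
  stopifnot(inherits(pl, "peak_list"))
  utils::write.table(pl$peaks, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_peak_list
#' @export
read_peak_list <- function(path, sample_id, class_window) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mz", "intensity") %in% names(d)))
    stop("peak-list TSV must have columns mz and intensity")
  peak_list(sample_id, class_window, d$mz, d$intensity)
}
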
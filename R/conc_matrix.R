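# Concentration matrix container: samples x lipid species molar
# concentrations (nmol/mL) with per-cell provenance.

#' Construct a concentration matrix
#'
#' Samples-by-species molar concentrations (nmol/mL) with a parallel
#' provenance matrix recording, for every cell, whether the value was
#' measured, imputed, or absent (species not observed in that sample;
#' stored as `NA` in the values).
#'
#' @param values Numeric matrix (samples in rows, species in columns) with
#'   row and column names; `NA` marks absent cells.
#' @param provenance Optional character matrix of the same shape with
#'   entries in `c("measured", "imputed", "absent")`; defaults to
#'   `"measured"` where `values` is finite and `"absent"` where `NA`.
#' @return Object of class `conc_matrix`.
#' @export
conc_matrix <- function(values, provenance = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry sample (row) and species (column) names")
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicate species names")
  if (any(values < 0, na.rm = TRUE)) stop("negative concentrations")
  if (is.null(provenance)) {
    provenance <- matrix(ifelse(is.na(values), "absent", "measured"),
                         nrow = nrow(values), dimnames = dimnames(values))
  }
  stopifnot(identical(dim(provenance), dim(values)))
  if (!all(provenance %in% c("measured", "imputed", "absent")))
    stop("invalid provenance flags")
  structure(list(values = values, provenance = provenance),
            class = "conc_matrix")
}

#' @export
dim.conc_matrix <- function(x) dim(x$values)

#' @export
as.matrix.conc_matrix <- function(x, ...) x$values

#' @export
print.conc_matrix <- function(x, ...) {
  cat("Concentration matrix [nmol/mL]:", nrow(x$values), "samples x",
      ncol(x$values), "species\n")
  tab <- table(factor(x$provenance,
                      levels = c("measured", "imputed", "absent")))
  cat("cells:", paste(names(tab), as.integer(tab), collapse = ", "), "\n")
  invisible(x)
}

#' Assemble a concentration matrix from per-sample quantitation results
#'
#' Takes the per-sample species/concentration tables produced by
#' [quantify_peaks()] and builds the cohort matrix over the union of all
#' observed species (canonically sorted); species not observed in a sample
#' are stored as absent.
#'
#' @param per_sample Named list (names are sample ids) of data frames with
#'   columns `name` and `concentration`.
#' @return A [conc_matrix()].
#' @export
build_matrix <- function(per_sample) {
  stopifnot(is.list(per_sample), length(per_sample) > 0)
  ids <- names(per_sample)
  if (is.null(ids) || any(!nzchar(ids))) stop("per-sample results must be named")
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  species <- sort(unique(unlist(lapply(per_sample, function(d) d$name))))
  if (!length(species)) stop("no species quantified in any sample")
  values <- matrix(NA_real_, nrow = length(ids), ncol = length(species),
                   dimnames = list(ids, species))
  for (id in ids) {
    d <- per_sample[[id]]
    if (!nrow(d)) next
    if (anyDuplicated(d$name)) stop("duplicate species in sample ", id)
    values[id, d$name] <- d$concentration
  }
  conc_matrix(values)
}

#' Read / write a concentration matrix as CSV
#'
#' The values and the provenance flags are written as two parallel CSV
#' files (`<path>` and `<path>` with suffix `"_provenance"`), samples in
#' rows, species in columns.
#'
#' @param m A `conc_matrix`.
#' @param path Path of the values CSV.
#' @return `read_conc_matrix` returns a `conc_matrix`.
#' @export
write_conc_matrix <- function(m, path) {
  stopifnot(inherits(m, "conc_matrix"))
  utils::write.csv(m$values, path, row.names = TRUE, na = "")
  prov_path <- sub("(\\.[A-Za-z]+)?$", "_provenance\\1", path)
  utils::write.csv(m$provenance, prov_path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_conc_matrix
#' @export
read_conc_matrix <- function(path) {
  vals <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  prov_path <- sub("(\\.[A-Za-z]+)?$", "_provenance\\1", path)
  prov <- NULL
  if (file.exists(prov_path)) {
    prov <- as.matrix(utils::read.csv(prov_path, row.names = 1,
                                      check.names = FALSE))
  }
  conc_matrix(vals, prov)
}
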
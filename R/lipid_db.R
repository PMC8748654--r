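# Lipid species database: LSI shorthand parsing, class-based formula
# construction, and a built-in synthetic database used by the simulator
# and the quantitation round-trip tests.

# per-class composition rules for species with total acyl carbons n and
# total double bonds d (species-level shorthand, [M+H]+ positive mode):
# carbon offset, heteroatoms, and double-bond-equivalent offset
.CLASS_RULES <- list(
  "PC"    = list(dC = 8L,  N = 1L, O = 8L, P = 1L, S = 0L, dbe0 = 2L),
  "PC O-" = list(dC = 8L,  N = 1L, O = 7L, P = 1L, S = 0L, dbe0 = 1L),
  "LPC"   = list(dC = 8L,  N = 1L, O = 7L, P = 1L, S = 0L, dbe0 = 1L),
  "PE"    = list(dC = 5L,  N = 1L, O = 8L, P = 1L, S = 0L, dbe0 = 2L),
  "LPE"   = list(dC = 5L,  N = 1L, O = 7L, P = 1L, S = 0L, dbe0 = 1L),
  "SM"    = list(dC = 5L,  N = 2L, O = 6L, P = 1L, S = 0L, dbe0 = 1L),
  "Cer"   = list(dC = 0L,  N = 1L, O = 3L, P = 0L, S = 0L, dbe0 = 1L),
  "HexCer" = list(dC = 6L, N = 1L, O = 8L, P = 0L, S = 0L, dbe0 = 1L),
  "DG"    = list(dC = 3L,  N = 0L, O = 5L, P = 0L, S = 0L, dbe0 = 2L),
  "TG"    = list(dC = 3L,  N = 0L, O = 6L, P = 0L, S = 0L, dbe0 = 3L),
  "CE"    = list(dC = 27L, N = 0L, O = 2L, P = 0L, S = 0L, dbe0 = 6L)
)

#' Parse an LSI lipid shorthand name
#'
#' Splits a species-level shorthand such as `"SM 41:1"` or `"PC O-36:3"`
#' into lipid class, total fatty-acyl carbons and total double bonds.
#'
#' @param name Character vector of shorthand names.
#' @return Data frame with columns `name`, `lipid_class`, `carbons`,
#'   `double_bonds`.
#' @examples
#' parse_lipid_name(c("SM 41:1", "PC O-36:3"))
#' @export
parse_lipid_name <- function(name) {
  stopifnot(is.character(name))
  m <- regmatches(name, regexec("^([A-Za-z]+(?: [OP]-)?)[ ]?([0-9]+):([0-9]+)$",
                                name))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    stop("unparseable lipid name(s): ", paste(name[bad], collapse = ", "))
  data.frame(
    name = name,
    lipid_class = trimws(vapply(m, `[`, character(1), 2L)),
    carbons = as.integer(vapply(m, `[`, character(1), 3L)),
    double_bonds = as.integer(vapply(m, `[`, character(1), 4L)),
    stringsAsFactors = FALSE
  )
}

#' Molecular formula of a lipid species from its shorthand name
#'
#' Builds the neutral elemental formula for a species-level shorthand using
#' fixed per-class composition rules (glycerophospholipids, sphingolipids,
#' glycerolipids, cholesteryl esters).
#'
#' @param name Character vector of shorthand names (e.g. `"SM 41:1"`).
#' @return Character vector of formulas.
#' @examples
#' lipid_formula("SM 34:1")  # "C39H79N2O6P"
#' @export
lipid_formula <- function(name) {
  info <- parse_lipid_name(name)
  vapply(seq_len(nrow(info)), function(i) {
    cls <- info$lipid_class[i]
    rule <- .CLASS_RULES[[cls]]
    if (is.null(rule))
      stop("no composition rule for lipid class '", cls, "'")
    C <- info$carbons[i] + rule$dC
    dbe <- info$double_bonds[i] + rule$dbe0
    H <- 2L * C + 2L + rule$N + rule$P - 2L * dbe
    if (H <= 0L) stop("impossible composition for ", info$name[i])
    paste0(
      "C", C, "H", H,
      if (rule$N > 0L) paste0("N", if (rule$N > 1L) rule$N else "") else "",
      if (rule$O > 0L) paste0("O", if (rule$O > 1L) rule$O else "") else "",
      if (rule$P > 0L) "P" else "",
      if (rule$S > 0L) "S" else ""
    )
  }, character(1))
}

#' Construct a lipid database
#'
#' A lipid database is a data frame with one row per quantifiable species or
#' class internal standard, carrying the identity, class, neutral formula,
#' adduct and theoretical m/z used for peak matching and isotope correction.
#'
#' @param name Character vector of shorthand names.
#' @param is_internal_standard Logical vector flagging class internal
#'   standards (exogenous species spiked at known concentration).
#' @param adduct Ion type (recycled); default `"[M+H]+"`.
#' @return Object of class `lipid_db` (a data frame with columns `name`,
#'   `lipid_class`, `carbons`, `double_bonds`, `formula`, `adduct`,
#'   `exact_mz`, `is_internal_standard`).
#' @export
lipid_db <- function(name, is_internal_standard = FALSE, adduct = "[M+H]+") {
  info <- parse_lipid_name(name)
  info$formula <- lipid_formula(name)
  info$adduct <- rep_len(adduct, nrow(info))
  info$exact_mz <- vapply(seq_len(nrow(info)),
                          function(i) adduct_mz(info$formula[i], info$adduct[i]),
                          numeric(1))
  info$is_internal_standard <- rep_len(is_internal_standard, nrow(info))
  if (anyDuplicated(info$name)) stop("duplicate species names in database")
  class(info) <- c("lipid_db", "data.frame")
  info
}

#' Built-in synthetic lipid database
#'
#' A small database of common serum lipid species (including the seven
#' marker species SM 39:1, SM 41:1, SM 42:1, Cer 41:1, Cer 42:1, LPC 18:2
#' and PC O-36:3) plus one exogenous internal standard per class.  The
#' species set and internal standards are synthetic stand-ins constructed
#' for simulation and testing; m/z values are computed from class
#' composition rules.
#'
#' @return A [lipid_db()] object.
#' @export
default_lipid_db <- function() {
  endo <- c(
    "SM 34:1", "SM 36:1", "SM 39:1", "SM 40:1", "SM 41:1", "SM 42:1",
    "SM 42:2", "SM 41:2",
    "Cer 34:1", "Cer 36:1", "Cer 38:1", "Cer 40:1", "Cer 41:1", "Cer 42:1",
    "Cer 42:2", "Cer 41:2",
    "LPC 16:0", "LPC 18:0", "LPC 18:1", "LPC 18:2",
    "PC 32:0", "PC 34:1", "PC 34:2", "PC 36:2", "PC 36:4",
    "PC O-34:1", "PC O-36:3", "PC O-38:5",
    "PE 36:2", "TG 52:2", "DG 36:2", "CE 18:2"
  )
  is <- c("SM 30:1", "Cer 30:1", "LPC 17:0", "PC 28:0", "PC O-28:0",
          "PE 28:0", "TG 45:0", "DG 24:0", "CE 17:0")
  lipid_db(c(endo, is),
           is_internal_standard = c(rep(FALSE, length(endo)),
                                    rep(TRUE, length(is))))
}

#' Default internal-standard spike table
#'
#' Spiked concentration (nmol/mL) of the class internal standard for each
#' lipid class in [default_lipid_db()].  Values are synthetic defaults of
#' realistic magnitude for a serum internal-standard mixture.
#'
#' @return Data frame with columns `lipid_class`, `is_name`,
#'   `concentration`.
#' @export
default_is_table <- function() {
  data.frame(
    lipid_class = c("SM", "Cer", "LPC", "PC", "PC O-", "PE", "TG", "DG", "CE"),
    is_name = c("SM 30:1", "Cer 30:1", "LPC 17:0", "PC 28:0", "PC O-28:0",
                "PE 28:0", "TG 45:0", "DG 24:0", "CE 17:0"),
    concentration = c(5, 1, 5, 20, 2, 5, 10, 2, 30),
    stringsAsFactors = FALSE
  )
}

#' Read / write a lipid database as CSV
#'
#' @param path File path.
#' @return `read_lipid_db` returns a [lipid_db()] object.
#' @export
read_lipid_db <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "is_internal_standard")
  if (!all(need %in% names(df)))
    stop("lipid database CSV must have columns: ", paste(need, collapse = ", "))
  lipid_db(df$name, is_internal_standard = as.logical(df$is_internal_standard))
}

#' @rdname read_lipid_db
#' @param db A `lipid_db` object.
#' @export
write_lipid_db <- function(db, path) {
  utils::write.csv(as.data.frame(db), path, row.names = FALSE)
  invisible(path)
}
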
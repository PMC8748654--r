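# Elemental-formula arithmetic: parsing, monoisotopic mass, and low-order
# isotope envelopes for the elements found in lipids (C, H, N, O, P, S).

# monoisotopic masses (u) and natural isotope abundances; +1/+2 refer to the
# nominal mass shift relative to the lightest isotope
.ELEMENTS <- list(
  C = list(mass = 12.0,            p0 = 0.9893,   p1 = 0.0107,    p2 = 0),
  H = list(mass = 1.00782503207,   p0 = 0.999885, p1 = 0.000115,  p2 = 0),
  N = list(mass = 14.0030740048,   p0 = 0.99636,  p1 = 0.00364,   p2 = 0),
  O = list(mass = 15.9949146196,   p0 = 0.99757,  p1 = 0.00038,   p2 = 0.00205),
  P = list(mass = 30.97376163,     p0 = 1,        p1 = 0,         p2 = 0),
  S = list(mass = 31.97207100,     p0 = 0.9499,   p1 = 0.0075,    p2 = 0.0425)
)

.PROTON_MASS <- 1.007276466879

#' Parse an elemental formula
#'
#' Parses a Hill-notation molecular formula restricted to the elements
#' C, H, N, O, P and S (the elements occurring in serum lipids).
#'
#' @param formula Character scalar, e.g. `"C39H79N2O6P"`.
#' @return Named integer vector of element counts (C, H, N, O, P, S).
#' @examples
#' parse_formula("C39H79N2O6P")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  counts <- c(C = 0L, H = 0L, N = 0L, O = 0L, P = 0L, S = 0L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens) || paste(tokens, collapse = "") != formula)
    stop("cannot parse formula: ", formula)
  for (tok in tokens) {
    el <- gsub("[0-9]", "", tok)
    n <- gsub("[A-Za-z]", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(counts))
      stop("unsupported element '", el, "' in formula ", formula)
    counts[el] <- counts[el] + n
  }
  counts
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula Character formula (see [parse_formula()]).
#' @return Monoisotopic (lightest-isotope) mass in u.
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(vapply(names(counts), function(el) counts[[el]] * .ELEMENTS[[el]]$mass,
             numeric(1)))
}

#' Theoretical m/z of a protonated molecule
#'
#' @param formula Neutral molecular formula.
#' @param adduct Ion type; only `"[M+H]+"` is supported.
#' @return m/z in Th.
#' @export
adduct_mz <- function(formula, adduct = "[M+H]+") {
  if (!identical(adduct, "[M+H]+"))
    stop("unsupported adduct: ", adduct)
  monoisotopic_mass(formula) + .PROTON_MASS
}

#' Low-order isotope envelope of a molecular formula
#'
#' Computes the relative abundances of the M+0, M+1 and M+2 isotopologues by
#' convolving the per-element isotope distributions (each element contributes
#' a 0/+1/+2 nominal mass-shift polynomial raised to its atom count).
#' Abundances are normalised so that the full (untruncated) envelope sums
#' to 1; the reported three terms therefore sum to slightly less than 1 for
#' large molecules.
#'
#' @param formula Character formula.
#' @return Numeric vector `c(M0, M1, M2)` of isotopologue probabilities.
#' @examples
#' isotope_envelope("C39H79N2O6P")
#' @export
isotope_envelope <- function(formula) {
  counts <- parse_formula(formula)
  # probability generating polynomial over mass shift, truncated at +2
  env <- c(1, 0, 0)
  for (el in names(counts)) {
    n <- counts[[el]]
    if (n == 0L) next
    e <- .ELEMENTS[[el]]
    single <- c(e$p0, e$p1, e$p2)
    for (i in seq_len(n)) {
      env <- c(
        env[1] * single[1],
        env[1] * single[2] + env[2] * single[1],
        env[1] * single[3] + env[2] * single[2] + env[3] * single[1]
      )
    }
  }
  names(env) <- c("M0", "M1", "M2")
  env
}

#' Monoisotopic fraction of an isotope envelope
#'
#' The fraction of all isotopologues found in the monoisotopic (M+0) peak,
#' used for type-I isotope correction (dividing an M+0 intensity by this
#' fraction recovers the total species intensity).
#'
#' @param formula Character formula.
#' @return Scalar in (0, 1].
#' @export
monoisotopic_fraction <- function(formula) {
  counts <- parse_formula(formula)
  p0 <- 1
  for (el in names(counts)) {
    n <- counts[[el]]
    if (n > 0L) p0 <- p0 * .ELEMENTS[[el]]$p0^n
  }
  p0
}
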
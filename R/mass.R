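#' Monoisotopic atomic masses
#'
#' Named vector of monoisotopic atomic masses (Da) for the elements handled by
#' [parseFormula()] and [neutralMonoisotopicMass()]. Values are the IUPAC
#' masses of the most abundant isotope of each element.
#'
#' @format Named numeric vector, names are element symbols.
#' @export
MONOISOTOPIC_MASSES <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100,
  Na = 22.9897692809,
  K = 38.96370668,
  Cl = 34.96885268,
  Fe = 55.9349375,
  Mg = 23.985041700,
  Se = 79.9165213
)

#' Mass of a proton (Da), used to neutralize deprotonated [M-H]- ions.
#' @export
PROTON_MASS <- 1.007276

#' Parse an elemental formula
#'
#' Parses a Hill-style elemental formula such as `"C6H12O6"` into a named
#' vector of element counts. Counts default to 1 when omitted (`"H2O"` has
#' one oxygen). Only elements present in the atomic mass table are accepted.
#'
#' @param formula Character scalar, e.g. `"C6H13O9P"`.
#' @return Named integer vector of element counts.
#' @examples
#' parseFormula("C6H12O6")
#' @export
parseFormula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop("formula must be a non-empty character scalar")
  }
  matches <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  tokens <- regmatches(formula, list(matches))[[1]]
  if (sum(attr(matches, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: '", formula, "'")
  }
  symbols <- sub("[0-9]+$", "", tokens)
  counts <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", tokens)))
  counts[is.na(counts)] <- 1L
  unknown <- setdiff(symbols, names(MONOISOTOPIC_MASSES))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  out <- tapply(counts, factor(symbols, levels = unique(symbols)), sum)
  storage.mode(out) <- "integer"
  if (any(out < 0L) || all(out == 0L)) {
    stop("element counts must be nonnegative and not all zero: '", formula, "'")
  }
  c(out)
}

#' Neutral monoisotopic mass of a formula
#'
#' Sum of element count times monoisotopic atomic mass over the parsed
#' formula. Deterministic; errors on unknown element symbols.
#'
#' @param formula Character scalar elemental formula.
#' @return Mass in Da.
#' @examples
#' neutralMonoisotopicMass("C6H12O6") # 180.06339
#' neutralMonoisotopicMass("H2O")     # 18.010565
#' @export
neutralMonoisotopicMass <- function(formula) {
  counts <- parseFormula(formula)
  sum(counts * MONOISOTOPIC_MASSES[names(counts)])
}

#' Deprotonated ([M-H]-) ion mass of a neutral mass
#'
#' @param neutralMass Neutral monoisotopic mass in Da.
#' @return `neutralMass - PROTON_MASS`.
#' @export
deprotonatedMass <- function(neutralMass) {
  stopifnot(is.numeric(neutralMass))
  neutralMass - PROTON_MASS
}
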
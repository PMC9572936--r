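#' Monoisotopic atomic masses and fundamental constants
#'
#' IUPAC monoisotopic atomic masses (Da) for the elements occurring in the
#' target panel, plus deuterium and carbon-13 for isotope-labelled internal
#' standards, and the electron and proton masses used in ion m/z arithmetic.
#'
#' @return Named list with components `elements` (named numeric vector of
#'   monoisotopic masses in Da), `electron` and `proton` (Da).
#' @examples
#' element_masses()$elements[["C"]]
#' @export
element_masses <- function() {
  list(
    elements = c(
      H  = 1.00782503207,
      C  = 12.0,
      N  = 14.0030740048,
      O  = 15.9949146196,
      S  = 31.97207100,
      F  = 18.99840322,
      Cl = 34.96885268,
      Na = 22.9897692809,
      P  = 30.97376163,
      # heavy isotopes used by labelled internal standards
      `2H`  = 2.01410177785,
      D     = 2.01410177785,
      `13C` = 13.0033548378
    ),
    electron = 0.000548579909,
    proton   = 1.007276466621
  )
}

#' Parse a molecular formula string into element counts
#'
#' Accepts Hill-style formulas such as `"C16H19N3O5S"`. Isotope labels are
#' written in brackets (`"[13C]6H8N2O2S"`, `"C19H17[2H]5FN3O3"`); `D` is
#' accepted as a synonym for `[2H]`.
#'
#' @param formula Formula string, or an already-parsed named numeric vector
#'   (returned unchanged after validation).
#' @return Named numeric vector of element counts.
#' @examples
#' parse_formula("C16H19N3O5S")
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    if (is.null(names(formula)) || any(!nzchar(names(formula))))
      stop("parsed formula must be a named numeric vector", call. = FALSE)
    return(formula)
  }
  stopifnot(is.character(formula), length(formula) == 1L)
  f <- gsub("[[:space:]]", "", formula)
  if (!nzchar(f)) stop("empty formula", call. = FALSE)
  pattern <- "(\\[[0-9]+[A-Z][a-z]?\\]|[A-Z][a-z]?)([0-9]*)"
  tokens <- regmatches(f, gregexpr(pattern, f, perl = TRUE))[[1]]
  if (sum(nchar(tokens)) != nchar(f))
    stop(sprintf("cannot parse formula '%s'", formula), call. = FALSE)
  counts <- numeric(0)
  for (tok in tokens) {
    sym <- sub("^(\\[[0-9]+[A-Z][a-z]?\\]|[A-Z][a-z]?).*$", "\\1", tok)
    num <- sub("^(\\[[0-9]+[A-Z][a-z]?\\]|[A-Z][a-z]?)", "", tok)
    sym <- gsub("\\[|\\]", "", sym)
    n <- if (nzchar(num)) as.numeric(num) else 1
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0) + n
  }
  counts
}

#' Monoisotopic mass of a molecular formula
#'
#' Sums count times monoisotopic atomic mass over the formula. Full double
#' precision is carried; rounding is left to display code.
#'
#' @param formula Formula string or named count vector (see [parse_formula()]).
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C16H19N3O5S") # 365.10454
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  masses <- element_masses()$elements
  unknown <- setdiff(names(counts), names(masses))
  if (length(unknown) > 0)
    stop(sprintf("unknown element symbol(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  if (any(counts < 1)) stop("element counts must be >= 1", call. = FALSE)
  sum(counts * masses[names(counts)])
}

# Adduct registry. `atoms` are net atom changes relative to the neutral
# molecule (negative counts are losses), `charge` the resulting positive
# charge. Only the four species observed on the panel are supported.
.adducts <- list(
  "[M+H]+"     = list(atoms = c(H = 1),           charge = 1L),
  "[M+Na]+"    = list(atoms = c(Na = 1),          charge = 1L),
  "[M+2H]2+"   = list(atoms = c(H = 2),           charge = 2L),
  "[M+H-NH3]+" = list(atoms = c(H = -2, N = -1),  charge = 1L)
)

# Normalize adduct spellings: spaces, unicode minus, and the doubly charged
# species written without the explicit charge count.
normalize_adduct <- function(label) {
  l <- gsub("[[:space:]]", "", label)
  l <- gsub("−|–", "-", l)
  if (l == "[M+2H]+") l <- "[M+2H]2+"
  if (l == "[M+H-NH3]+" || l == "[M+H][NH3]+") l <- "[M+H-NH3]+"
  l
}

#' Adduct specification
#'
#' @param label One of `"[M+H]+"`, `"[M+Na]+"`, `"[M+2H]2+"`, `"[M+H-NH3]+"`
#'   (common spelling variants are normalized).
#' @return List with `label`, `atoms` (net atom changes) and `charge`.
#' @export
adduct_spec <- function(label) {
  l <- normalize_adduct(label)
  if (!l %in% names(.adducts))
    stop(sprintf("unsupported adduct label '%s' (supported: %s)",
                 label, paste(names(.adducts), collapse = ", ")), call. = FALSE)
  c(list(label = l), .adducts[[l]])
}

#' Theoretical m/z of an adduct ion
#'
#' Computes `(M + sum of added-atom masses - charge * electron mass) / charge`
#' where `M` is the monoisotopic mass of the neutral molecule. The electron
#' mass is subtracted per unit charge so that the result is the physically
#' correct ion m/z rather than the atom-mass approximation.
#'
#' @param formula Formula string or named count vector.
#' @param adduct Adduct label or the result of [adduct_spec()].
#' @return Theoretical m/z (Th), full precision. Use `round(x, 4)` for
#'   display at the conventional 4-decimal precision.
#' @examples
#' round(adduct_mz("C16H19N3O5S", "[M+H]+"), 4) # amoxicillin, 366.1118
#' @export
adduct_mz <- function(formula, adduct) {
  spec <- if (is.list(adduct)) adduct else adduct_spec(adduct)
  M <- monoisotopic_mass(formula)
  tab <- element_masses()
  delta <- sum(spec$atoms * tab$elements[names(spec$atoms)])
  (M + delta - spec$charge * tab$electron) / spec$charge
}

#' Signed mass error in parts per million
#'
#' @param observed Observed m/z (vectorized).
#' @param theoretical Theoretical m/z (> 0).
#' @return Signed ppm error `1e6 * (observed - theoretical) / theoretical`.
#' @examples
#' ppm_error(366.11363, 366.1118) # ~ +5
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be > 0", call. = FALSE)
  1e6 * (observed - theoretical) / theoretical
}
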
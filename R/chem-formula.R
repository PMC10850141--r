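# Molecular formula arithmetic and monoisotopic mass.
#
# Masses are CODATA/IUPAC monoisotopic values for the principal isotope.
# Everything downstream (library enumeration, neutral-loss annotation,
# pmol <-> ng conversion) goes through monoisotopic_mass().

#' Monoisotopic element masses
#'
#' Returns the table of monoisotopic masses (Da) used throughout the package,
#' covering the elements occurring in copepodamides (C, H, N, O, S) plus P
#' and the halogens for generality. Carbon is exactly 12 by definition.
#'
#' @return Named numeric vector of monoisotopic masses in Da.
#' @examples
#' element_masses()[["C"]]  # exactly 12
#' @export
element_masses <- function() {
  c(
    C  = 12,
    H  = 1.00782503207,
    N  = 14.0030740048,
    O  = 15.9949146196,
    S  = 31.97207100,
    P  = 30.97376163,
    F  = 18.99840322,
    Cl = 34.96885268,
    Br = 78.9183371,
    I  = 126.904473,
    Na = 22.9897692809,
    K  = 38.96370668
  )
}

# rest mass of the electron, Da (CODATA)
.electron_mass <- 0.000548579909
# mass of the proton (H+), Da
.proton_mass <- 1.00782503207 - 0.000548579909

#' Parse a molecular formula string
#'
#' Converts a Hill-style formula string such as \code{"C22H42NO5S"} into a
#' named integer vector of element counts. Element symbols are one capital
#' letter optionally followed by one lowercase letter; counts default to 1.
#'
#' @param x Formula string. The empty string is a valid empty formula.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C2H6NO3S")
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  x <- gsub("[[:space:]]", "", x)
  if (!nzchar(x)) {
    return(stats::setNames(integer(0), character(0)))
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", x)[[1]]
  tokens <- regmatches(x, gregexpr("[A-Z][a-z]?[0-9]*", x))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x)) {
    stop("cannot parse formula string: '", x, "'")
  }
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- as.integer(sub("^[A-Za-z]+", "", tokens))
  cnt[is.na(cnt)] <- 1L
  out <- tapply(cnt, factor(sym, levels = unique(sym)), sum)
  stats::setNames(as.integer(out), names(out))
}

.as_formula_counts <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (length(formula) && (is.null(names(formula)) || any(!nzchar(names(formula))))) {
    stop("formula must be a named count vector or a formula string")
  }
  if (any(formula < 0)) stop("formula has negative element counts")
  if (any(formula != round(formula))) stop("formula has non-integer counts")
  formula
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula Named count vector (element symbol -> count) or a formula
#'   string such as \code{"C22H42NO5S"}. An empty formula has mass 0.
#' @param charge_mode \code{"neutral"} (default) or \code{"cation"}. Cation
#'   mode subtracts one electron mass: the printed diagnostic-fragment
#'   formulas (e.g. C22H42NO5S for the dhCA fragment at m/z 432) are the
#'   compositions of the charged fragments themselves, so their m/z is the
#'   formula mass less one electron, not a protonated neutral.
#' @return Mass in Da (equivalently m/z for a singly charged ion).
#' @examples
#' monoisotopic_mass("C2H6NO3S", "cation")  # taurine fragment, ~124.006
#' @export
monoisotopic_mass <- function(formula, charge_mode = c("neutral", "cation")) {
  charge_mode <- match.arg(charge_mode)
  counts <- .as_formula_counts(formula)
  if (!length(counts)) {
    m <- 0
  } else {
    em <- element_masses()
    unknown <- setdiff(names(counts), names(em))
    if (length(unknown)) {
      stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
    }
    m <- sum(counts * em[names(counts)])
  }
  if (charge_mode == "cation") m <- m - .electron_mass
  m
}

# sum two formula count vectors
.formula_add <- function(a, b) {
  a <- .as_formula_counts(a); b <- .as_formula_counts(b)
  sym <- union(names(a), names(b))
  out <- stats::setNames(integer(length(sym)), sym)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

.formula_to_string <- function(counts) {
  counts <- .as_formula_counts(counts)
  counts <- counts[counts > 0]
  if (!length(counts)) return("")
  # Hill order: C, H, then alphabetical
  sym <- names(counts)
  ord <- order(match(sym, c("C", "H"), nomatch = 3L), sym)
  paste0(sym[ord], ifelse(counts[ord] == 1L, "", counts[ord]), collapse = "")
}
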
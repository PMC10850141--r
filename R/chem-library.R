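# Copepodamide scaffolds, fatty acyls, homolog enumeration and annotation.
#
# A copepodamide is a taurine-conjugated lipid built from one of two
# scaffolds -- copepodamide (CA, methylene at C3) or dihydro-copepodamide
# (dhCA, methyl at C3) -- carrying a variable fatty acyl at C5. Collision-
# induced dissociation of the [M+H]+ precursor loses the acyl as the free
# fatty acid, leaving a charged diagnostic fragment common to the scaffold
# (m/z 430.26 for CA, 432.28 for dhCA). Precursor-ion scans on those two
# product channels therefore detect the whole class, and the neutral loss
# identifies the acyl.

#' Fatty acyl descriptor
#'
#' @param carbons Integer chain length (>= 2).
#' @param double_bonds Integer number of double bonds;
#'   must satisfy \code{0 <= double_bonds <= floor((carbons - 2) / 2)}.
#' @return An object of class \code{"fatty_acyl"} with fields \code{carbons},
#'   \code{double_bonds} and display \code{label} ("C:D").
#' @examples
#' fatty_acyl(22, 6)       # docosahexaenoyl, "22:6"
#' parse_acyl("18:4")
#' @export
fatty_acyl <- function(carbons, double_bonds) {
  carbons <- as.integer(carbons); double_bonds <- as.integer(double_bonds)
  if (is.na(carbons) || carbons < 2L) {
    stop("fatty acyl needs at least 2 carbons")
  }
  if (is.na(double_bonds) || double_bonds < 0L ||
      double_bonds > (carbons - 2L) %/% 2L) {
    stop("invalid double bond count ", double_bonds, " for ", carbons, " carbons")
  }
  structure(
    list(carbons = carbons, double_bonds = double_bonds,
         label = paste0(carbons, ":", double_bonds)),
    class = "fatty_acyl"
  )
}

#' @rdname fatty_acyl
#' @param label A "C:D" string such as \code{"22:6"}.
#' @export
parse_acyl <- function(label) {
  parts <- strsplit(label, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("acyl label must be 'C:D', got '", label, "'")
  fatty_acyl(as.integer(parts[1]), as.integer(parts[2]))
}

#' @export
print.fatty_acyl <- function(x, ...) {
  cat("<fatty acyl ", x$label, ">\n", sep = ""); invisible(x)
}

#' Molecular formula of the free fatty acid of an acyl
#'
#' The neutral loss observed on acyl cleavage is the free fatty acid
#' CnH(2n-2d)O2 of the "C:D" acyl (n carbons, d double bonds).
#'
#' @param acyl A \code{\link{fatty_acyl}} or a "C:D" label.
#' @return Named count vector (C, H, O).
#' @examples
#' fatty_acid_formula("14:0")  # myristic acid, C14 H28 O2
#' @export
fatty_acid_formula <- function(acyl) {
  if (is.character(acyl)) acyl <- parse_acyl(acyl)
  stopifnot(inherits(acyl, "fatty_acyl"))
  c(C = acyl$carbons, H = 2L * acyl$carbons - 2L * acyl$double_bonds, O = 2L)
}

#' The two copepodamide scaffolds
#'
#' Returns the CA and dhCA scaffold definitions: the molecular formula of the
#' charged diagnostic fragment retained after acyl loss and its m/z. The dhCA
#' fragment is the CA fragment plus two hydrogens (methyl vs methylene at C3,
#' 2.016 Da apart).
#'
#' @return Named list of scaffold objects (class \code{"ca_scaffold"}) with
#'   fields \code{name}, \code{fragment_formula}, \code{diagnostic_product_mz}.
#' @examples
#' copepodamide_scaffolds()$dhCA$diagnostic_product_mz  # ~432.278
#' @export
copepodamide_scaffolds <- function() {
  mk <- function(name, formula) {
    structure(
      list(name = name,
           fragment_formula = parse_formula(formula),
           diagnostic_product_mz = monoisotopic_mass(formula, "cation")),
      class = "ca_scaffold"
    )
  }
  list(CA = mk("CA", "C22H40NO5S"), dhCA = mk("dhCA", "C22H42NO5S"))
}

.get_scaffold <- function(scaffold) {
  if (inherits(scaffold, "ca_scaffold")) return(scaffold)
  sc <- copepodamide_scaffolds()
  if (is.character(scaffold) && scaffold %in% names(sc)) return(sc[[scaffold]])
  stop("unknown scaffold: must be 'CA' or 'dhCA'")
}

#' Theoretical precursor m/z of a copepodamide
#'
#' The singly protonated intact species fragments by neutral loss of the free
#' fatty acid, so its m/z equals the charged scaffold fragment mass plus the
#' neutral fatty acid mass.
#'
#' @param scaffold \code{"CA"}, \code{"dhCA"} or a scaffold object.
#' @param acyl A \code{\link{fatty_acyl}} or "C:D" label.
#' @return Precursor m/z in Da.
#' @examples
#' precursor_mz("dhCA", "14:0")  # 660.49, printed 660.5
#' @export
precursor_mz <- function(scaffold, acyl) {
  sc <- .get_scaffold(scaffold)
  sc$diagnostic_product_mz + monoisotopic_mass(fatty_acid_formula(acyl))
}

#' Enumerate the copepodamide homolog library
#'
#' All valid scaffold x acyl combinations over the given chain-length and
#' unsaturation ranges, with theoretical precursor m/z. Defaults (chains
#' 12-24, 0-6 double bonds) cover every reported copepodamide with margin,
#' including odd-chain species; no biological plausibility filter is applied.
#'
#' @param chain_range Integer length-2 vector, inclusive carbon range.
#' @param unsat_range Integer length-2 vector, inclusive double-bond range.
#' @param scaffolds Character subset of \code{c("CA", "dhCA")}.
#' @return A data.frame of class \code{"ca_library"} with columns
#'   \code{name} (e.g. "22:6 dhCA"), \code{scaffold}, \code{acyl},
#'   \code{carbons}, \code{double_bonds}, \code{precursor_mz},
#'   \code{product_mz}, \code{fatty_acid_mass}, sorted by
#'   (scaffold, carbons, double_bonds).
#' @examples
#' nrow(enumerate_library(c(14, 14), c(0, 0)))  # 2: one per scaffold
#' @export
enumerate_library <- function(chain_range = c(12L, 24L),
                              unsat_range = c(0L, 6L),
                              scaffolds = c("CA", "dhCA")) {
  stopifnot(length(chain_range) == 2L, length(unsat_range) == 2L,
            chain_range[1] <= chain_range[2], unsat_range[1] <= unsat_range[2])
  scaffolds <- match.arg(scaffolds, c("CA", "dhCA"), several.ok = TRUE)
  if (!length(scaffolds)) stop("at least one scaffold required")
  sc_defs <- copepodamide_scaffolds()[sort(scaffolds)]
  rows <- list()
  for (sc in sc_defs) {
    for (n in seq(chain_range[1], chain_range[2])) {
      dmax <- min(unsat_range[2], (n - 2L) %/% 2L)
      if (dmax < unsat_range[1]) next
      for (d in seq(unsat_range[1], dmax)) {
        fa_mass <- monoisotopic_mass(fatty_acid_formula(fatty_acyl(n, d)))
        rows[[length(rows) + 1L]] <- data.frame(
          name = paste0(n, ":", d, " ", sc$name),
          scaffold = sc$name, acyl = paste0(n, ":", d),
          carbons = n, double_bonds = d,
          precursor_mz = sc$diagnostic_product_mz + fa_mass,
          product_mz = sc$diagnostic_product_mz,
          fatty_acid_mass = fa_mass,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    lib <- data.frame(name = character(), scaffold = character(),
                      acyl = character(), carbons = integer(),
                      double_bonds = integer(), precursor_mz = numeric(),
                      product_mz = numeric(), fatty_acid_mass = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    lib <- do.call(rbind, rows)
    lib <- unique(lib)
    lib <- lib[order(lib$scaffold, lib$carbons, lib$double_bonds), ]
    rownames(lib) <- NULL
  }
  class(lib) <- c("ca_library", "data.frame")
  lib
}

#' Annotate a precursor/product pair by scaffold and neutral-loss matching
#'
#' The observed product m/z is matched against the scaffold diagnostic
#' fragments; the neutral loss (precursor - product) is then matched against
#' the free-fatty-acid masses of the library species on the matched
#' scaffold(s). All candidates within tolerance are returned, sorted by
#' absolute mass error of the neutral loss.
#'
#' @param observed_precursor,observed_product Observed m/z values (Da).
#' @param tolerance Matching tolerance in Da (> 0); default 0.3, suited to
#'   unit-resolution triple-quadrupole data.
#' @param library A library from \code{\link{enumerate_library}}.
#' @return Data.frame of candidate species (library columns plus
#'   \code{mass_error}), empty when nothing matches; the attribute
#'   \code{"status"} is \code{"ok"}, \code{"no scaffold"} (product matches
#'   neither diagnostic fragment) or \code{"no acyl"} (scaffold matched but
#'   the loss fits no library fatty acid).
#' @examples
#' assign_acyl(660.5, 432.3)  # 14:0 dhCA
#' @export
assign_acyl <- function(observed_precursor, observed_product, tolerance = 0.3,
                        library = enumerate_library()) {
  stopifnot(tolerance > 0)
  empty <- library[0, , drop = FALSE]
  empty$mass_error <- numeric(0)
  sc <- copepodamide_scaffolds()
  matched <- names(sc)[vapply(
    sc, function(s) abs(s$diagnostic_product_mz - observed_product) <= tolerance,
    logical(1))]
  if (!length(matched)) {
    attr(empty, "status") <- "no scaffold"
    return(empty)
  }
  loss <- observed_precursor - observed_product
  if (loss <= 0) stop("neutral loss must be positive (precursor <= product)")
  cand <- library[library$scaffold %in% matched, , drop = FALSE]
  cand$mass_error <- loss - cand$fatty_acid_mass
  cand <- cand[abs(cand$mass_error) <= tolerance, , drop = FALSE]
  if (!nrow(cand)) {
    attr(empty, "status") <- "no acyl"
    return(empty)
  }
  cand <- cand[order(abs(cand$mass_error)), , drop = FALSE]
  rownames(cand) <- NULL
  attr(cand, "status") <- "ok"
  cand
}

#' Build an MRM transition list
#'
#' One scaffold-diagnostic transition per species; with
#' \code{include_confirmatory}, taurine (m/z 124.0) and sulfonate (m/z 80.0)
#' product transitions are added per species as identity confirmation.
#'
#' @param species A library data.frame (or subset of one).
#' @param include_confirmatory Add taurine and sulfonate transitions.
#' @return Data.frame with columns \code{compound_name}, \code{scaffold},
#'   \code{acyl}, \code{precursor_mz}, \code{product_mz}, \code{kind}.
#' @examples
#' build_transitions(enumerate_library(c(14, 14), c(0, 0)))
#' @export
build_transitions <- function(species, include_confirmatory = FALSE) {
  stopifnot(is.data.frame(species), nrow(species) >= 1L)
  taurine <- monoisotopic_mass("C2H6NO3S", "cation")
  sulfonate <- monoisotopic_mass("SO3", "cation")
  one <- function(product, kind) {
    data.frame(compound_name = species$name, scaffold = species$scaffold,
               acyl = species$acyl, precursor_mz = species$precursor_mz,
               product_mz = product, kind = kind, stringsAsFactors = FALSE)
  }
  out <- one(species$product_mz, "scaffold")
  if (include_confirmatory) {
    out <- rbind(out, one(taurine, "taurine"), one(sulfonate, "sulfonate"))
  }
  out <- out[order(out$precursor_mz, out$compound_name,
                   match(out$kind, c("scaffold", "taurine", "sulfonate"))), ]
  rownames(out) <- NULL
  out
}

#' Write a vendor-neutral transition list as CSV
#'
#' @param transitions Output of \code{\link{build_transitions}}.
#' @param path CSV file path.
#' @param digits m/z display precision (default 4 decimals).
#' @return Invisibly, the path.
#' @export
write_transitions <- function(transitions, path, digits = 4) {
  out <- transitions
  out$precursor_mz <- round(out$precursor_mz, digits)
  out$product_mz <- round(out$product_mz, digits)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
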
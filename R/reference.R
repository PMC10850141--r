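# Packaged reference table of reported copepodamides: 21 dhCA and 14 CA
# species with their reported precursor m/z, first description
# (Grebner2019 = previously known; ThisStudy = newly described) and habitat
# occurrence class (F = freshwater only, M = marine only, B = both).
# The m/z values are stored as *reported*: they are instrument readings at
# unit resolution and deviate from formula-derived theory by up to ~0.2 Da
# for a few entries.

#' Reference table of reported copepodamides
#'
#' The packaged list of 35 reported copepodamide species: scaffold, fatty
#' acyl, reported precursor m/z, where each was first described, its habitat
#' occurrence class (F/M/B), and whether it was seen in a single sample only.
#' Theoretical precursor m/z and the reported-minus-theoretical difference
#' are appended.
#'
#' @return Data.frame with columns \code{name}, \code{scaffold}, \code{acyl},
#'   \code{reported_mz}, \code{theoretical_mz}, \code{mz_error},
#'   \code{described_in}, \code{present_in}, \code{one_sample}.
#' @examples
#' nrow(copepodamide_reference())  # 35
#' @export
copepodamide_reference <- function() {
  path <- system.file("extdata", "copepodamide_reference.csv",
                      package = "copepodamides", mustWork = TRUE)
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  ref$name <- paste(ref$acyl, ref$scaffold)
  ref$theoretical_mz <- mapply(precursor_mz, ref$scaffold, ref$acyl)
  ref$mz_error <- ref$reported_mz - ref$theoretical_mz
  ref[, c("name", "scaffold", "acyl", "reported_mz", "theoretical_mz",
          "mz_error", "described_in", "present_in", "one_sample")]
}

#' Validate reported m/z against an enumerated library
#'
#' Matches each reference entry to the nearest species of the same scaffold
#' in a theoretical library and reports the mass error. Most reported values
#' agree with theory to better than 0.12 Da; three entries (17:0 dhCA,
#' 20:3 dhCA, 22:6 CA) deviate by 0.16-0.20 Da, consistent with measured
#' rather than theoretical values having been reported.
#'
#' @param reference Output of \code{\link{copepodamide_reference}}.
#' @param library A library from \code{\link{enumerate_library}}.
#' @param tolerance Flagging tolerance in Da; entries whose nearest library
#'   match exceeds it get \code{within_tolerance = FALSE}.
#' @return The reference with columns \code{nearest_species},
#'   \code{nearest_error} (reported - nearest theoretical) and
#'   \code{within_tolerance} appended.
#' @export
validate_reference <- function(reference = copepodamide_reference(),
                               library = enumerate_library(),
                               tolerance = 0.15) {
  stopifnot(tolerance > 0)
  nearest <- t(vapply(seq_len(nrow(reference)), function(i) {
    cand <- library[library$scaffold == reference$scaffold[i], , drop = FALSE]
    err <- reference$reported_mz[i] - cand$precursor_mz
    j <- which.min(abs(err))
    c(idx = j, err = err[j])
  }, numeric(2)))
  reference$nearest_species <- vapply(seq_len(nrow(reference)), function(i) {
    library[library$scaffold == reference$scaffold[i], "name"][nearest[i, 1]]
  }, character(1))
  reference$nearest_error <- nearest[, 2]
  reference$within_tolerance <- abs(reference$nearest_error) <= tolerance
  reference
}

#' Count newly described species
#'
#' @param reference A reference table with \code{described_in} and
#'   \code{present_in} columns.
#' @return Named integer vector \code{c(n_new, n_new_freshwater_only)}:
#'   entries first described in this dataset, and those of them occurring
#'   exclusively in freshwater.
#' @examples
#' count_novel(copepodamide_reference())  # 10 new, 4 freshwater-only
#' @export
count_novel <- function(reference = copepodamide_reference()) {
  new <- reference$described_in == "ThisStudy"
  c(n_new = sum(new), n_new_freshwater_only = sum(new & reference$present_in == "F"))
}
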
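# Quantification: single-point external calibration, prosome length to dry
# mass, unit conversions and size-normalised content metrics.

#' Single-point calibration standard
#'
#' An authentic standard of known amount defines the response factor
#' (area per pmol) applied to every compound, under the assumption of equal
#' ionisation efficiency across the class.
#'
#' @param amount_pmol Known amount (> 0), pmol.
#' @param area Measured peak area, arbitrary units (> 0).
#' @return Object of class \code{"ca_standard"} with the derived
#'   \code{response_factor} (area / pmol).
#' @examples
#' calibration_standard(10, 1000)$response_factor  # 100
#' @export
calibration_standard <- function(amount_pmol, area) {
  stopifnot(is.numeric(amount_pmol), amount_pmol > 0, is.numeric(area))
  rf <- area / amount_pmol
  if (!is.finite(rf) || rf <= 0) stop("response factor must be positive")
  structure(list(amount_pmol = amount_pmol, area = area, response_factor = rf),
            class = "ca_standard")
}

#' Quantify an area against the calibration standard
#'
#' Linear single-point calibration through the origin: amount = area /
#' response factor, with the same response factor for every compound.
#'
#' @param area Peak area(s), >= 0; vectorised.
#' @param standard A \code{\link{calibration_standard}}.
#' @return Amount(s) in pmol.
#' @examples
#' quantify(500, calibration_standard(10, 1000))  # 5 pmol
#' @export
quantify <- function(area, standard) {
  stopifnot(inherits(standard, "ca_standard"), all(area >= 0))
  area / standard$response_factor
}

#' Convert pmol to ng of an intact species
#'
#' Uses the neutral monoisotopic mass of the intact species, i.e. the
#' precursor cation m/z minus one proton. The monoisotopic/average mass
#' difference is below 0.1 percent for these species.
#'
#' @param amount_pmol Amount(s) in pmol.
#' @param species One library row (from \code{\link{enumerate_library}}), a
#'   species name such as \code{"22:6 dhCA"}, or a numeric neutral mass (Da).
#' @return Mass in ng.
#' @export
pmol_to_ng <- function(amount_pmol, species) {
  stopifnot(all(amount_pmol >= 0))
  m <- species_neutral_mass(species)
  amount_pmol * m * 1e-3
}

#' Neutral monoisotopic mass of an intact copepodamide
#'
#' @inheritParams pmol_to_ng
#' @return Neutral mass in Da.
#' @export
species_neutral_mass <- function(species) {
  if (is.numeric(species)) return(species)
  if (is.character(species)) {
    parts <- strsplit(species, " ", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("species name must be like '22:6 dhCA'")
    return(precursor_mz(parts[2], parts[1]) - .proton_mass)
  }
  if (is.data.frame(species)) return(species$precursor_mz - .proton_mass)
  stop("cannot interpret species")
}

#' Length-weight power-law model
#'
#' Dry weight from prosome length via W = a * L^b with L in mm and W in ug.
#' The packaged defaults (a = 100, b = 2.5, so a 1 mm prosome maps to
#' 100 ug) are placeholder engineering values, not fitted coefficients:
#' supply taxon-specific regressions for real analyses.
#'
#' @param a Coefficient, ug (> 0).
#' @param b Exponent (> 0).
#' @param taxon Taxon name, or \code{"default"}.
#' @return Object of class \code{"lw_model"}.
#' @export
length_weight_model <- function(a = 100, b = 2.5, taxon = "default") {
  stopifnot(a > 0, b > 0)
  structure(list(taxon = taxon, a = a, b = b), class = "lw_model")
}

#' Dry mass from prosome length
#'
#' @param length_um Prosome length(s) in micrometres (> 0).
#' @param model A \code{\link{length_weight_model}}, or a named list of them
#'   keyed by taxon (with an optional \code{"default"} entry).
#' @param taxon Taxon name(s) used to pick a model from a list.
#' @return Dry mass(es) in ug, with attribute \code{"model_taxon"} recording
#'   which model was applied.
#' @examples
#' dry_mass(1000, length_weight_model(1, 1))  # 1 ug
#' @export
dry_mass <- function(length_um, model = length_weight_model(),
                     taxon = "default") {
  stopifnot(all(length_um > 0))
  pick <- function(tx) {
    if (inherits(model, "lw_model")) return(model)
    m <- model[[tx]]
    if (is.null(m)) m <- model[["default"]]
    if (is.null(m)) stop("no length-weight model for taxon '", tx,
                         "' and no default")
    m
  }
  taxon <- rep_len(taxon, length(length_um))
  w <- vapply(seq_along(length_um), function(i) {
    m <- pick(taxon[i])
    m$a * (length_um[i] / 1000)^m$b
  }, numeric(1))
  attr(w, "model_taxon") <- unname(vapply(taxon, function(tx) pick(tx)$taxon,
                                          character(1)))
  w
}

#' Size-normalised content metrics for one individual
#'
#' Totals the per-compound amounts and expresses the copepodamide content as
#' pmol, ng, and parts-per-thousand of dry mass:
#' ppt = total ng / (dry mass ug * 1000 ng/ug) * 1000.
#'
#' @param amounts_pmol Named numeric vector of per-compound amounts (names
#'   are species such as \code{"22:6 dhCA"}), or a single total in pmol when
#'   \code{total_ng} is given directly.
#' @param dry_mass_ug Dry mass in ug (> 0).
#' @param total_ng Optional: supply the total mass in ng directly, bypassing
#'   the per-species conversion.
#' @return Named numeric vector \code{c(total_pmol, total_ng, ppt)}.
#' @examples
#' content_metrics(numeric(0), 100, total_ng = 10)[["ppt"]]  # 0.1
#' @export
content_metrics <- function(amounts_pmol, dry_mass_ug, total_ng = NULL) {
  stopifnot(is.numeric(dry_mass_ug), length(dry_mass_ug) == 1L)
  if (dry_mass_ug <= 0) stop("dry mass must be positive")
  total_pmol <- sum(amounts_pmol)
  if (is.null(total_ng)) {
    if (length(amounts_pmol) && is.null(names(amounts_pmol))) {
      stop("amounts must be named by species for the pmol -> ng conversion")
    }
    total_ng <- sum(vapply(seq_along(amounts_pmol), function(i) {
      pmol_to_ng(amounts_pmol[i], names(amounts_pmol)[i])
    }, numeric(1)))
  }
  ppt <- total_ng / (dry_mass_ug * 1000) * 1000
  c(total_pmol = total_pmol, total_ng = unname(total_ng), ppt = unname(ppt))
}

#' Allometric regression of content on dry mass
#'
#' Ordinary least squares of ln(total pmol) on ln(dry mass ug), optionally
#' with an additional covariate on the linear predictor (e.g. handling time).
#' Records with non-positive content or mass are dropped with a message.
#'
#' @param total_pmol,dry_mass_ug Numeric vectors (paired observations).
#' @param covariate Optional additional numeric covariate.
#' @return Object of class \code{"ca_allometry"}: list with \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{n}, \code{n_dropped},
#'   \code{fit} (the underlying \code{lm}), and covariate statistics when
#'   supplied.
#' @export
allometric_regression <- function(total_pmol, dry_mass_ug, covariate = NULL) {
  stopifnot(length(total_pmol) == length(dry_mass_ug))
  ok <- is.finite(total_pmol) & is.finite(dry_mass_ug) &
    total_pmol > 0 & dry_mass_ug > 0
  if (!is.null(covariate)) ok <- ok & is.finite(covariate)
  n_dropped <- sum(!ok)
  if (n_dropped) message(n_dropped, " record(s) dropped (non-positive or missing)")
  if (sum(ok) < 3L) stop("need at least 3 usable records")
  y <- log(total_pmol[ok]); x <- log(dry_mass_ug[ok])
  if (is.null(covariate)) {
    fit <- stats::lm(y ~ x)
  } else {
    z <- covariate[ok]
    fit <- stats::lm(y ~ x + z)
  }
  # noiseless validation data fit exactly; that is expected, not a problem
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  r2 <- sm$r.squared
  tss <- sum((y - mean(y))^2)
  # constant response up to rounding: no variance to explain
  if (!is.finite(r2) || tss <= 1e-20 * max(1, mean(y)^2) * length(y)) r2 <- 0
  out <- list(slope = unname(stats::coef(fit)["x"]),
              intercept = unname(stats::coef(fit)[1]),
              r_squared = r2, n = sum(ok), n_dropped = n_dropped,
              fit = fit)
  if (!is.null(covariate)) {
    out$covariate_coef <- unname(stats::coef(fit)["z"])
    out$covariate_p <- sm$coefficients["z", 4]
  }
  structure(out, class = "ca_allometry")
}

#' @export
print.ca_allometry <- function(x, ...) {
  cat(sprintf("Ln(pmol) = %.3f * Ln(dry mass ug) + %.3f, R^2 = %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  if (!is.null(x$covariate_p)) {
    cat(sprintf("  covariate: coef = %.4f, p = %.4f\n",
                x$covariate_coef, x$covariate_p))
  }
  invisible(x)
}
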
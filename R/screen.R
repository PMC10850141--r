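# Screening of bulk precursor-ion scans: annotate class-specific peaks,
# pick MRM targets by the cumulative-abundance rule, and classify compounds
# by habitat occurrence across samples.

#' Screen a bulk precursor-ion-scan spectrum
#'
#' Peaks within the scan window are annotated by matching their product
#' channel to a scaffold diagnostic fragment and their neutral loss to a
#' library fatty acid (\code{\link{assign_acyl}}). Peaks that fail
#' annotation are retained with \code{annotation = NA} for QC.
#'
#' @param spectrum Data.frame with columns \code{mz} (precursor m/z),
#'   \code{intensity}, \code{channel} (observed product m/z, nominally
#'   430.3 or 432.3). An empty spectrum yields an empty hit list.
#' @param library Library from \code{\link{enumerate_library}}.
#' @param window Length-2 numeric scan window on precursor m/z, applied
#'   half-open: peaks with \code{window[1] <= mz < window[2]} are kept.
#' @param tolerance Annotation tolerance in Da.
#' @param sample Optional sample identifier stamped on each hit.
#' @return Data.frame of class \code{"ca_hits"}: \code{sample}, \code{mz},
#'   \code{channel}, \code{intensity}, \code{annotation} (species name or
#'   NA), \code{scaffold}, \code{acyl}, \code{mass_error}.
#' @export
screen_sample <- function(spectrum, library = enumerate_library(),
                          window = c(600, 1000), tolerance = 0.3,
                          sample = NA_character_) {
  stopifnot(is.data.frame(spectrum),
            all(c("mz", "intensity", "channel") %in% names(spectrum)),
            length(window) == 2L, window[1] < window[2], tolerance > 0)
  keep <- spectrum$mz >= window[1] & spectrum$mz < window[2]
  spectrum <- spectrum[keep, , drop = FALSE]
  n <- nrow(spectrum)
  out <- data.frame(
    sample = rep(sample, n), mz = spectrum$mz, channel = spectrum$channel,
    intensity = spectrum$intensity, annotation = rep(NA_character_, n),
    scaffold = rep(NA_character_, n), acyl = rep(NA_character_, n),
    mass_error = rep(NA_real_, n), stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    cand <- assign_acyl(spectrum$mz[i], spectrum$channel[i],
                        tolerance = tolerance, library = library)
    if (nrow(cand)) {
      out$annotation[i] <- cand$name[1]
      out$scaffold[i] <- cand$scaffold[1]
      out$acyl[i] <- cand$acyl[1]
      out$mass_error[i] <- cand$mass_error[1]
    }
  }
  class(out) <- c("ca_hits", "data.frame")
  out
}

#' Select MRM targets by the cumulative-abundance rule
#'
#' Annotated hits are ranked by intensity (ties broken by precursor m/z
#' ascending) and the minimal prefix whose cumulative intensity reaches
#' \code{threshold} of the total annotated intensity is selected; the result
#' is the union of that prefix with an optional list of previously known
#' compounds. With multiple samples present the rule is applied per sample
#' and the selections unioned (set \code{per_sample = FALSE} to pool samples
#' before ranking).
#'
#' @param hits Hits from \code{\link{screen_sample}} (possibly rbind-ed
#'   across samples); unannotated hits are ignored.
#' @param threshold Cumulative intensity fraction in (0, 1]; default 0.8.
#' @param known Optional character vector of compound names always included.
#' @param per_sample Apply the rule within each sample (default) or pooled.
#' @return Character vector of selected compound names, sorted by their
#'   theoretical precursor m/z where resolvable, otherwise by name.
#' @export
select_transitions <- function(hits, threshold = 0.8, known = NULL,
                               per_sample = TRUE) {
  stopifnot(threshold > 0, threshold <= 1)
  ann <- hits[!is.na(hits$annotation), , drop = FALSE]
  if (!nrow(ann)) stop("no annotated hits to select from")
  pick <- function(h) {
    # collapse duplicate annotations within a sample
    tot <- tapply(h$intensity, h$annotation, sum)
    mz <- tapply(h$mz, h$annotation, min)
    if (sum(tot) <= 0) stop("total annotated intensity is zero")
    ord <- order(-tot, mz)
    tot <- tot[ord]
    cum <- cumsum(tot)
    k <- which(cum >= threshold * sum(tot))[1]
    names(tot)[seq_len(k)]
  }
  sel <- if (per_sample) {
    groups <- split(ann, if (all(is.na(ann$sample))) rep(1L, nrow(ann)) else ann$sample)
    unique(unlist(lapply(groups, pick), use.names = FALSE))
  } else {
    pick(ann)
  }
  sel <- union(sel, known)
  # deterministic output order: by m/z of the annotated hit when available
  mzmap <- tapply(ann$mz, ann$annotation, min)
  key <- mzmap[sel]
  key[is.na(key)] <- Inf
  sel[order(key, sel)]
}

#' Classify compounds by habitat occurrence
#'
#' Builds the compounds x samples detection matrix from annotated hits and
#' classifies each compound as occurring only in freshwater samples (F),
#' only in marine samples (M), or in both (B). Detection means annotation in
#' at least one sample; no intensity filter is applied.
#'
#' @param hits Annotated hits across samples (rbind of
#'   \code{\link{screen_sample}} outputs), or a logical compounds x samples
#'   matrix with compound row names.
#' @param habitats Named character vector mapping sample id to
#'   \code{"freshwater"} or \code{"marine"}; every sample in \code{hits}
#'   must be covered.
#' @return Object of class \code{"ca_presence"}: list with \code{detection}
#'   (logical matrix), \code{table} (data.frame: compound, class,
#'   n_samples), and \code{counts} (named vector total/F/M/B).
#' @export
classify_presence <- function(hits, habitats) {
  if (is.matrix(hits)) {
    det <- hits
  } else {
    ann <- hits[!is.na(hits$annotation), , drop = FALSE]
    if (!nrow(ann)) stop("no annotated hits to classify")
    det <- table(ann$annotation, ann$sample) > 0
    det <- matrix(det, nrow = nrow(det), dimnames = dimnames(det))
  }
  if (is.null(names(habitats)) || !all(colnames(det) %in% names(habitats))) {
    stop("habitats must be a named vector covering every sample: missing ",
         paste(setdiff(colnames(det), names(habitats)), collapse = ", "))
  }
  hab <- habitats[colnames(det)]
  if (!all(hab %in% c("freshwater", "marine"))) {
    stop("habitat labels must be 'freshwater' or 'marine'")
  }
  n_det <- rowSums(det)
  det <- det[n_det > 0, , drop = FALSE]  # undetected compounds cannot be classified
  in_f <- rowSums(det[, hab == "freshwater", drop = FALSE]) > 0
  in_m <- rowSums(det[, hab == "marine", drop = FALSE]) > 0
  cls <- ifelse(in_f & in_m, "B", ifelse(in_f, "F", "M"))
  tab <- data.frame(compound = rownames(det), class = cls,
                    n_samples = rowSums(det), row.names = NULL,
                    stringsAsFactors = FALSE)
  counts <- c(total = nrow(tab), F = sum(cls == "F"), M = sum(cls == "M"),
              B = sum(cls == "B"))
  structure(list(detection = det, table = tab, counts = counts),
            class = "ca_presence")
}

#' @export
print.ca_presence <- function(x, ...) {
  cat("Copepodamide presence classification\n")
  cat(sprintf("  %d compounds across %d samples: F = %d, M = %d, B = %d\n",
              x$counts["total"], ncol(x$detection), x$counts["F"],
              x$counts["M"], x$counts["B"]))
  invisible(x)
}

#' Detection matrix of the packaged reference table
#'
#' Expands the reference occurrence classes into a minimal two-sample
#' detection matrix (one freshwater, one marine pseudo-sample) so the
#' reported classification can be reconstructed through
#' \code{\link{classify_presence}}.
#'
#' @param reference Output of \code{\link{copepodamide_reference}}.
#' @return Logical matrix, compounds x c("F_bulk", "M_bulk"), with attribute
#'   \code{"habitats"} suitable for \code{classify_presence}.
#' @export
reference_detection_matrix <- function(reference = copepodamide_reference()) {
  det <- cbind(F_bulk = reference$present_in %in% c("F", "B"),
               M_bulk = reference$present_in %in% c("M", "B"))
  rownames(det) <- reference$name
  attr(det, "habitats") <- c(F_bulk = "freshwater", M_bulk = "marine")
  det
}
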
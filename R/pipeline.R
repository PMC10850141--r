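# Orchestration: library export, the full screen -> quantify -> stats run,
# and JSON/Markdown reporting.

#' Export the theoretical library and its MRM transition list
#'
#' @param path Directory to write \code{library.csv} and
#'   \code{transitions.csv} into (created if needed); \code{NULL} to skip
#'   writing.
#' @param chain_range,unsat_range,scaffolds Passed to
#'   \code{\link{enumerate_library}}.
#' @param include_confirmatory Passed to \code{\link{build_transitions}}.
#' @return List with \code{library} and \code{transitions} data.frames.
#' @export
export_library <- function(path = NULL, chain_range = c(12L, 24L),
                           unsat_range = c(0L, 6L),
                           scaffolds = c("CA", "dhCA"),
                           include_confirmatory = FALSE) {
  lib <- enumerate_library(chain_range, unsat_range, scaffolds)
  if (!nrow(lib)) stop("empty library for the requested bounds")
  tr <- build_transitions(lib, include_confirmatory)
  if (!is.null(path)) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    out <- lib
    out$precursor_mz <- round(out$precursor_mz, 4)
    out$product_mz <- round(out$product_mz, 4)
    out$fatty_acid_mass <- round(out$fatty_acid_mass, 4)
    utils::write.csv(out, file.path(path, "library.csv"), row.names = FALSE)
    write_transitions(tr, file.path(path, "transitions.csv"))
  }
  list(library = lib, transitions = tr)
}

# site x compound intensity matrix from annotated screen hits
.bulk_composition <- function(hits) {
  ann <- hits[!is.na(hits$annotation), , drop = FALSE]
  tab <- tapply(ann$intensity, list(ann$sample, ann$annotation), sum,
                default = 0)
  mat <- matrix(tab, nrow = nrow(tab), dimnames = dimnames(tab))
  mat
}

#' Run the full analysis pipeline on a dataset
#'
#' Screens every bulk scan, selects MRM targets by the cumulative-abundance
#' rule, classifies compounds by habitat occurrence, quantifies individuals
#' by single-point calibration with dry-mass normalisation, and runs the
#' composition statistics (Bray-Curtis, PERMANOVA, PERMDISP, nMDS on bulk
#' samples; PERMANOVA on individual composition; ANCOVA of ln content on
#' habitat controlling for ln dry mass; the content/dry-mass allometric
#' regression). Stages that cannot run (e.g. an empty MRM table) are
#' skipped with a recorded reason, never silently.
#'
#' @param dataset A \code{\link{simulate_dataset}} result, or a list with
#'   the same fields built from files.
#' @param threshold Cumulative intensity fraction for MRM target selection.
#' @param n_perm Permutations for PERMANOVA/PERMDISP.
#' @param nmds_restarts Restarts for the bulk nMDS.
#' @param seed Seed for all stochastic stages (permutations, nMDS starts).
#' @return Object of class \code{"ca_report"}: list of stage results plus
#'   \code{summary} (named counts) and \code{skipped}.
#' @export
run_pipeline <- function(dataset, threshold = 0.8, n_perm = 999,
                         nmds_restarts = 4, seed = 1L) {
  stopifnot(is.list(dataset), !is.null(dataset$bulk), !is.null(dataset$sites))
  cfg <- dataset$config
  lib <- if (!is.null(cfg)) cfg$library else enumerate_library()
  tol <- if (!is.null(cfg)) cfg$tolerance else 0.3
  window <- if (!is.null(cfg)) cfg$window else c(600, 1000)
  skipped <- list()
  habitats <- stats::setNames(dataset$sites$habitat, dataset$sites$site)

  # -- screening ------------------------------------------------------
  hits <- do.call(rbind, lapply(names(dataset$bulk), function(s) {
    screen_sample(dataset$bulk[[s]], library = lib, window = window,
                  tolerance = tol, sample = s)
  }))
  known <- copepodamide_reference()
  targets <- select_transitions(hits, threshold = threshold,
                                known = known$name[known$described_in == "Grebner2019"])
  presence <- classify_presence(hits, habitats)

  # -- quantification -------------------------------------------------
  quant <- NULL
  if (is.null(dataset$mrm) || !nrow(dataset$mrm)) {
    skipped$quantification <- "empty MRM table"
    warning("quantification skipped: empty MRM table")
  } else {
    mrm <- dataset$mrm
    mrm$pmol <- quantify(mrm$area, dataset$calibration)
    recs <- dataset$records
    lw <- if (!is.null(cfg)) cfg$length_weight else length_weight_model()
    recs$dry_mass_ug <- as.numeric(dry_mass(recs$prosome_length_um, lw,
                                            taxon = recs$taxon))
    per_ind <- lapply(seq_len(nrow(recs)), function(i) {
      sub <- mrm[mrm$individual == recs$individual[i], , drop = FALSE]
      amounts <- stats::setNames(sub$pmol, sub$compound)
      content_metrics(amounts, recs$dry_mass_ug[i])
    })
    metrics <- do.call(rbind, per_ind)
    quant <- cbind(recs, as.data.frame(metrics))
  }

  # -- statistics -----------------------------------------------------
  bulk_mat <- .bulk_composition(hits)
  bulk_hab <- habitats[rownames(bulk_mat)]
  stats_out <- list()
  if (length(unique(bulk_hab)) >= 2 && nrow(bulk_mat) >= 4) {
    d_bulk <- bray_curtis(bulk_mat, normalise = TRUE)
    stats_out$permanova_bulk <- permanova(d_bulk, bulk_hab, n_perm = n_perm,
                                          seed = seed)
    stats_out$permdisp_bulk <- permdisp(d_bulk, bulk_hab, n_perm = n_perm,
                                        seed = seed + 1L)
    stats_out$nmds_bulk <- nmds(d_bulk, k = 2, n_restarts = nmds_restarts,
                                seed = seed + 2L)
  } else {
    skipped$bulk_statistics <- "fewer than 2 habitats or 4 bulk samples"
  }
  if (!is.null(quant)) {
    mrm <- dataset$mrm
    mrm$pmol <- quantify(mrm$area, dataset$calibration)
    ind_mat <- tapply(mrm$pmol, list(mrm$individual, mrm$compound), sum,
                      default = 0)
    ind_mat <- matrix(ind_mat, nrow = nrow(ind_mat), dimnames = dimnames(ind_mat))
    ind_hab <- quant$habitat[match(rownames(ind_mat), quant$individual)]
    d_ind <- bray_curtis(ind_mat, normalise = TRUE)
    stats_out$permanova_individuals <- permanova(d_ind, ind_hab,
                                                 n_perm = n_perm,
                                                 seed = seed + 3L)
    stats_out$ancova_content <- ancova(log(quant$total_pmol), quant$habitat,
                                       log(quant$dry_mass_ug))
    stats_out$allometry <- allometric_regression(quant$total_pmol,
                                                 quant$dry_mass_ug)
  } else {
    skipped$individual_statistics <- "quantification unavailable"
  }

  summary <- c(presence$counts,
               n_targets = length(targets),
               n_hits = nrow(hits),
               n_annotated = sum(!is.na(hits$annotation)))
  structure(list(hits = hits, targets = targets, presence = presence,
                 quant = quant, stats = stats_out, summary = summary,
                 skipped = skipped, seed = seed),
            class = "ca_report")
}

#' @export
print.ca_report <- function(x, ...) {
  cat("Copepodamide pipeline report\n")
  cat(sprintf("  hits: %d (%d annotated); MRM targets: %d\n",
              x$summary["n_hits"], x$summary["n_annotated"],
              x$summary["n_targets"]))
  cat(sprintf("  compounds: %d (F = %d, M = %d, B = %d)\n",
              x$summary["total"], x$summary["F"], x$summary["M"],
              x$summary["B"]))
  for (nm in names(x$stats)) {
    obj <- x$stats[[nm]]
    if (inherits(obj, "ca_permutest")) {
      cat(sprintf("  %s: F = %.3g, p = %.4g\n", nm, obj$statistic, obj$p_value))
    } else if (inherits(obj, "ca_nmds")) {
      cat(sprintf("  %s: stress = %.3g\n", nm, obj$stress))
    } else if (inherits(obj, "ca_allometry")) {
      cat(sprintf("  %s: slope = %.3f, R^2 = %.3f\n", nm, obj$slope,
                  obj$r_squared))
    }
  }
  for (nm in names(x$skipped)) {
    cat(sprintf("  skipped %s: %s\n", nm, x$skipped[[nm]]))
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' JSON summary (counts, test statistics, p-values, stress, seeds) plus a
#' short Markdown digest, a hits CSV and a per-individual quantification
#' CSV.
#'
#' @param report A \code{\link{run_pipeline}} result.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ca_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ptests <- lapply(Filter(function(o) inherits(o, "ca_permutest"),
                          report$stats), function(o) {
    list(statistic = o$statistic, df = o$df, p_value = o$p_value,
         r_squared = o$r_squared, n_perm = o$n_perm)
  })
  js <- list(summary = as.list(report$summary), tests = ptests,
             skipped = report$skipped, seed = report$seed)
  if (!is.null(report$stats$nmds_bulk)) {
    js$nmds_stress <- report$stats$nmds_bulk$stress
  }
  if (!is.null(report$stats$allometry)) {
    js$allometry <- report$stats$allometry[c("slope", "intercept", "r_squared", "n")]
  }
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(report$hits, file.path(dir, "hits.csv"), row.names = FALSE)
  if (!is.null(report$quant)) {
    utils::write.csv(report$quant, file.path(dir, "quantification.csv"),
                     row.names = FALSE)
  }
  md <- c("# Copepodamide pipeline report", "",
          sprintf("- compounds detected: %d (F = %d, M = %d, B = %d)",
                  report$summary["total"], report$summary["F"],
                  report$summary["M"], report$summary["B"]),
          sprintf("- MRM targets selected: %d", report$summary["n_targets"]),
          vapply(names(ptests), function(nm) {
            sprintf("- %s: F = %.3g, p = %.4g", nm,
                    ptests[[nm]]$statistic, ptests[[nm]]$p_value)
          }, character(1)),
          if (length(report$skipped)) {
            sprintf("- skipped %s: %s", names(report$skipped),
                    unlist(report$skipped))
          })
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' Stacked composition barplot per individual
#'
#' Per-individual relative composition, split by scaffold colour (CA vs
#' dhCA), grouped by habitat/taxon.
#'
#' @param quant_matrix Individuals x compounds amount matrix.
#' @param groups Factor ordering/grouping the individuals (e.g. taxon).
#' @param ... Passed to \code{barplot}.
#' @return Invisibly, the plotted relative matrix.
#' @export
plot_composition <- function(quant_matrix, groups = NULL, ...) {
  m <- as.matrix(quant_matrix)
  rel <- m / pmax(rowSums(m), .Machine$double.eps)
  ord <- if (!is.null(groups)) order(groups) else seq_len(nrow(rel))
  rel <- rel[ord, , drop = FALSE]
  is_dh <- grepl("dhCA$", colnames(rel))
  cols <- ifelse(is_dh, grDevices::hcl.colors(sum(is_dh), "Greens 3")[
    rank(colnames(rel)[is_dh])], NA)
  cols[!is_dh] <- grDevices::hcl.colors(max(sum(!is_dh), 1), "Blues 3")[
    rank(colnames(rel)[!is_dh])]
  graphics::barplot(t(rel), col = cols, border = NA, las = 2,
                    ylab = "relative abundance", ...)
  invisible(rel)
}
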
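# Plain-text I/O: peak-table CSV, minimal MGF, and whole-dataset writers.
# MGF blocks carry one precursor-ion-scan "spectrum" per product channel.

#' Read a peak-table CSV
#'
#' Expects columns \code{mz}, \code{intensity}, \code{channel}; extra
#' columns are preserved.
#'
#' @param path CSV path.
#' @return Spectrum data.frame.
#' @export
read_peaks_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mz", "intensity", "channel")
  if (!all(need %in% names(x))) {
    stop("peak table must have columns: ", paste(need, collapse = ", "))
  }
  x
}

#' Write bulk spectra as MGF
#'
#' One \code{BEGIN IONS} block per (sample, product channel), with
#' \code{TITLE=sample=<id> channel=<mz>} headers and "mz intensity" peak
#' lines.
#'
#' @param spectra Named list of spectrum data.frames (names are sample ids).
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in names(spectra)) {
    sp <- spectra[[s]]
    for (ch in sort(unique(sp$channel))) {
      sub <- sp[sp$channel == ch, , drop = FALSE]
      writeLines(c("BEGIN IONS",
                   sprintf("TITLE=sample=%s channel=%s", s, format(ch)),
                   sprintf("%.4f %.4f", sub$mz, sub$intensity),
                   "END IONS", ""), con)
    }
  }
  invisible(path)
}

#' Read an MGF written by \code{\link{write_mgf}}
#'
#' @param path MGF file path.
#' @return Named list of spectrum data.frames (mz, intensity, channel).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (lines[i] == "BEGIN IONS") {
      title <- lines[i + 1L]
      m <- regmatches(title, regexec("sample=(\\S+) channel=(\\S+)", title))[[1]]
      if (length(m) != 3L) stop("unparseable TITLE line: ", title)
      s <- m[2]; ch <- as.numeric(m[3])
      j <- i + 2L
      peaks <- list()
      while (lines[j] != "END IONS") {
        v <- as.numeric(strsplit(lines[j], " ", fixed = TRUE)[[1]])
        peaks[[length(peaks) + 1L]] <- v
        j <- j + 1L
      }
      if (length(peaks)) {
        mat <- do.call(rbind, peaks)
        df <- data.frame(mz = mat[, 1], intensity = mat[, 2], channel = ch)
        out[[s]] <- rbind(out[[s]], df)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Write a synthetic dataset to disk
#'
#' Emits the same formats the pipeline reads: per-site bulk peak tables
#' (long CSV and MGF), the MRM table, copepod metadata, the calibration
#' standard (JSON) and the ground-truth ledger (JSON).
#'
#' @param dataset A \code{\link{simulate_dataset}} result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ca_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  bulk <- do.call(rbind, lapply(names(dataset$bulk), function(s) {
    cbind(sample = s, dataset$bulk[[s]])
  }))
  p <- file.path(dir, "bulk_peaks.csv")
  utils::write.csv(bulk, p, row.names = FALSE); paths <- c(paths, p)
  p <- file.path(dir, "bulk_scans.mgf")
  write_mgf(dataset$bulk, p); paths <- c(paths, p)
  p <- file.path(dir, "mrm.csv")
  utils::write.csv(dataset$mrm, p, row.names = FALSE); paths <- c(paths, p)
  p <- file.path(dir, "records.csv")
  utils::write.csv(dataset$records, p, row.names = FALSE); paths <- c(paths, p)
  p <- file.path(dir, "sites.csv")
  utils::write.csv(dataset$sites, p, row.names = FALSE); paths <- c(paths, p)
  p <- file.path(dir, "calibration.json")
  jsonlite::write_json(dataset$calibration[c("amount_pmol", "area")], p,
                       auto_unbox = TRUE, digits = NA); paths <- c(paths, p)
  p <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(dataset$truth, p, digits = NA, dataframe = "columns")
  paths <- c(paths, p)
  invisible(paths)
}
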
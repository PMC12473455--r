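# Database layout: one CSV per record (5000 rows x 12 lead columns, header
# row of lead names) plus a diagnostics CSV keyed by FileName.

.lead_names <- c("I", "II", "III", "aVR", "aVL", "aVF",
                 "V1", "V2", "V3", "V4", "V5", "V6")

.muse_cols <- c("VentricularRate", "AtrialRate", "QRSDuration", "QTInterval",
                "QTCorrected", "RAxis", "TAxis", "QRSCount", "QOnset",
                "QOffset", "TOffset")

.diag_cols <- c("FileName", "Rhythm", "Age", "Gender", .muse_cols)

#' Construct an ECG record object
#'
#' @param signal Numeric matrix, 5000 rows x 12 columns (millivolts).
#' @param record_id Record identifier string.
#' @param fs Sampling rate in Hz.
#' @param lead_names Column labels; defaults to the standard 12-lead order.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(signal, record_id, fs = 500, lead_names = .lead_names) {
  signal <- as.matrix(signal)
  if (nrow(signal) != 5000 || ncol(signal) != 12)
    stopf("malformed record '%s': expected 5000 x 12 samples, got %d x %d",
          record_id, nrow(signal), ncol(signal))
  if (!all(is.finite(signal)))
    stopf("record '%s' contains non-finite samples", record_id)
  colnames(signal) <- lead_names
  structure(list(record_id = record_id, signal = signal, fs = fs,
                 lead_names = lead_names),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record '%s': %d samples x %d leads at %g Hz (%.1f s)\n",
              x$record_id, nrow(x$signal), ncol(x$signal), x$fs,
              nrow(x$signal) / x$fs))
  invisible(x)
}

#' Load one per-record CSV
#'
#' @param path Path to a record CSV: one header row of lead names followed
#'   by 5000 numeric rows x 12 columns.
#' @return An [ecg_record()]; `record_id` is the file stem.
#' @export
load_record <- function(path) {
  if (!file.exists(path)) stopf("record file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad))
    stopf("non-numeric values in record '%s', column(s): %s", path,
          paste(names(df)[bad], collapse = ", "))
  ecg_record(as.matrix(df),
             record_id = tools::file_path_sans_ext(basename(path)),
             lead_names = names(df))
}

#' Write one record to CSV
#'
#' Inverse of [load_record()]; sample values survive the round trip to full
#' precision.
#'
#' @param record An [ecg_record()].
#' @param dir Output directory (created if absent).
#' @return The written file path, invisibly.
#' @export
write_record <- function(record, dir) {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(record$record_id, ".csv"))
  df <- as.data.frame(record$signal)
  names(df) <- record$lead_names
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract one lead from a record
#'
#' Lead lookup is by header name, case-insensitive; `"II"` and `"DII"` are
#' accepted as synonyms (both spellings occur in practice), and the `D`
#' prefix is likewise accepted for leads I and III.
#'
#' @param record An [ecg_record()].
#' @param lead Lead label, default `"II"`.
#' @return Numeric vector of 5000 samples (a copy).
#' @export
select_lead <- function(record, lead = "II") {
  stopifnot(inherits(record, "ecg_record"))
  want <- toupper(lead)
  have <- toupper(record$lead_names)
  # DII -> II etc.
  norm <- function(v) sub("^D(I{1,3})$", "\\1", v)
  idx <- match(norm(want), norm(have))
  if (is.na(idx))
    stopf("unknown lead '%s'; valid leads: %s", lead,
          paste(record$lead_names, collapse = ", "))
  as.numeric(record$signal[, idx])
}

#' Load the diagnostics table
#'
#' @param path CSV with columns FileName, Rhythm, Age, Gender and the 11
#'   GE-MUSE attributes (VentricularRate ... TOffset). Missing numeric
#'   attributes are kept as `NA`, never silently replaced.
#' @return A data.frame, one row per subject.
#' @export
load_diagnostics <- function(path) {
  if (!file.exists(path)) stopf("diagnostics file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(.diag_cols, names(df))
  if (length(missing))
    stopf("diagnostics table lacks mandatory column(s): %s",
          paste(missing, collapse = ", "))
  for (col in c("Age", .muse_cols)) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Write a diagnostics table to CSV
#'
#' @param diagnostics Data.frame as returned by [load_diagnostics()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_diagnostics <- function(diagnostics, path) {
  utils::write.csv(diagnostics, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Load every record listed in a diagnostics table
#'
#' @param dir Directory holding one `<FileName>.csv` per subject. The loader
#'   takes an explicit directory (raw or denoised folder); there is no
#'   auto-discovery.
#' @param diagnostics Diagnostics data.frame; rows without a record file are
#'   dropped with a warning.
#' @return List of [ecg_record()] objects, in diagnostics order.
#' @export
load_records <- function(dir, diagnostics) {
  paths <- file.path(dir, paste0(diagnostics$FileName, ".csv"))
  ok <- file.exists(paths)
  if (!all(ok))
    warnf("%d diagnostics row(s) have no record file and were skipped",
          sum(!ok))
  lapply(paths[ok], load_record)
}
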
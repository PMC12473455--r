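# Canonical 38-column feature table: 13 metadata features (age, gender, 11
# GE-MUSE waveform attributes) + 25 signal descriptors from denoised lead
# II, plus the rhythm label.

.meta_features <- c("Age", "Gender", .muse_cols)

.time_features <- c("AR", "PPA", "MA", "MSI", "SignInt", "RMS1", "RMS2",
                    "MS", "MdS", "SNEO")
.spectral_features <- c("AMSA", "CF", "PF", "ENRG", "SFM", "CP", "MP", "PSA")
.nonlinear_features <- c("Hu", "ScE", "LAC", "WE", "SpeEnt", "ApEn",
                         "FuzzyEn")
.signal_features <- c(.time_features, .spectral_features, .nonlinear_features)

#' Canonical feature names
#'
#' @return Character vector of the 38 feature-column names (13 metadata +
#'   25 signal descriptors) in canonical order.
#' @export
feature_names <- function() c(.meta_features, .signal_features)

#' Named feature subsets
#'
#' The registered subsets used in the experiments: `general4` (age, gender,
#' ventricular and atrial rate), `morph13` (the 13 metadata features:
#' general4 plus the remaining GE-MUSE attributes), `ours29` (general4 plus
#' the 25 signal descriptors) and `all38` (everything).
#'
#' @param name One of `"general4"`, `"morph13"`, `"ours29"`, `"all38"`.
#' @return Character vector of feature names.
#' @export
feature_subset <- function(name = c("all38", "ours29", "morph13",
                                    "general4")) {
  name <- match.arg(name)
  general4 <- c("Age", "Gender", "VentricularRate", "AtrialRate")
  switch(name,
         general4 = general4,
         morph13 = .meta_features,
         ours29 = c(general4, .signal_features),
         all38 = feature_names())
}

#' All 25 signal descriptors of one lead-II signal
#'
#' Computes the 10 time-domain, 8 spectral and 7 nonlinear descriptors.
#' Degenerate values (constant signal, zero band power) are returned as
#' `NA` so they can be imputed downstream within training folds.
#'
#' @param x Numeric sample vector (denoised lead II).
#' @param fs Sampling rate (Hz).
#' @param band Spectral analysis band (Hz).
#' @return Named numeric vector of 25 values.
#' @export
extract_signal_features <- function(x, fs, band = c(0.5, 50)) {
  ps <- power_spectrum(x, fs, band = band)
  c(extract_time_features(x, fs),
    extract_spectral_features(ps),
    Hu = hurst_rs(x),
    ScE = dfa_alpha(x),
    LAC = lac(x),
    entropy_features(x, ps, fs))
}

#' Assemble the subjects x 38 feature table
#'
#' Per subject: optionally denoise lead II through the full chain, compute
#' the 25 signal descriptors, join the 13 metadata features from the
#' diagnostics row, and attach the scheme's class label as a final `Group`
#' column. Gender is encoded 0 (male) / 1 (female). Records without a
#' diagnostics row (or vice versa) are reported and skipped. Subjects whose
#' rhythm code is excluded by the scheme are dropped.
#'
#' @param records List of [ecg_record()] objects.
#' @param diagnostics Diagnostics data.frame (see [load_diagnostics()]).
#' @param scheme A [rhythm_scheme()]; default four-class.
#' @param denoise Run [denoise_pipeline()] on lead II first (default TRUE).
#' @param fs Sampling rate (Hz).
#' @param band Spectral analysis band (Hz).
#' @param filter,span_seconds,nlm Denoising settings, see
#'   [denoise_pipeline()].
#' @return Data.frame with the 38 canonical feature columns plus `Group`
#'   (factor). Row names are record ids.
#' @export
assemble_feature_table <- function(records, diagnostics,
                                   scheme = rhythm_scheme("four"),
                                   denoise = TRUE, fs = 500,
                                   band = c(0.5, 50),
                                   filter = filter_spec(),
                                   span_seconds = 1.5,
                                   nlm = nlm_params()) {
  ids <- vapply(records, function(r) r$record_id, character(1))
  hit <- match(ids, diagnostics$FileName)
  if (anyNA(hit)) {
    warnf("skipping %d record(s) without a diagnostics row: %s", sum(is.na(hit)),
          paste(utils::head(ids[is.na(hit)], 5), collapse = ", "))
    records <- records[!is.na(hit)]
    ids <- ids[!is.na(hit)]
    hit <- hit[!is.na(hit)]
  }
  diag <- diagnostics[hit, , drop = FALSE]
  applied <- apply_rhythm_scheme(diag, scheme)
  keep <- diag$FileName %in% applied$rows$FileName
  records <- records[keep]
  diag <- applied$rows
  labels <- applied$labels

  sig <- t(vapply(records, function(r) {
    x <- select_lead(r, "II")
    if (denoise) x <- denoise_pipeline(x, fs, filter, span_seconds, nlm)
    extract_signal_features(x, fs, band)
  }, numeric(length(.signal_features))))

  gender <- ifelse(toupper(as.character(diag$Gender)) %in%
                     c("FEMALE", "F", "1"), 1, 0)
  meta <- cbind(Age = as.numeric(diag$Age), Gender = gender,
                as.matrix(diag[, .muse_cols]))
  out <- as.data.frame(cbind(meta, sig))
  names(out) <- feature_names()
  out$Group <- labels
  rownames(out) <- diag$FileName
  out
}

#' Write / read a feature table CSV
#'
#' @param table Feature table from [assemble_feature_table()] or
#'   [generate_feature_table()].
#' @param path CSV path.
#' @return `path` (write) or the table (read); the label column is restored
#'   as a factor.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if ("Group" %in% names(df)) df$Group <- factor(df$Group)
  df
}
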
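# Delimited-text I/O for EEG records and concentration series, plus the
# end-to-end convenience pipeline from a raw record to the feature matrix.

#' Read an EEG record from delimited text
#'
#' Expects two columns, time in seconds and amplitude in microvolts (header
#' optional; any of comma, tab or whitespace delimited). The sampling rate
#' is taken from `fs` or inferred from the median time step.
#'
#' @param path file path.
#' @param fs sampling rate in Hz; inferred from the time column when `NULL`.
#' @param subject_id optional subject label.
#' @return an [eeg_record()].
#' @export
read_eeg_csv <- function(path, fs = NULL, subject_id = NULL) {
  d <- .read_two_cols(path)
  if (is.null(fs)) {
    dt <- stats::median(diff(d[[1L]]))
    if (!is.finite(dt) || dt <= 0) stop("cannot infer sampling rate", call. = FALSE)
    fs <- 1 / dt
  }
  eeg_record(d[[2L]], fs = fs, subject_id = subject_id, t0 = d[[1L]][1L])
}

#' Write an EEG record to CSV
#'
#' Two columns: `time_s`, `uV`.
#'
#' @param rec an [eeg_record()].
#' @param path output file path.
#' @export
write_eeg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_record"))
  t <- rec$t0 + (seq_along(rec$samples) - 1) / rec$fs
  utils::write.csv(data.frame(time_s = t, uV = rec$samples), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a concentration series from delimited text
#'
#' Expects two columns, time in seconds and concentration in vol %.
#'
#' @param path file path.
#' @param kind `"end_tidal"` or `"effect_site"`.
#' @return a [concentration_series()].
#' @export
read_concentration_csv <- function(path, kind = c("end_tidal", "effect_site")) {
  d <- .read_two_cols(path)
  concentration_series(d[[1L]], d[[2L]], kind = match.arg(kind))
}

#' Write a concentration series to CSV
#'
#' Two columns: `time_s`, `vol_pct`.
#'
#' @param cs a [concentration_series()].
#' @param path output file path.
#' @export
write_concentration_csv <- function(cs, path) {
  stopifnot(inherits(cs, "conc_series"))
  utils::write.csv(data.frame(time_s = cs$t, vol_pct = cs$c), path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a feature matrix to CSV
#'
#' One row per window: `center_time_s` followed by the 46 named feature
#' columns in the order of [feature_names()].
#'
#' @param features a `doa_features` object.
#' @param path output file path.
#' @export
write_features_csv <- function(features, path) {
  stopifnot(inherits(features, "doa_features"))
  d <- data.frame(center_time_s = features$centers_s, features$values,
                  check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' @param path a file written by [write_features_csv()].
#' @param subject_id optional subject label.
#' @return a `doa_features` object.
#' @export
read_features_csv <- function(path, subject_id = NULL) {
  d <- utils::read.csv(path, check.names = FALSE)
  needed <- feature_names()
  if (!all(needed %in% names(d))) {
    stop("file is missing expected feature columns", call. = FALSE)
  }
  structure(list(values = as.matrix(d[, needed]),
                 centers_s = d$center_time_s, fs = NA_real_,
                 subject_id = subject_id),
            class = "doa_features")
}

.read_two_cols <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("[A-Za-z]", first)
  d <- utils::read.table(path, header = header,
                         sep = if (grepl(",", first)) "," else "",
                         strip.white = TRUE)
  if (ncol(d) < 2L) stop("expected two columns (time, value)", call. = FALSE)
  d[, 1:2]
}

#' Extract hybrid features from a raw EEG record
#'
#' Convenience pipeline: optional mains notch (skipped with a message when
#' the mains frequency reaches Nyquist, as at 100 Hz sampling), 0.8-50 Hz
#' sixth-order Butterworth band-pass, segmentation into `window_len`-sample
#' windows, and assembly of the 46-column feature matrix.
#'
#' @param rec an [eeg_record()].
#' @param mains_hz mains frequency for the notch, `NULL` to skip.
#' @param low_hz,high_hz band-pass edges.
#' @param order band-pass filter order.
#' @param window_len,stride windowing parameters (samples).
#' @param ... further arguments passed to [assemble_features()].
#' @return a `doa_features` object.
#' @export
extract_features <- function(rec, mains_hz = 50, low_hz = 0.8, high_hz = 50,
                             order = 6L, window_len = 500L,
                             stride = window_len, ...) {
  stopifnot(inherits(rec, "eeg_record"))
  if (!is.null(mains_hz)) {
    if (mains_hz < rec$fs / 2) {
      rec <- notch_filter(rec, mains_hz)
    } else {
      message("mains frequency at or above Nyquist; notch skipped")
    }
  }
  rec <- suppressWarnings(bandpass_filter(rec, low_hz, high_hz, order))
  assemble_features(window_eeg(rec, window_len, stride), ...)
}

#' Features and labels for a synthetic session
#'
#' Runs [extract_features()] on a synthetic session's EEG and aligns its
#' effect-site concentration to the window centers.
#'
#' @param session a `synthetic_session` from [simulate_session()].
#' @param ... arguments passed to [extract_features()].
#' @return list with `features` (a `doa_features`) and `labels` (numeric).
#' @export
session_features <- function(session, ...) {
  stopifnot(inherits(session, "synthetic_session"))
  feats <- extract_features(session$eeg, ...)
  feats$subject_id <- session$subject_id
  list(features = feats, labels = align_labels(feats, session$ceff))
}
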
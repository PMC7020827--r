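# EEG preprocessing: record container, zero-phase notch and Butterworth
# band-pass filtering, fixed-length windowing, and wavelet-threshold
# smoothing of extracted feature tracks.

#' Single-channel EEG record
#'
#' @param samples numeric vector of EEG samples in microvolts.
#' @param fs sampling rate in Hz.
#' @param subject_id optional subject label.
#' @param t0 time of the first sample in seconds.
#' @return an `eeg_record` object.
#' @export
eeg_record <- function(samples, fs, subject_id = NULL, t0 = 0) {
  stopifnot(is.numeric(samples), length(samples) >= 1L, fs > 0)
  if (any(!is.finite(samples))) stop("EEG samples must be finite", call. = FALSE)
  structure(list(samples = as.numeric(samples), fs = fs,
                 subject_id = subject_id, t0 = t0),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d samples @ %g Hz (%.1f s)%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (is.null(x$subject_id)) "" else paste0(", subject ", x$subject_id)))
  invisible(x)
}

#' @export
length.eeg_record <- function(x) length(x$samples)

.replace_samples <- function(rec, samples) {
  rec$samples <- as.numeric(samples)
  rec
}

#' Zero-phase mains notch filter
#'
#' Removes power-line interference with a narrow Butterworth band-stop
#' applied forward-backward (`signal::filtfilt`), so the output has no phase
#' shift relative to the input and window-center times stay aligned with
#' concentration labels.
#'
#' @param rec an [eeg_record()].
#' @param mains_hz mains frequency (50 Hz default; set 60 for 60 Hz grids).
#'   Must lie strictly below the Nyquist frequency.
#' @param bw_hz stop-band width in Hz.
#' @return filtered `eeg_record` of the same length.
#' @export
notch_filter <- function(rec, mains_hz = 50, bw_hz = 2) {
  stopifnot(inherits(rec, "eeg_record"))
  nyq <- rec$fs / 2
  if (mains_hz <= 0 || mains_hz >= nyq) {
    stop("mains_hz must lie in (0, fs/2)", call. = FALSE)
  }
  edges <- c(max(mains_hz - bw_hz / 2, 1e-6), min(mains_hz + bw_hz / 2, 0.999 * nyq))
  bf <- signal::butter(2, edges / nyq, type = "stop")
  .replace_samples(rec, signal::filtfilt(bf, rec$samples))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Sixth-order Butterworth high-pass and low-pass sections applied
#' forward-backward, removing drift below `low_hz` and content above
#' `high_hz`. When `high_hz` reaches the Nyquist frequency (as with a 50 Hz
#' edge at 100 Hz sampling) the upper edge is clamped to `0.99 * fs / 2`
#' with a warning, since a Butterworth edge exactly at Nyquist is ill-posed.
#'
#' @param rec an [eeg_record()].
#' @param low_hz,high_hz pass-band edges in Hz (defaults 0.8 and 50).
#' @param order filter order of each section, default 6.
#' @return filtered `eeg_record` of the same length.
#' @export
bandpass_filter <- function(rec, low_hz = 0.8, high_hz = 50, order = 6L) {
  stopifnot(inherits(rec, "eeg_record"), order >= 1L)
  if (low_hz <= 0 || low_hz >= high_hz) {
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  }
  nyq <- rec$fs / 2
  if (low_hz >= nyq) stop("low_hz must lie below the Nyquist frequency", call. = FALSE)
  hi <- high_hz
  if (hi >= nyq) {
    hi <- 0.99 * nyq
    warning("high_hz clamped to ", signif(hi, 4), " Hz (below Nyquist)", call. = FALSE)
    if (low_hz >= hi) stop("low_hz must lie below the clamped upper edge", call. = FALSE)
  }
  hp <- signal::butter(order, low_hz / nyq, type = "high")
  lp <- signal::butter(order, hi / nyq, type = "low")
  y <- signal::filtfilt(hp, rec$samples)
  y <- signal::filtfilt(lp, y)
  .replace_samples(rec, y)
}

#' Segment an EEG record into fixed-length windows
#'
#' Slices the record into `window_len`-sample analysis windows advancing by
#' `stride` samples; a trailing partial window is discarded. The defaults
#' give non-overlapping 5 s windows at 100 Hz.
#'
#' @param rec an [eeg_record()].
#' @param window_len window length in samples, default 500.
#' @param stride hop between window starts in samples, default `window_len`.
#' @return a `windowed_eeg` object: `windows` (n_windows x window_len
#'   matrix), `centers_s` (window-center times in seconds), `window_len`,
#'   `stride`, `fs`, `subject_id`.
#' @export
window_eeg <- function(rec, window_len = 500L, stride = window_len) {
  stopifnot(inherits(rec, "eeg_record"), stride >= 1L)
  n <- length(rec$samples)
  if (window_len > n) stop("window_len exceeds record length", call. = FALSE)
  starts <- seq(1L, n - window_len + 1L, by = stride)
  win <- matrix(0, length(starts), window_len)
  for (i in seq_along(starts)) {
    win[i, ] <- rec$samples[starts[i]:(starts[i] + window_len - 1L)]
  }
  centers <- rec$t0 + (starts - 1 + (window_len - 1) / 2) / rec$fs
  structure(list(windows = win, centers_s = centers,
                 window_len = as.integer(window_len),
                 stride = as.integer(stride),
                 fs = rec$fs, subject_id = rec$subject_id),
            class = "windowed_eeg")
}

#' Wavelet-threshold smoothing of a feature track
#'
#' Denoises a per-window feature time series by soft universal thresholding
#' of its wavelet detail coefficients (db4, `level` scales; threshold
#' `sigma * sqrt(2 log n)` per detail level with `sigma` from the median
#' absolute coefficient). The track is extended by reflection before the
#' transform to avoid boundary artifacts from the periodized DWT, so smooth
#' trends pass through essentially unchanged while high-frequency noise is
#' suppressed.
#'
#' @param track numeric feature time series; length must be at least
#'   `2^level`.
#' @param wavelet wavelet basis (currently `"db4"`).
#' @param level decomposition depth, default 3.
#' @return smoothed track of the same length.
#' @export
smooth_feature_track <- function(track, wavelet = "db4", level = 3L) {
  n <- length(track)
  if (n < 2^level) {
    stop("track of length ", n, " too short for level-", level,
         " smoothing", call. = FALSE)
  }
  ext <- c(track, rev(track))            # reflection: periodic and continuous
  dec <- .wavedec(ext, level, wavelet)
  for (j in seq_len(level) + 1L) {
    d <- dec$coeffs[[j]]
    sigma <- stats::median(abs(d)) / 0.6745
    thr <- sigma * sqrt(2 * log(length(ext)))
    dec$coeffs[[j]] <- sign(d) * pmax(abs(d) - thr, 0)
  }
  .waverec(dec)[seq_len(n)]
}
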
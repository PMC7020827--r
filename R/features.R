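# Per-window EEG features: sample entropy, permutation entropy, wavelet
# entropy, half-Hz band spectra (30-50 Hz) and the alpha-ratio, assembled
# into the fixed 46-column hybrid feature matrix used by the depth-of-
# anesthesia regressor.

#' Sample entropy of a signal window
#'
#' Estimates signal irregularity as the negative log conditional probability
#' that template vectors matching for `m` consecutive points (Chebyshev
#' distance within tolerance `r`, self-matches excluded) also match for
#' `m + 1` points. Larger values indicate a more irregular signal; EEG sample
#' entropy falls with deepening anesthesia.
#'
#' @param x numeric signal window (typically 500 samples of 100 Hz EEG).
#' @param m template length (embedding dimension), default 2.
#' @param r similarity threshold; with `relative_r = TRUE` (default) it is a
#'   fraction of the window standard deviation, making the statistic
#'   invariant under positive affine rescaling of the signal.
#' @param relative_r interpret `r` relative to `sd(x)`?
#' @return non-negative scalar. A constant window returns 0 (every template
#'   matches at every length). If no template pair matches at length
#'   `m + 1` (or at `m`), the conditional probability is undefined and the
#'   largest representable finite value is returned with a warning.
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2, relative_r = TRUE) {
  n <- length(x)
  stopifnot(is.numeric(x), m >= 1L, r > 0)
  if (n <= m + 1L) stop("window too short for m = ", m, call. = FALSE)
  if (any(!is.finite(x))) stop("window contains non-finite values", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) return(0)
  r_abs <- if (relative_r) r * s else r
  # Pairwise Chebyshev template distances via a running max over the m (and
  # m+1) aligned scalar-difference matrices; templates i = 1..n-m for both
  # embedding lengths so the normalizing counts cancel in the ratio.
  nt <- n - m
  D <- abs(outer(x, x, "-"))
  dmax <- D[seq_len(nt), seq_len(nt)]
  for (k in seq_len(m - 1L)) {
    dmax <- pmax(dmax, D[seq_len(nt) + k, seq_len(nt) + k])
  }
  ut <- upper.tri(dmax)
  b_count <- sum(dmax[ut] <= r_abs)
  dmax <- pmax(dmax, D[seq_len(nt) + m, seq_len(nt) + m])
  a_count <- sum(dmax[ut] <= r_abs)
  if (b_count == 0L || a_count == 0L) {
    warning("no template matches at length m", if (b_count > 0L) " + 1",
            "; returning the maximum finite value", call. = FALSE)
    return(.Machine$double.xmax)
  }
  -log(a_count / b_count)
}

#' Permutation entropy of a signal window
#'
#' Normalized Shannon entropy of the ordinal-pattern distribution of delay
#' vectors `(x_i, x_{i+tau}, ..., x_{i+(m-1)tau})`. Equal values are ranked
#' by order of occurrence (stable sort). Returns a value in `[0, 1]`: 0 for a
#' monotone window (a single pattern), 1 when all `m!` patterns are
#' equiprobable. Invariant under strictly increasing transforms of the
#' signal.
#'
#' @param x numeric signal window.
#' @param m ordinal pattern length, default 4.
#' @param tau time delay in samples, default 1.
#' @return scalar in `[0, 1]`.
#' @export
permutation_entropy <- function(x, m = 4L, tau = 1L) {
  n <- length(x)
  stopifnot(m >= 2L, tau >= 1L)
  n_vec <- n - (m - 1L) * tau
  if (n_vec < 1L) stop("window too short for m = ", m, ", tau = ", tau, call. = FALSE)
  if (any(!is.finite(x))) stop("window contains non-finite values", call. = FALSE)
  emb <- vapply(seq_len(m) - 1L,
                function(k) x[seq_len(n_vec) + k * tau],
                numeric(n_vec))
  if (n_vec == 1L) emb <- matrix(emb, nrow = 1L)
  keys <- apply(emb, 1L, function(v) paste(order(v), collapse = "."))
  p <- tabulate(factor(keys))
  p <- p / sum(p)
  -sum(p * log(p)) / log(factorial(m))
}

#' Wavelet entropy of a signal window
#'
#' Shannon entropy of the relative wavelet energy distribution across
#' decomposition scales: the window is decomposed with a periodized
#' orthogonal DWT into `levels` detail scales plus one approximation, the
#' energy of each coefficient band is normalized to the total energy, and
#' `S = -sum(p_j * log(p_j))` (natural log) is returned. `S = 0` when all
#' energy sits in a single scale and `log(levels + 1)` when it is spread
#' uniformly.
#'
#' @param x numeric signal window; length must be at least `2^levels`.
#' @param wavelet wavelet basis (currently `"db4"`).
#' @param levels decomposition depth, default 5.
#' @return scalar in `[0, log(levels + 1)]`; an all-zero window returns 0.
#' @export
wavelet_entropy <- function(x, wavelet = "db4", levels = 5L) {
  stopifnot(levels >= 2L)
  if (length(x) < 2^levels) {
    stop("window shorter than 2^levels samples", call. = FALSE)
  }
  e <- wavelet_band_energies(x, wavelet, levels)
  total <- sum(e)
  if (total == 0) return(0)
  p <- e / total
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Wavelet band energies
#'
#' Energy `E_j = sum_k |C_j(k)|^2` of each wavelet decomposition band
#' (approximation first, then details coarse to fine) underlying
#' [wavelet_entropy()]. Exposed so the relative-energy distribution can be
#' inspected directly.
#'
#' @inheritParams wavelet_entropy
#' @return numeric vector of `levels + 1` non-negative energies.
#' @export
wavelet_band_energies <- function(x, wavelet = "db4", levels = 5L) {
  dec <- .wavedec(x, levels, wavelet)
  vapply(dec$coeffs, function(cf) sum(cf^2), numeric(1))
}

# Hann-windowed one-sided periodogram. Returns a data.frame of frequencies
# (Hz) and power density; the absolute scale is internally consistent, which
# is all the band-ratio and binned-spectrum features require.
.periodogram <- function(x, fs) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / n))
  xf <- stats::fft((x - mean(x)) * w)
  nf <- n %/% 2L + 1L
  p <- Mod(xf[seq_len(nf)])^2 / (sum(w^2) * fs)
  # double the interior bins to fold negative frequencies in
  if (nf > 2L) p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
  if (n %% 2L == 1L) p[nf] <- 2 * p[nf]
  data.frame(freq = (seq_len(nf) - 1L) * fs / n, power = p)
}

.band_power <- function(pg, lo, hi) {
  sum(pg$power[pg$freq >= lo & pg$freq < hi])
}

#' Binned high-frequency band spectra
#'
#' Aggregates the window periodogram into 40 half-Hz power bins covering
#' `[30, 50)` Hz plus the mean power of the `[30, 47)` and `[47, 50)` Hz
#' ranges (means of their constituent half-Hz bins). At the native setting
#' (500-sample window, 100 Hz) the periodogram resolution is 0.2 Hz and each
#' half-Hz bin sums the native bins whose centers fall in `[f, f + 0.5)`.
#'
#' @param x numeric signal window.
#' @param fs sampling rate in Hz.
#' @return named numeric vector of 42 non-negative values.
#' @export
band_spectra <- function(x, fs) {
  pg <- .periodogram(x, fs)
  edges <- seq(30, 49.5, by = 0.5)
  bins <- vapply(edges, function(f) .band_power(pg, f, f + 0.5), numeric(1))
  names(bins) <- sprintf("spec_%.1fHz", edges)
  c(bins,
    spec_mean_30_47 = mean(bins[edges < 47]),
    spec_mean_47_50 = mean(bins[edges >= 47]))
}

#' Alpha-ratio band-power index
#'
#' Log ratio of spectral energy in the 30-42.5 Hz band to the 6-12 Hz band,
#' `log10(E_30-42.5 / E_6-12)`. The high band collapses faster than the
#' alpha band with deepening anesthesia, so the ratio falls with depth.
#'
#' @param x numeric signal window.
#' @param fs sampling rate in Hz.
#' @param base logarithm base, default 10.
#' @return scalar; `NA` with a warning when the 6-12 Hz band has zero energy.
#' @export
alpha_ratio <- function(x, fs, base = 10) {
  pg <- .periodogram(x, fs)
  e_hi <- .band_power(pg, 30, 42.5)
  e_lo <- .band_power(pg, 6, 12)
  if (e_lo == 0) {
    warning("zero energy in the 6-12 Hz band; alpha-ratio undefined", call. = FALSE)
    return(NA_real_)
  }
  log(e_hi / e_lo, base = base)
}

#' Names and order of the 46 hybrid features
#'
#' Fixed column order of the feature matrix: 40 half-Hz spectral bins over
#' `[30, 50)` Hz, the two band-averaged spectra, permutation entropy, sample
#' entropy, wavelet entropy and the alpha-ratio.
#'
#' @return character vector of length 46.
#' @export
feature_names <- function() {
  c(sprintf("spec_%.1fHz", seq(30, 49.5, by = 0.5)),
    "spec_mean_30_47", "spec_mean_47_50",
    "peen", "sampen", "wavent", "alpha_ratio")
}

#' Assemble the 46-column hybrid feature matrix
#'
#' Computes all 46 features for every analysis window and optionally
#' wavelet-denoises each feature track over time (see
#' [smooth_feature_track()]). Row `i` depends only on window `i`; smoothing,
#' when enabled, operates along columns afterwards.
#'
#' @param windows a `windowed_eeg` object from [window_eeg()].
#' @param sampen_m,sampen_r sample entropy parameters.
#' @param peen_m,peen_tau permutation entropy parameters.
#' @param wavent_levels wavelet entropy decomposition depth.
#' @param smooth wavelet-denoise each feature track? Skipped with a message
#'   when the track is too short for the requested level.
#' @param smooth_level decomposition level for track smoothing.
#' @return a `doa_features` object: list with `values` (n_windows x 46
#'   matrix, columns ordered per [feature_names()]), `centers_s`, `fs`,
#'   `subject_id`.
#' @export
assemble_features <- function(windows, sampen_m = 2L, sampen_r = 0.2,
                              peen_m = 4L, peen_tau = 1L,
                              wavent_levels = 5L,
                              smooth = TRUE, smooth_level = 3L) {
  stopifnot(inherits(windows, "windowed_eeg"))
  n_win <- nrow(windows$windows)
  if (n_win < 1L) stop("no windows to extract features from", call. = FALSE)
  fs <- windows$fs
  vals <- matrix(NA_real_, n_win, 46L, dimnames = list(NULL, feature_names()))
  for (i in seq_len(n_win)) {
    w <- windows$windows[i, ]
    res <- tryCatch({
      sp <- band_spectra(w, fs)
      c(sp,
        peen = permutation_entropy(w, peen_m, peen_tau),
        sampen = sample_entropy(w, sampen_m, sampen_r),
        wavent = wavelet_entropy(w, levels = wavent_levels),
        alpha_ratio = alpha_ratio(w, fs))
    }, error = function(e) {
      stop("feature extraction failed for window ", i, ": ",
           conditionMessage(e), call. = FALSE)
    })
    vals[i, ] <- res
  }
  if (smooth) {
    if (n_win >= 2^smooth_level) {
      for (j in seq_len(ncol(vals))) {
        if (all(is.finite(vals[, j]))) {
          vals[, j] <- smooth_feature_track(vals[, j], level = smooth_level)
        }
      }
    } else {
      message("feature tracks too short for level-", smooth_level,
              " smoothing; skipped")
    }
  }
  structure(list(values = vals, centers_s = windows$centers_s, fs = fs,
                 subject_id = windows$subject_id),
            class = "doa_features")
}
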
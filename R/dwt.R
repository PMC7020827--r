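# Periodized discrete wavelet transform (Daubechies db4).
#
# A compact orthogonal DWT used by wavelet_entropy() and
# smooth_feature_track(). Circular (periodized) convolution keeps the
# transform orthogonal and the coefficient count minimal; odd-length inputs
# are extended by repeating the last sample and truncated back on
# reconstruction, which preserves perfect reconstruction.

# db4 (8-tap Daubechies, 4 vanishing moments) decomposition low-pass filter.
.DB4_DEC_LO <- c(-0.010597401784997278, 0.032883011666982945,
                 0.030841381835986965, -0.18703481171888114,
                 -0.02798376941698385, 0.6308807679295904,
                 0.7148465705525415, 0.23037781330885523)

.dwt_filters <- function(wavelet = "db4") {
  if (!identical(wavelet, "db4")) {
    stop("only the 'db4' wavelet is supported", call. = FALSE)
  }
  lo <- .DB4_DEC_LO
  L <- length(lo)
  hi <- rev(lo) * (-1)^seq_len(L)         # quadrature mirror
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi))
}

# One analysis step. Returns approximation and detail coefficients of
# length ceiling(n/2) plus the original input length (needed to undo the
# odd-length edge padding).
.dwt_step <- function(x, filt) {
  n0 <- length(x)
  if (n0 %% 2L == 1L) x <- c(x, x[n0])    # edge-pad odd lengths to even
  n <- length(x)
  L <- length(filt$dec_lo)
  s <- L %/% 2L
  k <- seq_len(n %/% 2L) - 1L
  cA <- numeric(length(k))
  cD <- numeric(length(k))
  for (j in seq_len(L) - 1L) {
    idx <- ((2L * k + s - j) %% n) + 1L
    cA <- cA + filt$dec_lo[j + 1L] * x[idx]
    cD <- cD + filt$dec_hi[j + 1L] * x[idx]
  }
  list(cA = cA, cD = cD, n = n0)
}

# One synthesis step, truncated to the pre-padding length out_len.
.idwt_step <- function(cA, cD, filt, out_len) {
  n <- 2L * length(cA)
  up_a <- numeric(n); up_a[seq(1L, n, by = 2L)] <- cA
  up_d <- numeric(n); up_d[seq(1L, n, by = 2L)] <- cD
  L <- length(filt$rec_lo)
  t_off <- L %/% 2L - 1L
  i <- seq_len(n) - 1L
  x <- numeric(n)
  for (j in seq_len(L) - 1L) {
    idx <- ((i + t_off - j) %% n) + 1L
    x <- x + filt$rec_lo[j + 1L] * up_a[idx] + filt$rec_hi[j + 1L] * up_d[idx]
  }
  x[seq_len(out_len)]
}

# Multilevel decomposition; coefficient list ordered coarse-to-fine:
# cA_level, cD_level, ..., cD_1 (one approximation + `level` details).
.wavedec <- function(x, level, wavelet = "db4") {
  stopifnot(level >= 1L)
  if (length(x) < 2^level) {
    stop("signal of length ", length(x),
         " is too short for a level-", level, " decomposition", call. = FALSE)
  }
  filt <- .dwt_filters(wavelet)
  details <- vector("list", level)
  lengths <- integer(level)
  cur <- x
  for (lev in seq_len(level)) {
    st <- .dwt_step(cur, filt)
    details[[level - lev + 1L]] <- st$cD
    lengths[level - lev + 1L] <- st$n
    cur <- st$cA
  }
  structure(list(coeffs = c(list(cur), details), lengths = lengths,
                 wavelet = wavelet, level = level), class = "doa_wavedec")
}

.waverec <- function(dec) {
  filt <- .dwt_filters(dec$wavelet)
  cur <- dec$coeffs[[1L]]
  for (lev in seq_len(dec$level)) {
    cur <- .idwt_step(cur, dec$coeffs[[lev + 1L]], filt, dec$lengths[lev])
  }
  cur
}
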
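# Entropy and spectral features against independent oracles and their
# documented invariances.

test_that("sample entropy matches the exhaustive counting oracle", {
  set.seed(11)
  for (k in 1:20) {
    x <- rnorm(60)
    ref <- sampen_oracle(x)
    if (is.na(ref)) {
      # oracle: no template matches at m + 1 -> documented sentinel + warning
      expect_warning(v <- sample_entropy(x), "maximum finite value")
      expect_identical(v, .Machine$double.xmax)
    } else {
      expect_equal(sample_entropy(x), ref, tolerance = 1e-9)
    }
  }
  # AR(1) windows have more template matches; exercise that regime too
  for (k in 1:5) {
    x <- as.numeric(arima.sim(list(ar = 0.9), 80))
    expect_equal(sample_entropy(x), sampen_oracle(x), tolerance = 1e-9)
  }
})

test_that("sample entropy is invariant under positive affine rescaling", {
  set.seed(12)
  x <- rnorm(100)
  expect_equal(sample_entropy(3.7 * x + 11), sample_entropy(x), tolerance = 1e-12)
})

test_that("sample entropy of a constant window is 0", {
  expect_identical(sample_entropy(rep(2.5, 50)), 0)
})

test_that("sample entropy returns the maximum finite value with a warning when nothing matches", {
  set.seed(13)
  x <- rnorm(30)
  expect_warning(v <- sample_entropy(x, r = 1e-14, relative_r = FALSE),
                 "maximum finite value")
  expect_identical(v, .Machine$double.xmax)
})

test_that("sample entropy rejects degenerate input", {
  expect_error(sample_entropy(c(1, 2, 3), m = 2L), "too short")
  expect_error(sample_entropy(c(rnorm(10), NA)), "non-finite")
})

test_that("permutation entropy matches the exhaustive pattern-table oracle", {
  set.seed(14)
  for (k in 1:20) {
    x <- rnorm(sample(30:80, 1))
    expect_equal(permutation_entropy(x), peen_oracle(x), tolerance = 1e-9)
  }
  # repeated values stress the stable tie-ranking
  x <- sample(1:4, 60, replace = TRUE)
  expect_equal(permutation_entropy(x), peen_oracle(x), tolerance = 1e-9)
  expect_equal(permutation_entropy(x, m = 3L, tau = 2L),
               peen_oracle(x, m = 3L, tau = 2L), tolerance = 1e-9)
})

test_that("permutation entropy of a monotone window is 0 and lies in [0, 1]", {
  expect_equal(permutation_entropy(1:50), 0)
  expect_equal(permutation_entropy(seq(10, 1, length.out = 40)), 0)
  set.seed(15)
  v <- replicate(10, permutation_entropy(rnorm(200)))
  expect_true(all(v >= 0 & v <= 1))
})

test_that("permutation entropy is invariant under strictly increasing transforms", {
  set.seed(16)
  x <- rnorm(150)
  expect_identical(permutation_entropy(exp(x)), permutation_entropy(x))
})

test_that("wavelet entropy matches the frozen reference and its analytic bounds", {
  t <- 0:99
  x <- sin(2 * pi * 2 * t / 100) + 0.5 * sin(2 * pi * 20 * t / 100 + 1)
  # reference computed with PyWavelets (db4, periodization, 5 levels)
  expect_equal(wavelet_entropy(x), 1.0258216245629803, tolerance = 1e-9)
  e <- wavelet_band_energies(x)
  expect_length(e, 6L)
  expect_equal(e, c(53.81477797981919, 9.252520714261685, 3.5694151933641827,
                    0.046004699368774875, 10.070932536440768,
                    2.4060058711180536), tolerance = 1e-9)
  expect_identical(wavelet_entropy(rep(0, 64)), 0)
  set.seed(17)
  expect_lte(wavelet_entropy(rnorm(500)), log(6) + 1e-12)
})

test_that("band spectra produce 42 named non-negative values with exact aggregates", {
  set.seed(18)
  x <- rnorm(500)
  sp <- band_spectra(x, fs = 100)
  expect_length(sp, 42L)
  expect_named(sp, c(sprintf("spec_%.1fHz", seq(30, 49.5, by = 0.5)),
                     "spec_mean_30_47", "spec_mean_47_50"))
  expect_true(all(sp >= 0))
  bins <- sp[1:40]
  edges <- seq(30, 49.5, by = 0.5)
  expect_equal(unname(sp["spec_mean_30_47"]), mean(bins[edges < 47]))
  expect_equal(unname(sp["spec_mean_47_50"]), mean(bins[edges >= 47]))
})

test_that("band spectra concentrate power at a tone's frequency", {
  t <- seq(0, 4.99, by = 0.01)
  x <- sin(2 * pi * 40 * t)
  sp <- band_spectra(x, fs = 100)
  expect_identical(names(which.max(sp[1:40])), "spec_40.0Hz")
})

test_that("alpha-ratio orders high-band versus alpha-band signals correctly", {
  t <- seq(0, 4.99, by = 0.01)
  hi <- sin(2 * pi * 40 * t) + 0.1 * sin(2 * pi * 10 * t)
  lo <- 0.1 * sin(2 * pi * 40 * t) + sin(2 * pi * 10 * t)
  expect_gt(alpha_ratio(hi, 100), alpha_ratio(lo, 100))
  expect_gt(alpha_ratio(hi, 100), 0)
  expect_lt(alpha_ratio(lo, 100), 0)
  expect_warning(v <- alpha_ratio(rep(0, 500), 100), "alpha-ratio undefined")
  expect_true(is.na(v))
})

test_that("assemble_features yields a complete 46-column matrix", {
  eeg <- short_session()$eeg
  win <- window_eeg(bandpass_filter(eeg, 0.8, 45), 500L)
  feats <- assemble_features(win)
  expect_s3_class(feats, "doa_features")
  expect_identical(dim(feats$values), c(24L, 46L))
  expect_identical(colnames(feats$values), feature_names())
  expect_true(all(is.finite(feats$values)))
  expect_identical(feats$centers_s, win$centers_s)
})

test_that("smoothing is columnwise and leaves per-window computation unchanged", {
  eeg <- short_session()$eeg
  win <- window_eeg(eeg, 500L)
  raw <- assemble_features(win, smooth = FALSE)
  sm <- assemble_features(win, smooth = TRUE)
  for (j in seq_len(46L)) {
    expect_equal(sm$values[, j], smooth_feature_track(raw$values[, j]),
                 tolerance = 1e-12)
  }
})
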
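---
title: "Methods: depth-of-anesthesia index estimation from single-channel EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-of-anesthesia index estimation from single-channel EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

During inhalational (sevoflurane) anesthesia the clinician titrates the drug
against the patient's *depth of anesthesia* (DoA), which is not directly
observable. Two observable quantities bracket it:

- the **end-tidal concentration** `Cet(t)` of the anesthetic gas in exhaled
  air (vol %), a proxy for arterial drug level; and
- the **electroencephalogram** (EEG), whose rhythm slows and becomes more
  regular as anesthesia deepens.

The brain does not respond to `Cet` instantaneously. The classical
effect-compartment model posits a hypothetical *effect site* whose
concentration `Ceff` lags `Cet` through first-order kinetics,

$$\frac{dC_{\mathrm{eff}}}{dt} = k_{e0}\,(C_{\mathrm{et}} - C_{\mathrm{eff}}),$$

with rate constant `keo` (1/min). `Ceff` is the pharmacologically meaningful
depth surrogate, and this package treats it as the regression target: an EEG
index is *good* exactly insofar as it orders observations the way `Ceff`
does.

The pipeline is:

1. preprocess single-channel EEG (notch + band-pass, 5 s windows);
2. extract a 46-dimensional hybrid feature vector per window;
3. convert the recorded `Cet` to `Ceff` labels at the window centers;
4. regress `Ceff` from the feature sequence with a sparse denoising
   autoencoder (SDAE) stacked onto an LSTM;
5. score any candidate index with the prediction probability `Pk`.

## Preprocessing

`notch_filter()` removes mains interference with a second-order Butterworth
band-stop (±1 Hz around the mains frequency) applied forward-backward
(`signal::filtfilt`), so filtering is zero-phase and window centers stay
aligned with the concentration time base. `bandpass_filter()` cascades
sixth-order Butterworth high-pass (0.8 Hz, removing drift) and low-pass
(50 Hz) sections, also zero-phase. A Butterworth edge exactly at the Nyquist
frequency is ill-posed, so when the upper edge reaches Nyquist (a 50 Hz edge
at 100 Hz sampling) it is clamped to `0.99 * fs / 2` with a warning; at
100 Hz sampling the notch is skipped entirely (50 Hz *is* Nyquist) with a
message. `window_eeg()` slices the record into non-overlapping 500-sample
(5 s at 100 Hz) analysis windows.

## The 46 hybrid features

`extract_features()` computes, per window and in this fixed column order
(`feature_names()`):

1. **40 half-Hz spectral bins** over 30–50 Hz (`spec_30.0Hz` …
   `spec_49.5Hz`): a Hann-windowed one-sided periodogram is aggregated into
   `[f, f + 0.5)` Hz bins. High-gamma power collapses as anesthesia deepens,
   and its fine spectral profile carries subject-specific information.
2. **Two band means** (`spec_mean_30_47`, `spec_mean_47_50`): means of the
   constituent half-Hz bins over 30–47 Hz and 47–50 Hz.
3. **Permutation entropy** (`peen`): normalized Shannon entropy of
   ordinal-pattern frequencies of delay vectors, order `m = 4`, delay
   `tau = 1`; ties ranked stably by position. 0 for a monotone window, 1
   when all `4! = 24` patterns are equiprobable; invariant under strictly
   increasing transforms of the signal.
4. **Sample entropy** (`sampen`): negative log conditional probability that
   templates matching for `m = 2` points (Chebyshev distance within
   `r = 0.2 * SD`, self-matches excluded) also match for `m + 1`; templates
   `i = 1..N-m` at both lengths so the normalizing counts cancel. A constant
   window returns 0; if no template pair matches, the largest representable
   finite value is returned with a warning.
5. **Wavelet entropy** (`wavent`): Shannon entropy (natural log) of the
   relative wavelet energies of a 5-level periodized db4 decomposition
   (implemented in `R/dwt.R`; the convention matches the standard
   periodized DWT, verified against an independent implementation in the
   test suite).
6. **Alpha-ratio** (`alpha_ratio`): `log10(E[30, 42.5) / E[6, 12))`. The
   high band collapses faster than the alpha band with depth, so the ratio
   falls monotonically.

Each per-feature time series is then denoised with `smooth_feature_track()`:
the track is extended by reflection, decomposed with a level-3 db4 DWT, and
its detail coefficients soft-thresholded with the universal threshold
`sigma * sqrt(2 log n)`, `sigma = median(|d|) / 0.6745`. This suppresses
window-to-window estimation noise while leaving the slow, drug-driven trend
intact.

## PK/PD: labels

`effect_site()` integrates the effect-compartment ODE with an update that is
exact for piecewise-linear `Cet` (the form in which end-tidal data are
recorded), so no step-size tuning is involved. The default `keo = 1.0` 1/min
gives an equilibration time constant of one minute, a mid-range value for
volatile agents; it is a parameter of `session_spec()`/`effect_site()` and
not hard-coded. `align_labels()` interpolates `Ceff` at the window centers.
`emax_effect()` provides the standard inhibitory sigmoid Emax curve
(`emax = 100`, `emin = 0`, `ec50 = 1.5` vol %, `gamma = 2` defaults) for
mapping concentrations onto a bounded 0–100 display scale, with
`emax_inverse()` as its exact inverse.

## The SDAE-LSTM regressor

`train_network()` fits a 46–92–12–18–1 network:

- **SDAE front end.** Two denoising autoencoders (sigmoid encoders
  46→92 and 92→12, linear decoders) are pretrained greedily: inputs are
  corrupted by masking each element to zero with probability 0.3
  (`corrupt()`), the clean input is reconstructed under squared loss, a
  KL-divergence sparsity penalty holds mean hidden activations near
  `rho = 0.05` (weight 0.1), and weights carry an L2 penalty (1e-4).
- **LSTM.** The 12-dimensional encodings feed a single LSTM layer of 18
  units (standard gate equations, exposed one step at a time in
  `lstm_cell()`; forget-gate biases initialized to 1) and a linear output
  node. Training minimizes squared error against standardized `Ceff` over
  non-overlapping `seq_len`-window sequences (truncated backpropagation
  through time) drawn with a fresh random offset each epoch. The default
  `seq_len = 180` spans a full default-length session, so each gradient
  step sees the whole induction–maintenance–emergence arc; in
  cross-validated comparisons on the synthetic cohort, short truncation
  (32 windows) cost roughly 0.02 of held-out `Pk`.
- **Fine-tuning.** Encoders, LSTM and output head are then trained jointly
  end to end at a lower learning rate.

Optimization uses Adam (learning rates 0.01 and 0.003 for fine-tuning) with
L2 weight decay as the regularizer; each LSTM/fine-tuning epoch is one
full-batch Adam step over all training sequences (the sequence count is
small), while pretraining iterates minibatches of 64. Features and labels
are z-scored internally; the statistics are stored in the fitted object and
inverted at prediction, so `predict()` returns an index on the `Ceff` scale
that *increases* with depth. Defaults (`network_spec()`): 30 pretraining,
200 LSTM, and 100 fine-tuning epochs, `seq_len = 180`, seeded and fully
reproducible. Analytic gradients (hand-derived BPTT, with an
RcppArmadillo kernel for speed and a pure-R reference implementation) are
verified against finite differences in the test suite. `use_sdae = FALSE`
trains the same LSTM on the raw standardized features — the ablation
baseline.

`predict()` streams a session's windows, in temporal order, through the
encoders and the LSTM from a zero initial state and returns the raw network
output per window; no post-hoc smoothing is applied to the index (its input
feature tracks are already denoised).

## Evaluation: prediction probability

`pk_statistic()` implements the concordance measure standard in DoA
validation: over all unordered observation pairs with distinct depth,

$$P_k = \frac{P_c + P_{tx}/2}{P_c + P_d + P_{tx}},$$

where `Pc`, `Pd`, `Ptx` are the probabilities of concordance, discordance
and index-only ties. `Pk = 1` means the index orders every pair as `Ceff`
does; 0.5 is chance. Values below 0.5 are reflected to `1 - Pk` (entropies
correlate *negatively* with depth). Pairs are enumerated exhaustively —
with 5 s windows the per-subject window count is small — and pairs tied in
depth are excluded by construction. Index ties are exact by default
(`tie_tol = 0`, configurable). `baseline_pk()` scores one raw (smoothed)
feature column; `loso_cv()` runs the leave-one-subject-out protocol: each
subject in turn is held out, the network is trained on the remaining
subjects (order shuffled, fold-specific seeds), and the held-out index is
scored against that subject's `Ceff`.

## The synthetic study

No clinical recordings ship with the package; `simulate_session()` and
`simulate_cohort()` generate a controlled stand-in whose construction
mirrors the qualitative EEG pharmacology above. Each session (defaults:
900 s at 100 Hz) follows an induction–maintenance–emergence end-tidal
profile — 3 vol % for one minute, a climb to 7 vol % by 180 s, maintenance
to 600 s, washout to 0 — passed through `effect_site()`. The EEG is a sum
of band-limited noise components whose amplitudes are logistic functions of
`Ceff`:

| component | band (Hz) | awake amplitude (µV) | deep amplitude (µV) |
|-----------|-----------|----------------------|---------------------|
| delta     | 0.8–4     | 8                    | 35                  |
| alpha     | 8–12      | 12                   | 6                   |
| beta      | 13–30     | 10                   | 2                   |
| gamma     | 30–47     | 9                    | 0.8                 |

plus 1 µV white measurement noise, clipped at ±300 µV. Slow-wave power
grows while fast activity collapses, so sample entropy, permutation
entropy, high-band power and the alpha-ratio all fall monotonically with
`Ceff` — the depth–EEG relation the features are designed to read out.

The logistic transition is centered at `depth_ec50 = 3.0` vol % with width
`depth_width = 1.2` vol %: the midpoint is half the peak end-tidal
concentration of the default profile and the width about one sixth of the
traversed range, so the EEG response is graded over the whole session
rather than saturating early. `simulate_cohort()` jitters `keo`,
`depth_ec50` and the noise level per subject by a uniform ±20% with
deterministic child seeds, giving reproducible inter-subject variability.

The generator is deliberately idealized: it produces stationary band-limited
noise modulated by depth and does **not** emulate burst suppression,
movement or electrode artifacts, ocular activity, or drug-specific
waveforms. Conclusions from it speak to the correctness of the pipeline,
not to clinical performance.

## Problem sizes and reproducibility

Validation problem sizes are chosen to keep the full test suite within a
desk-scale CPU budget while remaining statistically meaningful; they are
this package's own choices:

- cross-validation study: 20 synthetic subjects at generator defaults
  (900 s → 180 windows each), leave-one-subject-out, repeated over 5
  training seeds (100 folds);
- single-feature baselines and the SDAE-vs-plain-LSTM ablation on the same
  cohorts (the ablation on a 6-subject cohort over 3 seeds);
- entropy, Pk, DWT, gradient and PK/PD oracles at window scale (see
  `tests/testthat/`).

Every stochastic step — session synthesis, cohort jitter, weight
initialization, corruption masks, sequence offsets, fold shuffling — is
driven by explicit seeds, so all reported numbers are exactly reproducible.

## Limitations

- The regression target is `Ceff`, not a clinical depth score; systematic
  nonlinearity between `Ceff` and behavioral depth is outside the model.
- The network is small and CPU-trained by design; no hyperparameter search
  is performed, and the defaults are declared, not tuned.
- Only the `db4` wavelet is implemented for the DWT-based features.
- EDF import is not provided; records are exchanged as delimited text.
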
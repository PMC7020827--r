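# Synthetic anesthesia sessions: an end-tidal sevoflurane profile, its
# first-order effect-site transform, and EEG whose spectral content and
# irregularity fall monotonically with effect-site concentration. Stands in
# for clinical recordings so the full pipeline is testable end to end.

.default_cet_profile <- function() {
  # induction (3% for 2 min, then 7%), maintenance, washout
  data.frame(time_s = c(0, 60, 180, 600, 900),
             vol = c(0, 3, 7, 7, 0))
}

# Each EEG component: a frequency band (noise mode) or a pure tone (sine
# mode) whose amplitude follows a logistic function of effect-site
# concentration. Slow delta activity grows with depth; alpha, beta and gamma
# shrink, which drives both entropies and high-band power downward.
.default_components <- function() {
  list(
    list(name = "delta", mode = "noise", band = c(0.8, 4),  a_awake = 8,  a_deep = 35),
    list(name = "alpha", mode = "noise", band = c(8, 12),   a_awake = 12, a_deep = 6),
    list(name = "beta",  mode = "noise", band = c(13, 30),  a_awake = 10, a_deep = 2),
    list(name = "gamma", mode = "noise", band = c(30, 47),  a_awake = 9,  a_deep = 0.8)
  )
}

#' Synthetic anesthesia-session specification
#'
#' Parameters of one simulated induction-maintenance-emergence session. The
#' defaults emulate a sevoflurane induction protocol: 3 vol% for two
#' minutes, a step to 7 vol%, maintenance, then washout, over a 900 s
#' session sampled at 100 Hz.
#'
#' @param duration_s session length in seconds.
#' @param fs sampling rate in Hz for EEG and concentration series.
#' @param keo effect-compartment rate constant, 1/min.
#' @param cet_profile data frame of piecewise-linear breakpoints with
#'   columns `time_s` (strictly increasing, within `[0, duration_s]`) and
#'   `vol` (vol %, non-negative).
#' @param noise_sd additive white measurement-noise SD in microvolts.
#' @param depth_ec50 effect-site concentration (vol %) at which each EEG
#'   component's amplitude is halfway between its awake and deep values;
#'   the default sits at half the peak end-tidal concentration of the
#'   default profile, so the EEG transition spans the concentrations the
#'   session actually traverses.
#' @param depth_width logistic transition width in vol %; the default of
#'   roughly one sixth of the traversed concentration range keeps the
#'   amplitude response graded (rather than switch-like) across the whole
#'   induction-maintenance-emergence trajectory.
#' @param components list of oscillatory components (see package vignette);
#'   each has a `mode` (`"noise"` for band-limited noise, `"sine"` for a
#'   pure tone with `freq`), a band or frequency, and awake/deep amplitudes
#'   in microvolts.
#' @param amp_ceiling EEG amplitude ceiling in microvolts (samples are
#'   clipped).
#' @param seed integer random seed making the session reproducible.
#' @return a `session_spec` object.
#' @export
session_spec <- function(duration_s = 900, fs = 100, keo = 1.0,
                         cet_profile = .default_cet_profile(),
                         noise_sd = 1.0, depth_ec50 = 3.0, depth_width = 1.2,
                         components = .default_components(),
                         amp_ceiling = 300, seed = 1L) {
  stopifnot(duration_s > 0, fs > 0, keo > 0, noise_sd >= 0,
            depth_ec50 > 0, depth_width > 0, amp_ceiling > 0)
  stopifnot(is.data.frame(cet_profile),
            all(c("time_s", "vol") %in% names(cet_profile)))
  if (nrow(cet_profile) > 1L && any(diff(cet_profile$time_s) <= 0)) {
    stop("cet_profile times must be strictly increasing", call. = FALSE)
  }
  if (any(cet_profile$time_s < 0) || any(cet_profile$time_s > duration_s)) {
    stop("cet_profile times must lie within [0, duration_s]", call. = FALSE)
  }
  if (any(cet_profile$vol < 0)) {
    stop("cet_profile concentrations must be non-negative", call. = FALSE)
  }
  structure(list(duration_s = duration_s, fs = fs, keo = keo,
                 cet_profile = cet_profile, noise_sd = noise_sd,
                 depth_ec50 = depth_ec50, depth_width = depth_width,
                 components = components, amp_ceiling = amp_ceiling,
                 seed = as.integer(seed)),
            class = "session_spec")
}

#' End-tidal concentration profile of a session
#'
#' Piecewise-linear interpolation of the specification's breakpoints onto
#' the full session time base; held constant beyond the last breakpoint.
#'
#' @param spec a [session_spec()].
#' @return an end-tidal [concentration_series()].
#' @export
make_cet_profile <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  t <- seq(0, spec$duration_s - 1 / spec$fs, by = 1 / spec$fs)
  bp <- spec$cet_profile
  c_out <- if (nrow(bp) == 1L) {
    rep(bp$vol, length(t))
  } else {
    stats::approx(bp$time_s, bp$vol, xout = t, rule = 2)$y
  }
  concentration_series(t, pmax(c_out, 0), kind = "end_tidal")
}

# logistic amplitude of one component at concentration c
.component_amp <- function(comp, ceff, ec50, width) {
  comp$a_awake + (comp$a_deep - comp$a_awake) * stats::plogis((ceff - ec50) / width)
}

#' Synthesize concentration-dependent EEG
#'
#' Generates single-channel EEG as a sum of band-limited oscillatory
#' components plus white noise. Each component's instantaneous amplitude is
#' a logistic function of the effect-site concentration: slow-wave (delta)
#' amplitude grows with depth while alpha, beta and gamma amplitudes shrink,
#' so high-frequency (30-50 Hz) relative power, sample entropy and
#' permutation entropy all fall as the drug takes effect. Deterministic
#' given `spec$seed`.
#'
#' @param ceff effect-site [concentration_series()] covering the session.
#' @param spec a [session_spec()].
#' @return an [eeg_record()] of `round(duration_s * fs)` samples.
#' @export
synthesize_eeg <- function(ceff, spec) {
  stopifnot(inherits(ceff, "conc_series"), inherits(spec, "session_spec"))
  n <- round(spec$duration_s * spec$fs)
  if (length(ceff$t) < 2L || max(ceff$t) < (n - 1) / spec$fs - 1e-9) {
    stop("ceff does not cover the session duration", call. = FALSE)
  }
  t <- seq(0, n - 1) / spec$fs
  cefft <- stats::approx(ceff$t, ceff$c, xout = t, rule = 2)$y
  set.seed(spec$seed)
  nyq <- spec$fs / 2
  x <- numeric(n)
  for (comp in spec$components) {
    amp <- .component_amp(comp, cefft, spec$depth_ec50, spec$depth_width)
    if (identical(comp$mode, "sine")) {
      carrier <- sin(2 * pi * comp$freq * t)
    } else {
      band <- pmin(comp$band, 0.99 * nyq)
      bf <- signal::butter(4, band / nyq, type = "pass")
      carrier <- signal::filtfilt(bf, stats::rnorm(n))
      carrier <- carrier / stats::sd(carrier)   # unit-RMS band process
    }
    x <- x + amp * carrier
  }
  if (spec$noise_sd > 0) x <- x + stats::rnorm(n, sd = spec$noise_sd)
  x <- pmin(pmax(x, -spec$amp_ceiling), spec$amp_ceiling)
  eeg_record(x, spec$fs)
}

#' Simulate one complete synthetic session
#'
#' Chains [make_cet_profile()], [effect_site()] and [synthesize_eeg()].
#'
#' @param spec a [session_spec()].
#' @param subject_id optional subject label attached to the EEG record.
#' @return a `synthetic_session`: list with `eeg`, `cet`, `ceff`, `spec`.
#' @export
simulate_session <- function(spec = session_spec(), subject_id = NULL) {
  cet <- make_cet_profile(spec)
  ceff <- effect_site(cet, keo = spec$keo)
  eeg <- synthesize_eeg(ceff, spec)
  eeg$subject_id <- subject_id
  structure(list(eeg = eeg, cet = cet, ceff = ceff, spec = spec,
                 subject_id = subject_id),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session>%s %g s @ %g Hz, Cet peak %.2f vol%%\n",
              if (is.null(x$subject_id)) "" else paste0(" ", x$subject_id),
              x$spec$duration_s, x$spec$fs, max(x$cet$c)))
  invisible(x)
}

#' Simulate a cohort of synthetic subjects
#'
#' Draws per-subject variations of the base specification (keo, the
#' depth-response midpoint and the noise level each jittered by a uniform
#' +/-20%) with deterministic per-subject child seeds, so two cohorts built
#' from the same master seed are identical element-wise.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param base_spec the shared [session_spec()].
#' @param seed master seed.
#' @param jitter relative half-width of the parameter jitter, default 0.2.
#' @return list of `synthetic_session` objects with ids `"S01"`, `"S02"`, ...
#' @export
simulate_cohort <- function(n_subjects, base_spec = session_spec(), seed = 1L,
                            jitter = 0.2) {
  stopifnot(n_subjects >= 1L, jitter >= 0, jitter < 1)
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max, n_subjects)
  jit <- matrix(stats::runif(3L * n_subjects, 1 - jitter, 1 + jitter),
                n_subjects, 3L)
  lapply(seq_len(n_subjects), function(i) {
    sp <- base_spec
    sp$keo <- base_spec$keo * jit[i, 1L]
    sp$depth_ec50 <- base_spec$depth_ec50 * jit[i, 2L]
    sp$noise_sd <- base_spec$noise_sd * jit[i, 3L]
    sp$seed <- child_seeds[i]
    simulate_session(sp, subject_id = sprintf("S%02d", i))
  })
}
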
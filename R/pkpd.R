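# Effect-compartment pharmacokinetics and the inhibitory sigmoid Emax
# concentration-response curve. Effect-site concentration is the regression
# label for the depth-of-anesthesia network; the Emax curve is used for
# index visualization and by the synthetic-session generator.

#' Time-stamped anesthetic concentration series
#'
#' @param t times in seconds, strictly increasing.
#' @param c concentrations in vol %, non-negative.
#' @param kind `"end_tidal"` (measured exhaled concentration) or
#'   `"effect_site"` (modeled concentration at the neural site of action).
#' @return a `conc_series` object.
#' @export
concentration_series <- function(t, c, kind = c("end_tidal", "effect_site")) {
  kind <- match.arg(kind)
  stopifnot(length(t) == length(c), length(t) >= 1L)
  if (any(diff(t) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(t)) || any(!is.finite(c))) {
    stop("times and concentrations must be finite", call. = FALSE)
  }
  if (any(c < 0)) stop("concentrations must be non-negative", call. = FALSE)
  structure(list(t = as.numeric(t), c = as.numeric(c), kind = kind),
            class = "conc_series")
}

#' @export
print.conc_series <- function(x, ...) {
  cat(sprintf("<conc_series> %s, %d points over [%g, %g] s, range %.3g-%.3g vol%%\n",
              x$kind, length(x$t), min(x$t), max(x$t), min(x$c), max(x$c)))
  invisible(x)
}

#' Effect-site concentration from end-tidal concentration
#'
#' Integrates the classical first-order effect-compartment model
#' `dCeff/dt = keo * (Cet - Ceff)` on the input time base. Within each step
#' `Cet` is taken as linear, for which the ODE has a closed-form exponential
#' update; the scheme is unconditionally stable and exact for piecewise-
#' linear input. The output lags the input: for a concentration step from 0
#' the response is `c * (1 - exp(-keo * t))`.
#'
#' @param cet end-tidal [concentration_series()].
#' @param keo effect-compartment rate constant in 1/min (default 1.0).
#' @param ceff0 initial effect-site concentration; defaults to `Cet(0)`
#'   (0 for an awake patient whose profile starts at zero).
#' @return effect-site `conc_series` on the same time base.
#' @export
effect_site <- function(cet, keo = 1.0, ceff0 = NULL) {
  stopifnot(inherits(cet, "conc_series"), keo > 0)
  k <- keo / 60                          # per-second rate
  t <- cet$t; u <- cet$c
  n <- length(t)
  y <- numeric(n)
  y[1] <- if (is.null(ceff0)) u[1] else ceff0
  if (n > 1L) {
    dt <- diff(t)
    b <- diff(u) / dt                    # Cet slope within each step
    ek <- exp(-k * dt)
    for (i in seq_len(n - 1L)) {
      a <- u[i]
      # exact solution of y' = k(a + b*s - y) over s in [0, dt]
      y[i + 1L] <- a + b[i] * dt[i] - b[i] / k +
        (y[i] - a + b[i] / k) * ek[i]
    }
  }
  concentration_series(t, pmax(y, 0), kind = "effect_site")
}

#' Inhibitory sigmoid Emax concentration-response curve
#'
#' Maps effect-site concentration to a nominal effect index:
#' `Effect = emax - (emax - emin) * ceff^gamma / (ec50^gamma + ceff^gamma)`.
#' The curve starts at `emax` with no drug, passes through
#' `(emax + emin) / 2` at `ceff = ec50`, and saturates at `emin`; it is
#' strictly decreasing in `ceff` for `gamma > 0`.
#'
#' @param ceff effect-site concentration(s), vol %, non-negative.
#' @param emax,emin maximum (awake) and minimum (deep) effect values.
#' @param ec50 concentration producing 50% of the maximum effect, vol %.
#' @param gamma slope of the concentration-response relationship.
#' @return effect values in `[emin, emax]`, same length as `ceff`.
#' @export
emax_effect <- function(ceff, emax = 100, emin = 0, ec50 = 1.5, gamma = 2) {
  stopifnot(emax > emin, ec50 > 0, gamma > 0)
  if (any(ceff < 0)) stop("ceff must be non-negative", call. = FALSE)
  cg <- (ceff / ec50)^gamma
  emax - (emax - emin) * cg / (1 + cg)
}

#' Invert the sigmoid Emax curve
#'
#' Recovers the effect-site concentration producing a given effect strictly
#' inside `(emin, emax)`.
#'
#' @param effect effect values strictly between `emin` and `emax`.
#' @inheritParams emax_effect
#' @return concentrations in vol %.
#' @export
emax_inverse <- function(effect, emax = 100, emin = 0, ec50 = 1.5, gamma = 2) {
  stopifnot(emax > emin, ec50 > 0, gamma > 0)
  if (any(effect <= emin) || any(effect >= emax)) {
    stop("effect must lie strictly inside (emin, emax)", call. = FALSE)
  }
  frac <- (emax - effect) / (emax - emin)
  ec50 * (frac / (1 - frac))^(1 / gamma)
}

#' Align effect-site labels to feature windows
#'
#' Linearly interpolates an effect-site concentration series at the feature
#' windows' center times, producing the per-window regression labels.
#'
#' @param features a `doa_features` object from [assemble_features()].
#' @param ceff effect-site [concentration_series()] spanning all window
#'   centers.
#' @return numeric label vector, one value per window.
#' @export
align_labels <- function(features, ceff) {
  stopifnot(inherits(features, "doa_features"), inherits(ceff, "conc_series"))
  ctr <- features$centers_s
  if (min(ctr) < min(ceff$t) || max(ctr) > max(ceff$t)) {
    stop("window centers fall outside the concentration series span", call. = FALSE)
  }
  stats::approx(ceff$t, ceff$c, xout = ctr)$y
}
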
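# SAFE-style peripheral nerve stimulation supervision: filter-rectify-weight
# surrogate for the nerve membrane response to gradient switching, plus the
# amplitude-versus-rise-time operating curve.

#' Gradient waveform on a uniform raster
#'
#' @param samples numeric vector (one axis) or matrix with one column per
#'   gradient axis, amplitudes in mT/m.
#' @param raster_us sample spacing in microseconds.
#' @return object of class `gradient_waveform`.
#' @export
gradient_waveform <- function(samples, raster_us = 10) {
  if (raster_us <= 0) stop("raster_us must be positive")
  m <- as.matrix(samples)
  if (!all(is.finite(m))) stop("waveform samples must be finite")
  structure(list(samples = m, raster_us = raster_us),
            class = "gradient_waveform")
}

#' Single trapezoid waveform
#'
#' @param amplitude_mT_per_m plateau amplitude.
#' @param ramp_ms,flat_ms ramp and flat durations.
#' @param raster_us raster.
#' @param pad_ms zero padding appended on both sides.
#' @return a [gradient_waveform()].
#' @export
trapezoid_waveform <- function(amplitude_mT_per_m, ramp_ms, flat_ms = 0,
                               raster_us = 10, pad_ms = 2) {
  dt <- raster_us / 1000
  t_up <- seq(0, ramp_ms, by = dt)
  up <- amplitude_mT_per_m * t_up / max(ramp_ms, dt)
  flat <- rep(amplitude_mT_per_m, max(0, round(flat_ms / dt)))
  pad <- rep(0, round(pad_ms / dt))
  gradient_waveform(c(pad, up, flat, rev(up), pad), raster_us)
}

#' Bipolar EPI readout gradient train
#'
#' Alternating readout lobes at `+/- amplitude`, one lobe per echo spacing.
#' The polarity transition ramps through `2 * amplitude` at the given slew
#' rate; when the ramp fills the whole echo spacing the train degenerates to
#' a triangle wave (e.g. 98 mT/m at 213 T/m/s with ES 0.92 ms).
#'
#' @param amplitude_mT_per_m lobe amplitude.
#' @param slew_T_per_m_per_s slew rate used on the transitions.
#' @param es_ms echo spacing (one lobe duration).
#' @param n_echoes number of lobes.
#' @param raster_us raster.
#' @return a [gradient_waveform()] (single axis).
#' @export
bipolar_readout_waveform <- function(amplitude_mT_per_m, slew_T_per_m_per_s,
                                     es_ms, n_echoes = 16, raster_us = 10) {
  a <- amplitude_mT_per_m
  ramp <- 2 * a / slew_T_per_m_per_s # ms, full polarity swing
  if (ramp > es_ms * 1.02)
    stop("slew rate too low to alternate polarity within one echo spacing")
  ramp <- min(ramp, es_ms) # rounded inputs: degenerate to a pure triangle
  dt <- raster_us / 1000
  t <- seq(0, n_echoes * es_ms, by = dt)
  # phase within a 2*ES period: up-ramp, +flat, down-ramp, -flat; start at
  # the zero crossing of the first up-ramp so the train begins at 0
  ph <- (t + ramp / 2) %% (2 * es_ms)
  g <- ifelse(ph < ramp, -a + slew_T_per_m_per_s * ph,
       ifelse(ph < es_ms, a,
       ifelse(ph < es_ms + ramp, a - slew_T_per_m_per_s * (ph - es_ms), -a)))
  # ramp the final plateau back to zero at the same slew rate
  g_end <- g[length(g)]
  n_out <- ceiling(abs(g_end) / (slew_T_per_m_per_s * dt))
  ramp_out <- g_end * (1 - seq_len(n_out) / n_out)
  pad <- rep(0, round(2 / dt))
  gradient_waveform(c(pad, g, ramp_out, pad), raster_us)
}

#' SAFE supervision parameters
#'
#' A chain of parallel first-order low-pass filters applied to the rectified
#' gradient slew, mimicking fast and slow components of the nerve membrane
#' response; the weighted sum, scaled by `scale`, is the stimulation signal
#' in units of the first-level ceiling Stimlim.  The defaults are a
#' synthetic calibration (the scanner's fitted constants are not public):
#' weights sum to 1 and `scale = 1/240 (mT/m/ms)^-1`, so a sustained slew of
#' 240 T/m/s sits exactly at Stimlim.  Normal operating mode is capped at
#' `0.8 * Stimlim`.
#'
#' @param tau_ms filter time constants.
#' @param weights filter weights (same length as `tau_ms`).
#' @param scale stimulation per unit steady slew, 1/(mT/m/ms).
#' @param stim_limit first-level ceiling (dimensionless; 1 by convention).
#' @param normal_mode_fraction normal-mode cap as a fraction of Stimlim.
#' @return object of class `safe_params`.
#' @export
safe_params <- function(tau_ms = c(0.12, 0.6, 3.0),
                        weights = c(0.6, 0.3, 0.1),
                        scale = 1 / 240, stim_limit = 1,
                        normal_mode_fraction = 0.8) {
  if (length(tau_ms) != length(weights))
    stop("tau_ms and weights must have equal length")
  if (any(tau_ms <= 0) || any(weights <= 0))
    stop("time constants and weights must be positive")
  if (normal_mode_fraction != 0.8)
    stop("normal_mode_fraction is fixed at 0.8 (IEC normal mode)")
  structure(list(tau_ms = tau_ms, weights = weights, scale = scale,
                 stim_limit = stim_limit,
                 normal_mode_fraction = normal_mode_fraction),
            class = "safe_params")
}

# first-order low-pass of x (uniform raster dt) with time constant tau
.lp1 <- function(x, dt, tau) {
  a <- exp(-dt / tau)
  stats::filter(x * (1 - a), filter = a, method = "recursive")
}

#' SAFE stimulation response of a gradient waveform
#'
#' Per axis the waveform is differentiated to slew, rectified, passed
#' through the weighted low-pass chain and scaled; axes combine by
#' root-sum-square and the time-maximum is returned as a fraction of
#' Stimlim.  The response is positively homogeneous
#' (`response(a*w) = a*response(w)` for `a > 0`) and invariant to time
#' shifts of a zero-padded waveform.
#'
#' @param w a [gradient_waveform()].
#' @param p a [safe_params()].
#' @return maximum stimulation as a fraction of Stimlim, with attributes
#'   `allowed_first_level` (<= 1) and `allowed_normal_mode` (<= 0.8).
#' @export
safe_response <- function(w, p = safe_params()) {
  stopifnot(inherits(w, "gradient_waveform"), inherits(p, "safe_params"))
  dt <- w$raster_us / 1000
  s2 <- 0
  for (ax in seq_len(ncol(w$samples))) {
    slew <- abs(diff(w$samples[, ax])) / dt # mT/m/ms, rectified
    resp <- 0
    for (k in seq_along(p$tau_ms))
      resp <- resp + p$weights[k] * .lp1(slew, dt, p$tau_ms[k])
    s2 <- s2 + (p$scale * resp)^2
  }
  frac <- max(sqrt(s2)) / p$stim_limit
  structure(frac,
            allowed_first_level = frac <= 1,
            allowed_normal_mode = frac <= p$normal_mode_fraction)
}

#' PNS operating curve: allowed amplitude versus rise time
#'
#' For each rise time, bisects the amplitude of a bipolar trapezoid train
#' (flat top equal to the rise time) until the SAFE response reaches the
#' normal-mode limit `0.8 * Stimlim`; slow ramps stimulate less, so the
#' curve is non-decreasing in rise time.  When a coil is supplied the
#' amplitude is additionally capped at its absolute limit and the implied
#' slew at its slew limit.
#'
#' @param p a [safe_params()].
#' @param rise_times_ms vector of rise times.
#' @param coil optional [gradient_coil()] providing hard amplitude/slew caps.
#' @param n_echoes lobes in the probe train.
#' @param raster_us raster.
#' @return data.frame with `rise_time_ms`, `max_amplitude_mT_per_m`,
#'   `limited_by` (`"pns"`, `"amplitude"` or `"slew"`).
#' @export
operating_curve <- function(p = safe_params(), rise_times_ms,
                            coil = NULL, n_echoes = 8, raster_us = 10) {
  if (any(rise_times_ms <= 0)) stop("rise times must be positive")
  rows <- lapply(rise_times_ms, function(rt) {
    resp_at <- function(a) {
      slew <- 2 * a / rt
      wv <- bipolar_readout_waveform(a, slew, es_ms = 2 * rt,
                                     n_echoes = n_echoes,
                                     raster_us = raster_us)
      as.numeric(safe_response(wv, p))
    }
    a_cap <- Inf
    lim <- "pns"
    if (!is.null(coil)) {
      a_cap <- min(coil$g_abs_max, coil$sr_max * rt / 2)
      lim <- if (coil$g_abs_max < coil$sr_max * rt / 2) "amplitude" else "slew"
    }
    hi <- min(a_cap, 1000)
    if (resp_at(hi) <= p$normal_mode_fraction) {
      a <- hi
    } else {
      lo <- 0
      for (i in 1:60) {
        mid <- (lo + hi) / 2
        if (resp_at(mid) > p$normal_mode_fraction) hi <- mid else lo <- mid
      }
      a <- lo
      lim <- "pns"
    }
    data.frame(rise_time_ms = rt, max_amplitude_mT_per_m = a,
               limited_by = lim)
  })
  do.call(rbind, rows)
}
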
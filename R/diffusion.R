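# Stejskal-Tanner diffusion-encoding timing for monopolar trapezoidal
# pulsed-gradient spin echo (PGSE).

#' PGSE pulse parameters
#'
#' `delta_ms` is the conventional lobe duration (flat top plus one ramp, so
#' the lobe area is `G * delta`), `Delta_ms` the leading-edge separation of
#' the two lobes, `ramp_ms` the rise time.
#'
#' @param g_amp_mT_per_m gradient amplitude G.
#' @param delta_ms lobe duration (flat + ramp).
#' @param Delta_ms lobe separation; must be >= `delta_ms`.
#' @param ramp_ms rise time; must be <= `delta_ms`.
#' @return object of class `pgse_params` including the computed `b_s_per_mm2`.
#' @export
pgse_params <- function(g_amp_mT_per_m, delta_ms, Delta_ms, ramp_ms = 0) {
  if (Delta_ms < delta_ms) stop("Delta must be >= delta")
  if (ramp_ms < 0 || ramp_ms > delta_ms)
    stop("ramp must lie in [0, delta]")
  p <- structure(list(g_amp = g_amp_mT_per_m, delta_ms = delta_ms,
                      Delta_ms = Delta_ms, ramp_ms = ramp_ms,
                      gamma = GAMMA_RAD_PER_S_T),
                 class = "pgse_params")
  p$b_s_per_mm2 <- b_value(p)
  p
}

#' Stejskal-Tanner b-value of a trapezoidal PGSE pair
#'
#' For rectangular lobes `b = gamma^2 G^2 delta^2 (Delta - delta/3)`; finite
#' ramps of duration `eps` contribute the standard correction
#' `+ eps^3/30 - delta eps^2/6`.  At constant b this implies the `b = G^2
#' t^3` scaling: raising G by a factor `a` shortens the encoding time by
#' `a^(-2/3)` (see [encoding_time_factor()]).
#'
#' @param params a [pgse_params()] object, or amplitude in mT/m when the
#'   remaining arguments are given.
#' @param delta_ms,Delta_ms,ramp_ms timing, ms (used when `params` is
#'   numeric).
#' @return b-value in s/mm^2.
#' @examples
#' b_value(200, delta_ms = 17.4, Delta_ms = 17.4) # ~10,000 s/mm^2
#' @export
b_value <- function(params, delta_ms = NULL, Delta_ms = NULL, ramp_ms = 0) {
  if (is.numeric(params)) {
    if (Delta_ms < delta_ms) stop("Delta must be >= delta")
    g <- params
  } else {
    g <- params$g_amp; delta_ms <- params$delta_ms
    Delta_ms <- params$Delta_ms; ramp_ms <- params$ramp_ms
  }
  g_si <- g * 1e-3          # T/m
  d <- delta_ms * 1e-3      # s
  D <- Delta_ms * 1e-3
  e <- ramp_ms * 1e-3
  b_si <- GAMMA_RAD_PER_S_T^2 * g_si^2 *
    (d^2 * (D - d / 3) + e^3 / 30 - d * e^2 / 6)
  b_si * 1e-6               # s/m^2 -> s/mm^2
}

#' Encoding-time scaling with gradient amplitude
#'
#' From `b = G^2 t^3` at constant b, an amplitude improvement by `g_ratio`
#' shortens the diffusion encoding time by `g_ratio^(-2/3)`; a 2.5x
#' amplitude gain (80 to 200 mT/m) gives a 0.54x encoding time.
#'
#' @param g_ratio amplitude ratio (> 0).
#' @return encoding-time factor.
#' @examples
#' encoding_time_factor(2.5) # ~0.543
#' @export
encoding_time_factor <- function(g_ratio) {
  stopifnot(g_ratio > 0)
  g_ratio^(-2 / 3)
}

#' Minimum spin-echo TE reaching a target b-value
#'
#' Places symmetric trapezoidal lobes at the coil's absolute amplitude limit
#' tightly around the refocusing pulse (`Delta = delta + ramp + refocus`)
#' and solves for the smallest lobe duration reaching `b_target` by
#' bisection.  The echo must sit at twice the refocusing-pulse centre, so
#' `TE = refocus + 2 (delta + ramp) + 2 readout_to_center`, where
#' `readout_to_center` is the pre-echo part of the EPI readout (mirrored on
#' the excitation side by construction).
#'
#' @param b_target_s_per_mm2 target b-value.
#' @param coil a [gradient_coil()]; lobes run at `g_abs_max` (diffusion
#'   encoding is low duty cycle).
#' @param readout_to_center_ms pre-echo readout duration, ms (default 8).
#' @param refocus_ms refocusing-pulse duration including crushers, ms
#'   (default 7).
#' @return list with `params` (a [pgse_params()]) and `te_ms`; also
#'   `encoding_ms = 2 (delta + ramp)`, the overhead-free encoding time.
#' @examples
#' min_te_pgse(10000, load_coil_preset("impulse"))$te_ms
#' @export
min_te_pgse <- function(b_target_s_per_mm2, coil, readout_to_center_ms = 8,
                        refocus_ms = 7) {
  stopifnot(inherits(coil, "gradient_coil"))
  if (b_target_s_per_mm2 <= 0) stop("b_target must be positive")
  g <- coil$g_abs_max
  ramp <- g / coil$sr_max
  b_of <- function(delta) {
    b_value(g, delta_ms = delta, Delta_ms = delta + ramp + refocus_ms,
            ramp_ms = min(ramp, delta))
  }
  lo <- ramp
  hi <- max(2 * ramp, 1)
  while (b_of(hi) < b_target_s_per_mm2) {
    hi <- hi * 2
    if (hi > 1e4) stop("infeasible geometry: b_target unreachable")
  }
  if (b_of(lo) > b_target_s_per_mm2) lo <- 1e-6
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (b_of(mid) < b_target_s_per_mm2) lo <- mid else hi <- mid
  }
  delta <- hi
  params <- pgse_params(g, delta, delta + ramp + refocus_ms,
                        ramp_ms = min(ramp, delta))
  list(params = params,
       te_ms = refocus_ms + 2 * (delta + ramp) + 2 * readout_to_center_ms,
       encoding_ms = 2 * (delta + ramp))
}
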
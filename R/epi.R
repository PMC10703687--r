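# EPI readout timing: minimum echo spacing under coil limits and forbidden
# mechanical-resonance bands, echo-train structure, minimum TE, and the
# inverse problem (finest achievable resolution at a target TE).

#' Describe an EPI acquisition protocol
#'
#' @param resolution_mm nominal in-plane resolution.
#' @param fov_mm field of view.
#' @param matrix_n matrix size (phase and read); defaults to
#'   `round(fov_mm / resolution_mm)`, and must match `fov/resolution`
#'   within one voxel.
#' @param grappa_r in-plane (GRAPPA) acceleration factor, integer >= 1.
#' @param partial_fourier fraction of phase-encode k-space acquired, in
#'   (1/2, 1]; conventional values 1, 7/8, 6/8, 5/8.
#' @param sms_factor simultaneous-multislice factor.
#' @param segments number of in-plane shots.
#' @param pe_axis label of the phase-encode axis.
#' @return an object of class `epi_protocol`.
#' @export
epi_protocol <- function(resolution_mm, fov_mm, matrix_n = NULL,
                         grappa_r = 1L, partial_fourier = 1,
                         sms_factor = 1L, segments = 1L, pe_axis = "AP") {
  if (is.null(matrix_n)) matrix_n <- round(fov_mm / resolution_mm)
  matrix_n <- as.integer(matrix_n)
  if (abs(matrix_n * resolution_mm - fov_mm) > resolution_mm)
    stop("matrix_n * resolution must equal fov within one voxel")
  if (partial_fourier <= 0.5 || partial_fourier > 1)
    stop("partial_fourier must lie in (1/2, 1]")
  if (grappa_r < 1 || segments < 1 || sms_factor < 1)
    stop("grappa_r, segments and sms_factor must be >= 1")
  structure(list(resolution_mm = resolution_mm, fov_mm = fov_mm,
                 matrix_n = matrix_n, grappa_r = as.integer(grappa_r),
                 partial_fourier = partial_fourier,
                 sms_factor = as.integer(sms_factor),
                 segments = as.integer(segments), pe_axis = pe_axis),
            class = "epi_protocol")
}

#' @export
print.epi_protocol <- function(x, ...) {
  cat(sprintf(
    "EPI protocol: %.3g mm in-plane, FOV %g mm, matrix %d, GRAPPA %d, PF %.3g, SMS %d, segments %d, PE axis %s\n",
    x$resolution_mm, x$fov_mm, x$matrix_n, x$grappa_r, x$partial_fourier,
    x$sms_factor, x$segments, x$pe_axis))
  invisible(x)
}

#' Minimum echo spacing for an EPI readout
#'
#' The readout lobe is the shortest trapezoid traversing the read axis of
#' k-space (`matrix_n/(fov * gamma_bar)` of gradient area) at the coil's
#' duty-cycle nominal amplitude, with ADC sampling over the ramps; a fixed
#' per-echo dead time (`overhead_us`) is added.  If the result falls inside
#' one of the coil's forbidden echo-spacing bands it is bumped to the band's
#' upper edge (attribute `bumped` set to `TRUE`), mirroring scanner practice
#' of excluding the mechanical-resonance ESs.
#'
#' @param protocol an [epi_protocol()].
#' @param coil a [gradient_coil()].
#' @param overhead_us per-echo dead time in microseconds (default 30).
#' @return echo spacing in ms, with attribute `bumped`.
#' @examples
#' p <- epi_protocol(0.6, 192, 320)
#' min_echo_spacing(p, load_coil_preset("impulse")) # ~0.58 ms
#' @export
min_echo_spacing <- function(protocol, coil, overhead_us = 30) {
  stopifnot(inherits(protocol, "epi_protocol"), inherits(coil, "gradient_coil"))
  if (overhead_us < 0) stop("overhead_us must be >= 0")
  area <- readout_area(protocol$matrix_n, protocol$fov_mm)
  lobe <- trapezoid_for_area(area, coil, use_abs_limit = FALSE)
  es <- lobe$duration_ms + overhead_us / 1000
  bumped <- FALSE
  for (b in coil$forbidden_es_bands) {
    if (es >= b[1] && es <= b[2]) {
      es <- b[2]
      bumped <- TRUE
      warning(sprintf(
        "echo spacing fell in forbidden band [%g, %g] ms; bumped to %g ms",
        b[1], b[2], b[2]))
      break
    }
  }
  structure(es, bumped = bumped)
}

#' Echo-train structure and minimum TE
#'
#' Echo counts follow the partial-Fourier convention that the centre echo is
#' counted among the echoes before (and including) the k-space centre:
#' `echoes_before_center = ceil(matrix_n (PF - 1/2) / (R segments))`,
#' `n_echoes = ceil(matrix_n PF / (R segments))`.  Minimum TE is a fixed
#' pre-readout time (excitation half-duration plus phase pre-winders,
#' default 1.3 ms) plus the traversal to the k-space centre.
#'
#' @inheritParams min_echo_spacing
#' @param pre_time_ms pre-readout time, ms.
#' @param overhead_us passed to [min_echo_spacing()].
#' @return an object of class `epi_timing` with fields `es_ms`, `es_eff_ms`
#'   (= es/(R*segments)), `bw_per_pixel_hz` (~1/es per read pixel),
#'   `n_echoes`, `echoes_before_center`, `train_ms`, `te_min_ms`,
#'   `es_bumped`.
#' @examples
#' p <- epi_protocol(0.6, 192, 320, grappa_r = 3, partial_fourier = 6/8)
#' min_te(p, load_coil_preset("impulse")) # TE ~17 ms
#' @export
min_te <- function(protocol, coil, pre_time_ms = 1.3, overhead_us = 30) {
  es <- min_echo_spacing(protocol, coil, overhead_us = overhead_us)
  rseg <- protocol$grappa_r * protocol$segments
  # guard the ceilings against floating-point excess (e.g. PF = 1/2 + 1/N)
  ebc <- ceiling(protocol$matrix_n * (protocol$partial_fourier - 0.5) / rseg -
                   1e-9)
  ne <- ceiling(protocol$matrix_n * protocol$partial_fourier / rseg - 1e-9)
  structure(
    list(es_ms = as.numeric(es),
         es_eff_ms = as.numeric(es) / rseg,
         bw_per_pixel_hz = 1000 / as.numeric(es),
         n_echoes = as.integer(ne),
         echoes_before_center = as.integer(ebc),
         train_ms = ne * as.numeric(es),
         te_min_ms = pre_time_ms + ebc * as.numeric(es),
         es_bumped = isTRUE(attr(es, "bumped")),
         protocol = protocol, coil_name = coil$name,
         pre_time_ms = pre_time_ms, overhead_us = overhead_us),
    class = "epi_timing")
}

#' @export
print.epi_timing <- function(x, ...) {
  cat(sprintf("EPI timing (%s coil):\n", x$coil_name))
  cat(sprintf("  echo spacing:        %.4f ms%s\n", x$es_ms,
              if (x$es_bumped) " (bumped out of forbidden band)" else ""))
  cat(sprintf("  effective ES:        %.4f ms\n", x$es_eff_ms))
  cat(sprintf("  bandwidth/pixel:     %.0f Hz\n", x$bw_per_pixel_hz))
  cat(sprintf("  echoes (before ctr): %d (%d)\n", x$n_echoes,
              x$echoes_before_center))
  cat(sprintf("  echo train:          %.2f ms\n", x$train_ms))
  cat(sprintf("  minimum TE:          %.2f ms\n", x$te_min_ms))
  invisible(x)
}

#' Finest achievable resolution at a target TE
#'
#' Scans matrix sizes upward and returns the finest resolution (largest
#' matrix) whose minimum TE does not exceed the target.  Minimum TE is
#' monotone non-decreasing in matrix size (longer readout lobes and more
#' echoes before the centre), so the first infeasible matrix bounds the
#' search.
#'
#' @param coil a [gradient_coil()].
#' @param te_target_ms target echo time, ms.
#' @param fov_mm field of view.
#' @param grappa_r,partial_fourier,segments protocol parameters.
#' @param pre_time_ms,overhead_us timing constants, see [min_te()].
#' @param matrix_max largest matrix size considered.
#' @return resolution in mm, with attributes `matrix_n` and `te_ms`.
#' @examples
#' achievable_resolution(load_coil_preset("impulse"), 26, 200, grappa_r = 4,
#'                       partial_fourier = 0.75)
#' @export
achievable_resolution <- function(coil, te_target_ms, fov_mm, grappa_r = 1L,
                                  partial_fourier = 1, segments = 1L,
                                  pre_time_ms = 1.3, overhead_us = 30,
                                  matrix_max = 1024L) {
  stopifnot(inherits(coil, "gradient_coil"))
  if (te_target_ms <= pre_time_ms)
    stop("te_target must exceed the pre-readout time")
  best <- NULL
  for (m in seq(2L * grappa_r, matrix_max)) {
    p <- epi_protocol(fov_mm / m, fov_mm, m, grappa_r = grappa_r,
                      partial_fourier = partial_fourier, segments = segments)
    t <- suppressWarnings(min_te(p, coil, pre_time_ms = pre_time_ms,
                                 overhead_us = overhead_us))
    if (t$te_min_ms <= te_target_ms) {
      best <- list(m = m, te = t$te_min_ms)
    }
    # te_min is monotone in m up to forbidden-band bumps; a generous slack
    # guards against a bump making one matrix infeasible while a larger one
    # is feasible again.
    if (t$te_min_ms > te_target_ms + 5 && !is.null(best)) break
  }
  if (is.null(best))
    stop("no feasible matrix size: te_target too small for this geometry")
  structure(fov_mm / best$m, matrix_n = best$m, te_ms = best$te)
}
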
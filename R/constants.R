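# Physical constants and the internal unit system.
#
# All timing is in milliseconds, gradient amplitude in mT/m.  A slew rate in
# T/m/s is numerically identical in mT/m/ms, so slew values are carried
# unchanged.  Conversions to SI happen only at the boundary (b-values, k-space
# areas).

#' Gyromagnetic constants for the proton
#'
#' `gamma_bar_hz_per_t` is the reduced gyromagnetic ratio (42.576 MHz/T);
#' `gamma_rad_per_s_t` the angular form (2.6752e8 rad/s/T) used in
#' Stejskal-Tanner b-value algebra.
#'
#' @name gyromagnetic
#' @keywords internal
NULL

GAMMA_BAR_HZ_PER_T <- 42.576e6
GAMMA_RAD_PER_S_T <- 2.6752e8

#' Readout gradient area for one k-space line
#'
#' The zeroth gradient moment needed to traverse the read axis of k-space:
#' `matrix_n / (fov * gamma_bar)`, returned in (mT/m)*ms.
#'
#' @param matrix_n read-axis matrix size (number of samples).
#' @param fov_mm field of view in mm.
#' @return gradient area in (mT/m)*ms.
#' @examples
#' readout_area(320, 192) # ~39.1 (mT/m)*ms
#' @export
readout_area <- function(matrix_n, fov_mm) {
  stopifnot(matrix_n > 0, fov_mm > 0)
  matrix_n * 1e3 / (fov_mm * 42.576)
}
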
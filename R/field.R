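#' Static-field configuration
#'
#' Describes the spectrometer field through the observed-nucleus Larmor
#' frequency and the gyromagnetic ratio. All chemical-shift/frequency
#' conversions in the package go through this object, so ppm, Hz and
#' rad s^-1 never get mixed silently. The gyromagnetic ratio is stored as
#' a magnitude plus a separate sign: Xe-129 has a negative ratio, but
#' only the gradient-encoding axis direction cares about the sign.
#'
#' @param larmor_mhz Larmor frequency of the observed nucleus in MHz
#'   (e.g. 12.09 for Xe-129 on a 1 T benchtop magnet, 138.36 at 11.7 T).
#' @param gamma_bar_mhz_t Magnitude of the reduced gyromagnetic ratio
#'   gamma-bar = gamma / (2 pi) in MHz T^-1. Default 11.79 (Xe-129).
#' @param gamma_sign Sign of the gyromagnetic ratio, `+1` or `-1`.
#'   Default `-1` (Xe-129).
#'
#' @return An object of class `field_config`.
#' @examples
#' benchtop <- field_config(12.09)
#' ppm_to_rad(benchtop, 144)
#' @export
field_config <- function(larmor_mhz, gamma_bar_mhz_t = 11.79, gamma_sign = -1) {
  stopifnot(
    is.numeric(larmor_mhz), length(larmor_mhz) == 1, larmor_mhz > 0,
    is.numeric(gamma_bar_mhz_t), length(gamma_bar_mhz_t) == 1, gamma_bar_mhz_t > 0,
    gamma_sign %in% c(-1, 1)
  )
  structure(
    list(
      larmor_mhz = larmor_mhz,
      gamma_bar_mhz_t = gamma_bar_mhz_t,
      gamma_sign = gamma_sign
    ),
    class = "field_config"
  )
}

#' @export
print.field_config <- function(x, ...) {
  cat(sprintf(
    "<field_config> Larmor %.4g MHz, gamma-bar %s%.4g MHz/T\n",
    x$larmor_mhz, if (x$gamma_sign < 0) "-" else "+", x$gamma_bar_mhz_t
  ))
  invisible(x)
}

#' Chemical-shift unit conversions
#'
#' Linear, invertible bridges between ppm, Hz and rad s^-1 at the field's
#' Larmor frequency. 1 ppm corresponds to `larmor_mhz` Hz.
#'
#' @param field A [field_config()].
#' @param shift_ppm Chemical shift (or shift difference) in ppm.
#' @param freq_rad Angular frequency in rad s^-1.
#' @param freq_hz Frequency in Hz.
#' @return A numeric vector in the target unit.
#' @examples
#' f <- field_config(12.09)
#' rad_to_ppm(f, ppm_to_rad(f, 52))
#' @export
ppm_to_rad <- function(field, shift_ppm) {
  stopifnot(inherits(field, "field_config"))
  2 * pi * field$larmor_mhz * shift_ppm
}

#' @rdname ppm_to_rad
#' @export
rad_to_ppm <- function(field, freq_rad) {
  stopifnot(inherits(field, "field_config"))
  freq_rad / (2 * pi * field$larmor_mhz)
}

#' @rdname ppm_to_rad
#' @export
ppm_to_hz <- function(field, shift_ppm) {
  stopifnot(inherits(field, "field_config"))
  field$larmor_mhz * shift_ppm
}

#' @rdname ppm_to_rad
#' @export
hz_to_ppm <- function(field, freq_hz) {
  stopifnot(inherits(field, "field_config"))
  freq_hz / field$larmor_mhz
}

#' Saturation-field strength conversions
#'
#' The rf amplitude is handled internally as the nutation rate omega_1 in
#' rad s^-1; B1 in microtesla is a derived display value through
#' B1 = omega_1 / gamma.
#'
#' @inheritParams ppm_to_rad
#' @param omega1 rf amplitude in rad s^-1.
#' @param b1_ut rf amplitude in microtesla.
#' @return Numeric vector in the target unit.
#' @export
omega1_to_b1 <- function(field, omega1) {
  stopifnot(inherits(field, "field_config"))
  omega1 / (2 * pi * field$gamma_bar_mhz_t)  # rad/s / (rad/s/uT) = uT
}

#' @rdname omega1_to_b1
#' @export
b1_to_omega1 <- function(field, b1_ut) {
  stopifnot(inherits(field, "field_config"))
  b1_ut * 2 * pi * field$gamma_bar_mhz_t
}
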
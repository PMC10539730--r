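#' Tilt angle of the effective field
#'
#' Off-resonance CW irradiation of amplitude omega_1 at an offset
#' Delta_i from the observed resonance tilts the effective field by
#' theta = arctan(omega_1 / |Delta_i|), taken in \[-pi/2, pi/2\]. On
#' resonance (Delta_i = 0, omega_1 > 0) the angle is pi/2.
#'
#' @param omega1 rf amplitude in rad s^-1 (scalar, >= 0).
#' @param delta_i Offset of the rf from the observed resonance in
#'   rad s^-1 (vectorized).
#' @return Tilt angle(s) in radians.
#' @export
tilt_angle <- function(omega1, delta_i) {
  stopifnot(omega1 >= 0)
  if (omega1 == 0 && any(delta_i == 0)) {
    stop("tilt angle undefined: omega1 and the offset are both zero")
  }
  ifelse(delta_i == 0, pi / 2, atan(omega1 / abs(delta_i)))
}

#' Direct depolarization rate of the free pool
#'
#' The rf irradiation itself, even without any exchange, mixes
#' longitudinal and transverse relaxation along the tilted effective
#' field: lambda_direct = R1A cos^2(theta) + R2A sin^2(theta). This term
#' sets the Z-spectrum baseline and is what forces small saturation
#' amplitudes at low field, where the caged pool sits only ~1.8 kHz from
#' the free pool.
#'
#' @param free A [free_pool()].
#' @param omega1 rf amplitude in rad s^-1.
#' @param delta_i Offset of the rf from the free-pool resonance in
#'   rad s^-1 (vectorized).
#' @return Depolarization rate(s) in s^-1, bounded between R1A and R2A.
#' @export
lambda_direct <- function(free, omega1, delta_i) {
  stopifnot(inherits(free, "free_pool"))
  theta <- tilt_angle(omega1, delta_i)
  free$r1 * cos(theta)^2 + free$r2 * sin(theta)^2
}

#' On-resonance CEST depolarization rate
#'
#' Peak depolarization of the free pool when saturating exactly on the
#' bound-pool resonance, valid for k_out >> R2B and k_out >> k_in:
#' lambda_on = f k_out omega_1^2 / (omega_1^2 + k_out^2). It increases
#' monotonically with omega_1 and saturates at f * k_out, the full
#' exchange-limited depolarization rate.
#'
#' @param pool A [bound_pool()].
#' @param omega1 rf amplitude in rad s^-1 (vectorized).
#' @return Rate(s) in s^-1.
#' @export
lambda_on <- function(pool, omega1) {
  stopifnot(inherits(pool, "bound_pool"), all(omega1 >= 0))
  pool$f * pool$k_out * omega1^2 / (omega1^2 + pool$k_out^2)
}

#' Full width at half maximum of the CEST dip
#'
#' Gamma = 2 sqrt(omega_1^2 + k_out^2) in rad s^-1: the dip can never be
#' narrower than 2 k_out, and power-broadens with omega_1.
#'
#' @inheritParams lambda_on
#' @return FWHM(s) in rad s^-1.
#' @export
gamma_fwhm <- function(pool, omega1) {
  stopifnot(inherits(pool, "bound_pool"), all(omega1 >= 0))
  2 * sqrt(omega1^2 + pool$k_out^2)
}

#' Off-resonance CEST depolarization rate (Lorentzian dip)
#'
#' As a function of the rf offset the CEST depolarization rate is a
#' Lorentzian centred on the bound-pool shift with peak [lambda_on()]
#' and FWHM [gamma_fwhm()]:
#' lambda_CEST = lambda_on * (Gamma^2/4) / (Gamma^2/4 + (w_i - w_B)^2).
#'
#' @param pool A [bound_pool()].
#' @param field A [field_config()] (converts the ppm offsets to rad s^-1).
#' @param omega1 rf amplitude in rad s^-1 (scalar).
#' @param offset_ppm rf offset(s) in ppm (vectorized).
#' @return Rate(s) in s^-1.
#' @export
lambda_cest <- function(pool, field, omega1, offset_ppm) {
  stopifnot(inherits(pool, "bound_pool"), inherits(field, "field_config"))
  dw <- ppm_to_rad(field, offset_ppm - pool$delta_ppm)
  lon <- lambda_on(pool, omega1)
  g2_4 <- (gamma_fwhm(pool, omega1) / 2)^2
  lon * g2_4 / (g2_4 + dw^2)
}

#' Total depolarization rate of the free pool
#'
#' Sum of the direct term and one Lorentzian CEST term per bound pool.
#' Pools are dilute and independent, so multi-pool dips add. With
#' `simplified = TRUE` the high-field form is used instead, where the
#' rf is always far off-resonance from the free pool
#' (|w_i - w_A| >> omega_1) and the direct term collapses to R1A.
#'
#' @param system An [exchange_system()].
#' @param sat A [saturation_scheme()]; its `offset_ppm` may be a vector.
#' @param simplified Use the far-off-resonance approximation for the
#'   direct term (default `FALSE`, i.e. full tilt-angle form).
#' @param weighted_relaxation Use the population-weighted effective
#'   relaxation rates in the direct term instead of the bare free-pool
#'   rates (default `FALSE`; the correction is O(f)).
#' @return Rate(s) in s^-1, one per rf offset.
#' @export
lambda_total <- function(system, sat, simplified = FALSE,
                         weighted_relaxation = FALSE) {
  stopifnot(inherits(system, "exchange_system"),
            inherits(sat, "saturation_scheme"))
  free <- system$free
  if (weighted_relaxation) {
    eff <- effective_relaxation(system)
    free <- free_pool(free$delta_ppm, eff$r1_eff, eff$r2_eff, free$m0)
  }
  offs <- sat$offset_ppm
  direct <- if (simplified) {
    rep(free$r1, length(offs))
  } else {
    delta_i <- ppm_to_rad(system$field, offs - free$delta_ppm)
    lambda_direct(free, sat$omega1, delta_i)
  }
  cest <- rep(0, length(offs))
  for (b in system$bound) {
    cest <- cest + lambda_cest(b, system$field, sat$omega1, offs)
  }
  direct + cest
}

#' Free-pool magnetization after saturation
#'
#' Hyperpolarized magnetization decays as a single exponential at the
#' total depolarization rate: Z = M0A exp(-lambda t_sat). There is no
#' recovery toward thermal equilibrium.
#'
#' @inheritParams lambda_total
#' @return Magnetization value(s), same units as `m0` of the free pool.
#' @export
z_value <- function(system, sat, simplified = FALSE,
                    weighted_relaxation = FALSE) {
  lam <- lambda_total(system, sat, simplified, weighted_relaxation)
  system$free$m0 * exp(-lam * sat$t_sat)
}

#' Simulate a Z spectrum
#'
#' Evaluates the analytic Z value over a grid of rf offsets, producing
#' the familiar Z-spectrum picture: a baseline set by the direct term
#' (sinking toward the free-pool resonance) with one Lorentzian dip per
#' caged-xenon pool.
#'
#' @param system An [exchange_system()].
#' @param omega1 rf amplitude in rad s^-1.
#' @param t_sat Saturation duration in s.
#' @param offsets_ppm Vector of rf offsets in ppm.
#' @param simplified Use the far-off-resonance direct term (see
#'   [lambda_total()]).
#' @return A tibble with columns `offset_ppm`, `lambda` (s^-1), `z`
#'   (magnetization units) and `z_norm` (z / M0A).
#' @examples
#' sys <- exchange_system(
#'   field_config(12.09),
#'   free_pool(196, r1 = 0.01, r2 = 20),
#'   bound_pool(f = 0.04, k_out = 50, delta_ppm = 52)
#' )
#' zs <- z_spectrum(sys, omega1 = 64.7, t_sat = 3,
#'                  offsets_ppm = seq(0, 100, by = 0.5))
#' zs[which.min(zs$z_norm), ]
#' @export
z_spectrum <- function(system, omega1, t_sat, offsets_ppm,
                       simplified = FALSE) {
  stopifnot(length(offsets_ppm) > 0)
  sat <- saturation_scheme(omega1, offsets_ppm, t_sat)
  lam <- lambda_total(system, sat, simplified)
  tibble::tibble(
    offset_ppm = offsets_ppm,
    lambda = lam,
    z = system$free$m0 * exp(-lam * t_sat),
    z_norm = exp(-lam * t_sat)
  )
}
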
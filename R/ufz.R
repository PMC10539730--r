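#' Sample-tube geometry
#'
#' For a transverse gradient on a cylindrical tube the sample extent
#' along the gradient axis equals the inner diameter, and the 1-D
#' magnetization profile is the chord-length projection of the disc.
#'
#' @param inner_diameter_m Tube inner diameter in m (4.3 mm = 0.0043 for
#'   a standard 5 mm NMR tube).
#' @param extent_m Sample extent along the gradient axis in m; defaults
#'   to the inner diameter (transverse gradient).
#' @return An object of class `tube_geometry`.
#' @export
tube_geometry <- function(inner_diameter_m = 0.0043,
                          extent_m = inner_diameter_m) {
  stopifnot(inner_diameter_m > 0, extent_m > 0)
  structure(
    list(inner_diameter_m = inner_diameter_m, extent_m = extent_m),
    class = "tube_geometry"
  )
}

#' Saturation / acquisition gradient pair
#'
#' Signed gradient amplitudes in T m^-1. The saturation gradient encodes
#' rf offset into position; the acquisition gradient decodes position
#' into detected frequency. Their ratio rescales true chemical-shift
#' splittings into apparent splittings on the UFZ axis.
#'
#' @param g_sat Saturation gradient in T m^-1 (signed; 21 mT/m = 0.021).
#' @param g_acq Acquisition gradient in T m^-1 (signed, non-zero).
#' @return An object of class `gradient_scheme`.
#' @export
gradient_scheme <- function(g_sat, g_acq) {
  stopifnot(is.numeric(g_sat), is.numeric(g_acq), g_acq != 0)
  structure(list(g_sat = g_sat, g_acq = g_acq), class = "gradient_scheme")
}

#' Ultra-fast Z experiment description
#'
#' Bundles everything the UFZ simulator needs: the exchange system, the
#' CW saturation (its `offset_ppm` is the rf carrier, placed in the
#' caged-xenon region), tube geometry, gradient pair, spatial
#' discretization and the noise model.
#'
#' @param system An [exchange_system()].
#' @param sat A [saturation_scheme()] (scalar offset).
#' @param geometry A [tube_geometry()].
#' @param gradients A [gradient_scheme()] with non-zero `g_sat`.
#' @param n_positions Number of spatial sample points across the tube
#'   (>= 32; default 512).
#' @param noise_sigma Relative (multiplicative) Gaussian noise s.d. per
#'   point; 0 disables noise.
#' @param off_scale Polarization scale of the off scan relative to the
#'   on scan: the simulated off profile is envelope / `off_scale`, and
#'   supplying the same value to [saturation_ratio()] undoes it.
#' @param rng_seed Integer seed for the noise generator, or `NULL` to
#'   use the session RNG stream.
#' @return An object of class `ufz_experiment`.
#' @export
ufz_experiment <- function(system, sat, geometry = tube_geometry(),
                           gradients, n_positions = 512,
                           noise_sigma = 0, off_scale = 1,
                           rng_seed = NULL) {
  stopifnot(
    inherits(system, "exchange_system"),
    inherits(sat, "saturation_scheme"), length(sat$offset_ppm) == 1,
    inherits(geometry, "tube_geometry"),
    inherits(gradients, "gradient_scheme"), gradients$g_sat != 0,
    n_positions >= 32, noise_sigma >= 0, off_scale > 0
  )
  structure(
    list(system = system, sat = sat, geometry = geometry,
         gradients = gradients, n_positions = as.integer(n_positions),
         noise_sigma = noise_sigma, off_scale = off_scale,
         rng_seed = rng_seed),
    class = "ufz_experiment"
  )
}

#' Chord-projection density profile of the tube
#'
#' Projecting a homogeneously filled cylinder onto a transverse axis
#' gives the chord length of the circular cross-section:
#' rho(x) proportional to sqrt((d/2)^2 - x^2) for |x| <= d/2, zero
#' outside. This rounded envelope is what every UFZ profile sits under.
#' The profile is normalized to 1 at the tube axis.
#'
#' @param geometry A [tube_geometry()].
#' @param n_positions Number of evenly spaced sample points spanning the
#'   extent.
#' @return A tibble with columns `position_m` (strictly increasing,
#'   centred on the tube axis) and `density`.
#' @export
density_profile <- function(geometry, n_positions = 512) {
  stopifnot(inherits(geometry, "tube_geometry"), n_positions >= 2)
  half_ext <- geometry$extent_m / 2
  radius <- geometry$inner_diameter_m / 2
  x <- seq(-half_ext, half_ext, length.out = n_positions)
  rho <- ifelse(abs(x) <= radius, sqrt(pmax(radius^2 - x^2, 0)) / radius, 0)
  tibble::tibble(position_m = x, density = rho)
}

#' Local rf offset under the saturation gradient
#'
#' Saturating in the presence of a gradient makes the rf appear shifted
#' by -gamma * G_sat * x at position x: each slice of the tube sees a
#' different effective saturation offset, which is the spatial encoding
#' at the heart of the UFZ experiment. A pool with shift delta_B is
#' saturated on-resonance at x_B = (w_rf - w_B) / (gamma * G_sat).
#'
#' @param x Position(s) along the gradient axis in m.
#' @param rf_offset_ppm rf carrier position in ppm.
#' @param gradients A [gradient_scheme()].
#' @param field A [field_config()].
#' @return Effective saturation offset(s) in ppm.
#' @export
local_offset <- function(x, rf_offset_ppm, gradients, field) {
  stopifnot(inherits(gradients, "gradient_scheme"),
            inherits(field, "field_config"))
  gamma_hz_t <- field$gamma_sign * field$gamma_bar_mhz_t * 1e6
  shift_hz <- gamma_hz_t * gradients$g_sat * x
  rf_offset_ppm - hz_to_ppm(field, shift_hz)
}

# relative multiplicative Gaussian noise, isolated from the session RNG
# stream when a seed is given
apply_noise <- function(y, sigma, seed) {
  if (sigma <= 0) return(y)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  y * (1 + stats::rnorm(length(y), sd = sigma))
}

#' Simulate the on and off UFZ profiles
#'
#' The off scan is the bare tube envelope (recorded without saturation,
#' at a polarization `off_scale` times lower than the on scan); the on
#' scan is the envelope attenuated pointwise by
#' exp(-lambda(offset(x)) * t_sat), with the local offset set by the
#' saturation gradient. Dips appear where a bound pool comes
#' on-resonance, at x_Bj = (w_rf - w_Bj) / (gamma * G_sat). The dip
#' width along x is not imposed: it follows from the Lorentzian
#' selectivity of the CEST rate evaluated continuously at every
#' position.
#'
#' @param experiment A [ufz_experiment()].
#' @return A tibble with columns `position_m`, `offset_ppm` (local
#'   saturation offset), `on`, `off`.
#' @export
simulate_profiles <- function(experiment) {
  stopifnot(inherits(experiment, "ufz_experiment"))
  prof <- density_profile(experiment$geometry, experiment$n_positions)
  offs <- local_offset(prof$position_m, experiment$sat$offset_ppm,
                       experiment$gradients, experiment$system$field)
  sat_x <- saturation_scheme(experiment$sat$omega1, offs,
                             experiment$sat$t_sat)
  lam <- lambda_total(experiment$system, sat_x)
  on <- prof$density * exp(-lam * experiment$sat$t_sat)
  off <- prof$density / experiment$off_scale
  seed <- experiment$rng_seed
  on <- apply_noise(on, experiment$noise_sigma, seed)
  off <- apply_noise(off, experiment$noise_sigma,
                     if (!is.null(seed)) seed + 1L)
  tibble::tibble(
    position_m = prof$position_m,
    offset_ppm = offs,
    on = on,
    off = off
  )
}

#' Decode profiles into a UFZ spectrum
#'
#' Maps the position axis to the detected frequency nu(x) =
#' gamma * G_acq * x, expressed as apparent ppm at the configured Larmor
#' frequency, and forms the difference trace off_scale * off - on. The
#' apparent axis runs reversed when the two gradients have opposite
#' relative sign, exactly as on the instrument.
#'
#' @param profiles Tibble from [simulate_profiles()] (columns
#'   `position_m`, `on`, `off`).
#' @param gradients A [gradient_scheme()].
#' @param field A [field_config()].
#' @param off_scale Scale applied to the off profile before subtraction
#'   (default 1).
#' @return A tibble with columns `apparent_ppm` (strictly increasing),
#'   `position_m`, `on`, `off`, `diff`, where `diff` is the Z-spectrum
#'   signal (positive at the dips).
#' @export
acquire_ufz <- function(profiles, gradients, field, off_scale = 1) {
  stopifnot(inherits(gradients, "gradient_scheme"),
            inherits(field, "field_config"))
  need <- c("position_m", "on", "off")
  if (!all(need %in% names(profiles))) {
    stop("profiles must contain columns ", paste(need, collapse = ", "))
  }
  gamma_hz_t <- field$gamma_sign * field$gamma_bar_mhz_t * 1e6
  nu_hz <- gamma_hz_t * gradients$g_acq * profiles$position_m
  out <- tibble::tibble(
    apparent_ppm = hz_to_ppm(field, nu_hz),
    position_m = profiles$position_m,
    on = profiles$on,
    off = profiles$off,
    diff = off_scale * profiles$off - profiles$on
  )
  dplyr::arrange(out, .data$apparent_ppm)
}

#' Run a complete UFZ experiment
#'
#' Convenience wrapper: [simulate_profiles()] then [acquire_ufz()] with
#' the experiment's own `off_scale`.
#'
#' @param experiment A [ufz_experiment()].
#' @return The UFZ spectrum tibble of [acquire_ufz()].
#' @export
simulate_ufz <- function(experiment) {
  profiles <- simulate_profiles(experiment)
  acquire_ufz(profiles, experiment$gradients, experiment$system$field,
              off_scale = experiment$off_scale)
}

#' Apparent splitting of two dips on the UFZ axis
#'
#' Two resonances separated by Delta-delta on a conventional spectrum
#' appear separated by Delta-delta * |G_acq / G_sat| on the UFZ axis:
#' saturation encodes at G_sat, readout decodes at G_acq.
#'
#' @param delta_b1_ppm,delta_b2_ppm Bound-pool shifts in ppm.
#' @param gradients A [gradient_scheme()] with non-zero `g_sat`.
#' @return Apparent splitting in ppm (non-negative).
#' @examples
#' apparent_splitting(52, 42, gradient_scheme(0.021, 0.084))  # 40 ppm
#' @export
apparent_splitting <- function(delta_b1_ppm, delta_b2_ppm, gradients) {
  stopifnot(inherits(gradients, "gradient_scheme"))
  if (gradients$g_sat == 0) stop("g_sat must be non-zero")
  abs(delta_b1_ppm - delta_b2_ppm) * abs(gradients$g_acq / gradients$g_sat)
}

#' Does a dip exit the magnetization envelope?
#'
#' Lowering G_sat magnifies the apparent splitting but pushes the
#' saturated slice outward; the dip leaves the sample when
#' 2 |w_rf - w_B| / G_sat > gamma * r, i.e. when |x_B| exceeds half the
#' sample extent.
#'
#' @param rf_offset_ppm rf carrier position in ppm.
#' @param delta_b_ppm Bound-pool shift in ppm.
#' @param gradients A [gradient_scheme()] (only `g_sat` is used).
#' @param geometry A [tube_geometry()].
#' @param field A [field_config()].
#' @return `TRUE` if the dip falls strictly outside the envelope.
#' @export
envelope_exit_check <- function(rf_offset_ppm, delta_b_ppm, gradients,
                                geometry, field) {
  stopifnot(inherits(gradients, "gradient_scheme"),
            inherits(geometry, "tube_geometry"),
            inherits(field, "field_config"))
  if (gradients$g_sat == 0) stop("g_sat must be non-zero")
  dnu_hz <- abs(ppm_to_hz(field, rf_offset_ppm - delta_b_ppm))
  gamma_hz_t <- field$gamma_bar_mhz_t * 1e6
  2 * dnu_hz / abs(gradients$g_sat) > gamma_hz_t * geometry$extent_m
}

#' Locate dips in a UFZ spectrum
#'
#' Finds the `n_dips` most prominent local maxima of the difference
#' trace (off - on), i.e. the saturation dips, and returns them ordered
#' by position on the apparent axis.
#'
#' @param ufz UFZ spectrum tibble from [acquire_ufz()] (columns
#'   `apparent_ppm`, `diff`).
#' @param n_dips Number of dips to report.
#' @param min_height Minimum `diff` value (as a fraction of the largest
#'   local maximum) for a candidate dip; guards against noise maxima.
#' @return A tibble with columns `apparent_ppm`, `position_m` (if
#'   present in `ufz`), `depth`, one row per dip.
#' @export
find_dips <- function(ufz, n_dips = 2, min_height = 0.2) {
  stopifnot(all(c("apparent_ppm", "diff") %in% names(ufz)))
  y <- ufz$diff
  n <- length(y)
  if (n < 3) stop("trace too short to locate dips")
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  idx <- which(is_max)
  if (!length(idx)) stop("no local maxima found in the difference trace")
  idx <- idx[y[idx] >= min_height * max(y[idx])]
  idx <- idx[order(y[idx], decreasing = TRUE)]
  idx <- sort(utils::head(idx, n_dips))
  # three-point parabolic refinement of each maximum: removes the
  # half-bin snapping bias of the sampled grid
  refined <- vapply(idx, function(i) {
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    shift <- if (denom < 0) 0.5 * (y[i - 1] - y[i + 1]) / denom else 0
    shift <- max(min(shift, 0.5), -0.5)
    ufz$apparent_ppm[i] + shift * (ufz$apparent_ppm[i + 1] -
                                     ufz$apparent_ppm[i - 1]) / 2
  }, numeric(1))
  out <- tibble::tibble(apparent_ppm = refined,
                        depth = y[idx])
  if ("position_m" %in% names(ufz)) {
    out$position_m <- ufz$position_m[idx]
  }
  out
}
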
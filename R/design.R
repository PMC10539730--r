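#' Upper bound on the saturation gradient
#'
#' The spectral spread of the saturation across the tube,
#' gamma * G_sat * d, must stay below the frequency splitting between
#' free and caged xenon, or the saturated slice walks onto the free-pool
#' resonance. The bound is |Delta nu_AB| / (gamma-bar * d): at 1 T with
#' a 4.3 mm tube and an 1800 Hz splitting this is 35.5 mT/m.
#'
#' @param field A [field_config()].
#' @param geometry A [tube_geometry()] (its inner diameter is used).
#' @param delta_a_ppm,delta_b_ppm Free- and bound-pool shifts in ppm.
#' @param delta_nu_hz Optional splitting in Hz, overriding the ppm
#'   difference (useful when the splitting is known directly).
#' @return Maximum usable saturation gradient in T m^-1.
#' @examples
#' gsat_bound(field_config(12.09), tube_geometry(0.0043),
#'            delta_nu_hz = 1800)  # 0.0355 T/m
#' @export
gsat_bound <- function(field, geometry, delta_a_ppm = 196,
                       delta_b_ppm = 52, delta_nu_hz = NULL) {
  stopifnot(inherits(field, "field_config"),
            inherits(geometry, "tube_geometry"))
  dnu <- if (is.null(delta_nu_hz)) {
    abs(ppm_to_hz(field, delta_a_ppm - delta_b_ppm))
  } else {
    abs(delta_nu_hz)
  }
  dnu / (field$gamma_bar_mhz_t * 1e6 * geometry$inner_diameter_m)
}

#' Classify the saturation-strength regime of a pool
#'
#' Eq.-level behaviour of the on-resonance depolarization rate as the
#' rf amplitude moves across the exit rate: well above k_out the rate
#' saturates at f k_out; at omega_1 = k_out it is exactly half of that;
#' well below, it grows parabolically as (f / k_out) omega_1^2. The
#' decade thresholds (factor 10 either side of k_out) put the
#' asymptotic formulas within 1 percent.
#'
#' @param pool A [bound_pool()].
#' @param omega1 rf amplitude in rad s^-1.
#' @return A list with `label` (one of `"saturated"`, `"intermediate"`,
#'   `"parabolic"`), `lambda_on` (s^-1) and `ratio` (omega1 / k_out).
#' @export
regime_classify <- function(pool, omega1) {
  stopifnot(inherits(pool, "bound_pool"), omega1 >= 0)
  ratio <- omega1 / pool$k_out
  label <- if (ratio >= 10) "saturated"
           else if (ratio <= 0.1) "parabolic"
           else "intermediate"
  list(label = label, lambda_on = lambda_on(pool, omega1), ratio = ratio)
}

# depth of pool j's dip at (omega1, t_sat): baseline (direct term only,
# evaluated at the dip minimum) minus dip minimum, on the z_norm scale
dip_depth_one <- function(system, omega1, t_sat, j, offsets_ppm) {
  zs <- z_spectrum(system, omega1, t_sat, offsets_ppm)
  bare <- exchange_system(system$field, system$free, list())
  z0 <- z_spectrum(bare, omega1, t_sat, offsets_ppm)
  db <- system$bound[[j]]$delta_ppm
  others <- vapply(system$bound, `[[`, numeric(1), "delta_ppm")
  half_sep <- if (length(others) > 1) {
    min(abs(db - others[others != db])) / 2
  } else Inf
  win <- abs(offsets_ppm - db) <= min(half_sep, 10)
  i_min <- which(win)[which.min(zs$z_norm[win])]
  list(depth = z0$z_norm[i_min] - zs$z_norm[i_min],
       z_min = zs$z_norm[i_min], at = offsets_ppm[i_min], idx = i_min)
}

#' Scan saturation strength for dip contrast and separation
#'
#' For each rf amplitude on the grid, simulates the analytic Z spectrum
#' over the caged-xenon region and reports, per bound pool, the dip
#' depth (direct-term baseline at the dip minimum minus the dip
#' minimum, on the Z/M0A scale), the baseline level in the dip region,
#' and whether the dips are mutually resolved (each dip minimum lies
#' below the saddle between adjacent dips by at least 10 percent of the
#' deepest dip). Raising omega_1 deepens the dips but sinks the
#' baseline and power-broadens the dips together, so a compromise
#' window exists; the recommendation keeps the omega_1 values whose
#' score (smallest dip depth, zeroed when unresolved) is within 90
#' percent of the best score.
#'
#' @param system An [exchange_system()] with at least one bound pool.
#' @param t_sat Saturation duration in s.
#' @param omega1_grid rf amplitudes to scan, rad s^-1.
#' @param offsets_ppm Offset grid for the spectra; defaults to the
#'   bound-pool region padded by 20 ppm at 0.1 ppm resolution.
#' @return An object of class `omega1_scan` with elements `scan` (a
#'   tibble: `omega1`, `pool`, `depth`, `z_min`, `baseline`,
#'   `resolved`, `score`), `recommended` (the omega_1 values retained)
#'   and `window` (their range, or `NULL` when no amplitude produces
#'   any dip).
#' @export
omega1_scan <- function(system, t_sat, omega1_grid, offsets_ppm = NULL) {
  stopifnot(inherits(system, "exchange_system"),
            length(system$bound) >= 1, length(omega1_grid) > 0)
  db <- vapply(system$bound, `[[`, numeric(1), "delta_ppm")
  if (is.null(offsets_ppm)) {
    offsets_ppm <- seq(min(db) - 20, max(db) + 20, by = 0.1)
  }
  bare <- exchange_system(system$field, system$free, list())
  rows <- purrr::map_dfr(omega1_grid, function(w1) {
    zs <- z_spectrum(system, w1, t_sat, offsets_ppm)
    z0 <- z_spectrum(bare, w1, t_sat, offsets_ppm)
    per_pool <- purrr::map_dfr(seq_along(system$bound), function(j) {
      d <- dip_depth_one(system, w1, t_sat, j, offsets_ppm)
      tibble::tibble(pool = j, depth = d$depth, z_min = d$z_min,
                     at_ppm = d$at, idx = d$idx)
    })
    region <- abs(offsets_ppm - mean(range(db))) <= diff(range(db)) / 2 + 5
    baseline <- mean(z0$z_norm[region])
    resolved <- TRUE
    if (nrow(per_pool) > 1) {
      pp <- dplyr::arrange(per_pool, .data$at_ppm)
      deepest <- max(pp$depth)
      for (i in seq_len(nrow(pp) - 1)) {
        between <- offsets_ppm > pp$at_ppm[i] & offsets_ppm < pp$at_ppm[i + 1]
        saddle <- if (any(between)) max(zs$z_norm[between]) else -Inf
        if (!((saddle - pp$z_min[i]) >= 0.1 * deepest &&
              (saddle - pp$z_min[i + 1]) >= 0.1 * deepest)) {
          resolved <- FALSE
        }
      }
    }
    score <- if (resolved) min(per_pool$depth) else 0
    dplyr::mutate(per_pool[, c("pool", "depth", "z_min")],
                  omega1 = w1, baseline = baseline,
                  resolved = resolved, score = score,
                  .before = 1)
  })
  by_w1 <- dplyr::distinct(rows, .data$omega1, .data$score)
  best <- max(by_w1$score)
  recommended <- if (best > 0) {
    by_w1$omega1[by_w1$score >= 0.9 * best]
  } else numeric(0)
  structure(
    list(scan = tibble::as_tibble(rows),
         recommended = recommended,
         window = if (length(recommended)) range(recommended) else NULL),
    class = "omega1_scan"
  )
}

#' @export
print.omega1_scan <- function(x, ...) {
  if (is.null(x$window)) {
    cat("<omega1_scan> no usable saturation amplitude on the grid\n")
  } else {
    cat(sprintf(
      "<omega1_scan> recommended omega1 window: [%.3g, %.3g] rad/s (%d grid values)\n",
      x$window[1], x$window[2], length(x$recommended)))
  }
  invisible(x)
}

#' Saturation-time trade-off against a reference setting
#'
#' A weak saturation needs a longer hold to dig the same dip. This scan
#' evaluates the first pool's dip depth at a low rf amplitude over a
#' grid of saturation times and marks where it reaches at least 90
#' percent of the depth delivered by a reference (typically high-field,
#' stronger-rf) setting, which may use a different exchange system
#' (field, relaxation).
#'
#' @param system An [exchange_system()] for the scanned (low-amplitude)
#'   setting; pool 1 is tracked.
#' @param omega1_low rf amplitude of the scanned setting, rad s^-1.
#' @param tsat_grid Saturation times to scan, s.
#' @param ref_system An [exchange_system()] for the reference setting
#'   (defaults to `system`).
#' @param omega1_ref,tsat_ref rf amplitude and saturation time of the
#'   reference setting.
#' @return An object of class `tsat_tradeoff`: a list with `table` (a
#'   tibble `t_sat`, `depth`, `frac_of_ref`, `meets_ref`),
#'   `ref_depth`, and `t_sat_90` (smallest scanned time whose depth
#'   reaches 90 percent of the reference depth, `NA` if never).
#' @export
tsat_tradeoff <- function(system, omega1_low, tsat_grid,
                          ref_system = system, omega1_ref, tsat_ref) {
  stopifnot(length(tsat_grid) > 0, length(system$bound) >= 1,
            length(ref_system$bound) >= 1)
  db <- system$bound[[1]]$delta_ppm
  offs <- seq(db - 15, db + 15, by = 0.05)
  db_ref <- ref_system$bound[[1]]$delta_ppm
  offs_ref <- seq(db_ref - 15, db_ref + 15, by = 0.05)
  ref_depth <- dip_depth_one(ref_system, omega1_ref, tsat_ref, 1,
                             offs_ref)$depth
  tab <- purrr::map_dfr(sort(tsat_grid), function(ts) {
    d <- dip_depth_one(system, omega1_low, ts, 1, offs)$depth
    tibble::tibble(t_sat = ts, depth = d,
                   frac_of_ref = d / ref_depth,
                   meets_ref = d >= 0.9 * ref_depth)
  })
  t90 <- if (any(tab$meets_ref)) min(tab$t_sat[tab$meets_ref]) else NA_real_
  structure(
    list(table = tab, ref_depth = ref_depth, t_sat_90 = t90),
    class = "tsat_tradeoff"
  )
}

#' @export
print.tsat_tradeoff <- function(x, ...) {
  cat(sprintf(
    "<tsat_tradeoff> reference depth %.4g; 90%% reached at t_sat = %s s\n",
    x$ref_depth,
    if (is.na(x$t_sat_90)) "never (on this grid)" else format(x$t_sat_90)))
  print(x$table)
  invisible(x)
}
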
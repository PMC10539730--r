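#' Pointwise depolarization rate from on/off traces
#'
#' Inverts the exponential saturation law pointwise:
#' lambda_hat = -log(on / (off_scale * off)) / t_sat. Working in the
#' rate domain rather than the intensity domain makes the model additive
#' (direct baseline + Lorentzian dips), which is what the dip fitter
#' assumes. Points where the (scaled) off intensity falls below
#' `support_frac` of its maximum — the edges of the chord envelope,
#' where the ratio blows up — are excluded (`lambda_hat = NA`). A
#' non-positive ratio inside the support is clipped to the support
#' threshold and flagged in the `clipped` column.
#'
#' @param data Tibble with columns `on` and `off` (any axis columns,
#'   e.g. `position_m`, `offset_ppm`, `apparent_ppm`, are carried
#'   through).
#' @param t_sat Saturation duration in s (> 0).
#' @param off_scale Scale applied to the off trace; supply the value
#'   used when the data were generated or recorded.
#' @param support_frac Envelope support threshold (default 0.1).
#' @return The input tibble plus columns `lambda_hat` (s^-1, `NA`
#'   outside the support) and `clipped` (logical).
#' @export
saturation_ratio <- function(data, t_sat, off_scale = 1,
                             support_frac = 0.1) {
  stopifnot(all(c("on", "off") %in% names(data)), t_sat > 0,
            off_scale > 0)
  off_corr <- off_scale * data$off
  support <- off_corr >= support_frac * max(off_corr)
  ratio <- data$on / off_corr
  clipped <- support & (ratio <= 0)
  floor_ratio <- support_frac
  ratio[clipped] <- floor_ratio
  lam <- -log(ratio) / t_sat
  lam[!support] <- NA_real_
  out <- data
  out$lambda_hat <- lam
  out$clipped <- clipped & support
  out
}

#' Convert a UFZ apparent axis back to true saturation offsets
#'
#' Undoes the gradient-ratio magnification of the UFZ readout: a
#' feature at `apparent_ppm` was saturated at
#' rf_offset - apparent * (G_sat / G_acq) ppm on the true shift axis.
#'
#' @param apparent_ppm Apparent-ppm value(s) from a UFZ spectrum.
#' @param rf_offset_ppm rf carrier position in ppm.
#' @param gradients A [gradient_scheme()].
#' @return True saturation offset(s) in ppm.
#' @export
apparent_to_offset <- function(apparent_ppm, rf_offset_ppm, gradients) {
  stopifnot(inherits(gradients, "gradient_scheme"))
  rf_offset_ppm - apparent_ppm * gradients$g_sat / gradients$g_acq
}

# running-mean smoother used only for peak seeding, never for fitting
smooth3 <- function(y, k = 5) {
  if (length(y) < k) return(y)
  as.numeric(stats::filter(y, rep(1 / k, k), sides = 2)) |>
    (\(s) ifelse(is.na(s), y, s))()
}

# seed (center, amplitude, fwhm) for the j-th tallest peak of y over x
seed_peaks <- function(x, y, n_dips) {
  ys <- smooth3(y)
  n <- length(ys)
  is_max <- c(FALSE, ys[2:(n - 1)] >= ys[1:(n - 2)] &
                ys[2:(n - 1)] >= ys[3:n], FALSE)
  idx <- which(is_max)
  if (!length(idx)) idx <- which.max(ys)
  idx <- idx[order(ys[idx], decreasing = TRUE)]
  # keep peaks separated by at least 3 samples
  keep <- idx[1]
  for (i in idx[-1]) {
    if (all(abs(i - keep) > 3)) keep <- c(keep, i)
    if (length(keep) >= n_dips) break
  }
  while (length(keep) < n_dips) keep <- c(keep, which.max(ys))
  base0 <- stats::quantile(y, 0.1, names = FALSE)
  purrr::map_dfr(keep[seq_len(n_dips)], function(i) {
    amp <- max(y[i] - base0, .Machine$double.eps)
    half <- base0 + amp / 2
    above <- y >= half
    lo <- i
    while (lo > 1 && above[lo - 1]) lo <- lo - 1
    hi <- i
    while (hi < length(y) && above[hi + 1]) hi <- hi + 1
    fwhm <- abs(x[hi] - x[lo])
    if (fwhm <= 0) fwhm <- abs(x[2] - x[1]) * 3
    tibble::tibble(center = x[i], amp = amp, fwhm = fwhm)
  })
}

#' Fit Lorentzian dips to a depolarization-rate trace
#'
#' Least-squares fit of a constant baseline plus `n_dips` Lorentzian
#' components to lambda(offset):
#' lambda = b + sum_j A_j (G_j^2/4) / (G_j^2/4 + (w - c_j)^2),
#' with the offset axis in rad s^-1 internally so the fitted width
#' G-hat feeds [invert_exchange()] directly. Initial values are seeded
#' from the trace itself (tallest local maxima, half-height crossings).
#'
#' @param data Tibble with an `offset_ppm` column and a rate column
#'   (`lambda_hat` from [saturation_ratio()], or `lambda`). Rows with
#'   `NA` rates are dropped. At least 8 points are required.
#' @param field A [field_config()] (converts the ppm axis to rad s^-1).
#' @param n_dips Number of Lorentzian components (1 or more).
#' @return An object of class `dip_fit`: see [tidy.dip_fit()] and
#'   [glance.dip_fit()]. Components are ordered by center position. A
#'   trace with no discernible dip yields a degenerate fit
#'   (`degenerate = TRUE`, amplitude ~ 0) rather than an error.
#' @examples
#' sys <- exchange_system(field_config(12.09), free_pool(196, 0.1, 10),
#'                        bound_pool(0.037, 50, 52))
#' zs <- z_spectrum(sys, 64.7, 3, seq(40, 64, by = 0.25))
#' fit <- fit_dip(zs, field_config(12.09))
#' tidy(fit)
#' @export
fit_dip <- function(data, field, n_dips = 1) {
  stopifnot(inherits(field, "field_config"), n_dips >= 1)
  ycol <- intersect(c("lambda_hat", "lambda"), names(data))[1]
  if (is.na(ycol)) stop("data must contain a `lambda_hat` or `lambda` column")
  if (!"offset_ppm" %in% names(data)) {
    stop("data must contain an `offset_ppm` column")
  }
  ok <- is.finite(data[[ycol]]) & is.finite(data$offset_ppm)
  x_ppm <- data$offset_ppm[ok]
  y <- data[[ycol]][ok]
  if (length(y) < 8) stop("need at least 8 finite points to fit a dip")
  x <- ppm_to_rad(field, x_ppm)

  span <- max(y) - min(y)
  if (span <= .Machine$double.eps * 100 ||
      span < 1e-6 * max(abs(y), 1e-12)) {
    pars <- tibble::tibble(
      component = seq_len(n_dips),
      center_ppm = rep(stats::median(x_ppm), n_dips),
      lambda_on_hat = 0, gamma_hat = NA_real_,
      se_center = NA_real_, se_lambda_on = NA_real_, se_gamma = NA_real_
    )
    return(structure(
      list(pars = pars, baseline_rate_hat = mean(y), se_baseline = NA_real_,
           goodness = stats::sd(y) * sqrt(length(y)), n = length(y),
           degenerate = TRUE, converged = FALSE, field = field,
           data = tibble::tibble(offset_ppm = x_ppm, lambda = y)),
      class = "dip_fit"
    ))
  }

  seeds <- seed_peaks(x, y, n_dips)
  start <- list(b = stats::quantile(y, 0.1, names = FALSE))
  terms <- character(n_dips)
  for (j in seq_len(n_dips)) {
    start[[paste0("A", j)]] <- seeds$amp[j]
    start[[paste0("c", j)]] <- seeds$center[j]
    start[[paste0("g", j)]] <- seeds$fwhm[j]
    terms[j] <- sprintf("A%d * (g%d^2 / 4) / (g%d^2 / 4 + (x - c%d)^2)",
                        j, j, j, j)
  }
  form <- stats::as.formula(paste("y ~ b +", paste(terms, collapse = " + ")))
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("dip fit failed to converge: ",
                             conditionMessage(e))
  )
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_,
                                                         length(cf)),
                                                     names(cf)))
  pars <- purrr::map_dfr(seq_len(n_dips), function(j) {
    tibble::tibble(
      component = j,
      center_ppm = rad_to_ppm(field, cf[[paste0("c", j)]]),
      lambda_on_hat = cf[[paste0("A", j)]],
      gamma_hat = abs(cf[[paste0("g", j)]]),
      se_center = unname(se[paste0("c", j)]),
      se_lambda_on = unname(se[paste0("A", j)]),
      se_gamma = unname(se[paste0("g", j)])
    )
  })
  pars <- dplyr::arrange(pars, .data$center_ppm)
  pars$component <- seq_len(nrow(pars))
  structure(
    list(pars = pars, baseline_rate_hat = unname(cf[["b"]]),
         se_baseline = unname(se["b"]),
         goodness = sqrt(sum(stats::resid(fit)^2)), n = length(y),
         degenerate = FALSE, converged = TRUE, field = field,
         data = tibble::tibble(offset_ppm = x_ppm, lambda = y)),
    class = "dip_fit"
  )
}

#' @export
print.dip_fit <- function(x, ...) {
  cat(sprintf("<dip_fit> %d component(s), baseline %.4g s^-1, residual norm %.3g%s\n",
              nrow(x$pars), x$baseline_rate_hat, x$goodness,
              if (x$degenerate) " [degenerate: no dip]" else ""))
  print(x$pars)
  invisible(x)
}

#' Tidy a dip fit
#'
#' One row per Lorentzian component: fitted center (true ppm), peak
#' depolarization rate lambda_on (s^-1), FWHM Gamma (rad s^-1), and
#' least-squares standard errors.
#'
#' @param x A `dip_fit` from [fit_dip()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy dip_fit
#' @export
tidy.dip_fit <- function(x, ...) {
  x$pars
}

#' One-line summary of a dip fit
#'
#' @param x A `dip_fit` from [fit_dip()].
#' @param ... Unused.
#' @return A one-row tibble with `baseline_rate_hat`, `goodness`
#'   (residual norm), `n`, `n_components`, `degenerate`, `converged`.
#' @method glance dip_fit
#' @export
glance.dip_fit <- function(x, ...) {
  tibble::tibble(
    baseline_rate_hat = x$baseline_rate_hat,
    goodness = x$goodness,
    n = x$n,
    n_components = nrow(x$pars),
    degenerate = x$degenerate,
    converged = x$converged
  )
}

#' Invert fitted dip observables to exchange parameters
#'
#' The two dip observables determine the two exchange parameters in
#' closed form: the FWHM gives the exit rate,
#' k_out = sqrt(Gamma^2/4 - omega_1^2), and the peak rate then gives
#' the caged fraction, f = lambda_on (omega_1^2 + k_out^2) /
#' (k_out omega_1^2). Identifiability requires Gamma/2 > omega_1 —
#' power broadening must not exhaust the whole width — otherwise the
#' inversion is refused rather than clipped. Uncertainties are
#' first-order propagations of the fit standard errors.
#'
#' @param fit A `dip_fit` from [fit_dip()].
#' @param omega1 rf amplitude used in the experiment, rad s^-1 (> 0).
#' @return A tibble with one row per component: `component`,
#'   `center_ppm`, `f_hat`, `k_out_hat`, `se_f`, `se_k_out`.
#' @export
invert_exchange <- function(fit, omega1) {
  stopifnot(inherits(fit, "dip_fit"), omega1 > 0)
  if (fit$degenerate) {
    stop("cannot invert a degenerate (dipless) fit")
  }
  purrr::map_dfr(seq_len(nrow(fit$pars)), function(j) {
    p <- fit$pars[j, ]
    half_g <- p$gamma_hat / 2
    if (!(half_g > omega1)) {
      stop(sprintf(
        "component %d unidentifiable: fitted half-width %.4g rad/s does not exceed omega1 = %.4g rad/s",
        j, half_g, omega1))
    }
    k_out <- sqrt(half_g^2 - omega1^2)
    f <- p$lambda_on_hat * (omega1^2 + k_out^2) / (k_out * omega1^2)
    # delta-method propagation: dk/dGamma = Gamma / (4 k)
    se_k <- if (is.finite(p$se_gamma)) p$gamma_hat / (4 * k_out) * p$se_gamma
            else NA_real_
    df_dlon <- (omega1^2 + k_out^2) / (k_out * omega1^2)
    # (w1^2+k^2)/(k w1^2) = 1/k + k/w1^2, so d/dk = (k^2 - w1^2)/(k^2 w1^2)
    df_dk <- p$lambda_on_hat * (k_out^2 - omega1^2) / (k_out^2 * omega1^2)
    se_f <- if (is.finite(p$se_lambda_on)) {
      sqrt((df_dlon * p$se_lambda_on)^2 +
             (if (is.finite(se_k)) (df_dk * se_k)^2 else 0))
    } else NA_real_
    tibble::tibble(component = p$component, center_ppm = p$center_ppm,
                   f_hat = f, k_out_hat = k_out, se_f = se_f,
                   se_k_out = se_k)
  })
}
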
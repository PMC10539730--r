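#' Plot a Z spectrum
#'
#' Standard Z-spectrum view: normalized free-pool magnetization against
#' rf offset, with the conventional reversed ppm axis so the free pool
#' sits to the left.
#'
#' @param zs Tibble from [z_spectrum()] or [bm_z_spectrum()].
#' @return A ggplot object.
#' @export
plot_z_spectrum <- function(zs) {
  stopifnot(all(c("offset_ppm", "z_norm") %in% names(zs)))
  ggplot2::ggplot(zs, ggplot2::aes(.data$offset_ppm, .data$z_norm)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "saturation offset (ppm)",
                  y = expression(Z / M[A]^0)) +
    ggplot2::theme_minimal()
}

#' Plot a UFZ spectrum
#'
#' Overlays the on and off profiles and the off - on difference on the
#' apparent-ppm axis, mirroring the way instrument software displays
#' the experiment.
#'
#' @param ufz Tibble from [acquire_ufz()] / [simulate_ufz()].
#' @return A ggplot object.
#' @export
plot_ufz <- function(ufz) {
  stopifnot(all(c("apparent_ppm", "on", "off", "diff") %in% names(ufz)))
  long <- tidyr::pivot_longer(
    ufz[, c("apparent_ppm", "on", "off", "diff")],
    cols = c("on", "off", "diff"),
    names_to = "trace", values_to = "intensity"
  )
  long$trace <- factor(long$trace, levels = c("off", "on", "diff"))
  ggplot2::ggplot(long,
                  ggplot2::aes(.data$apparent_ppm, .data$intensity,
                               colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "apparent shift (ppm)", y = "intensity",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a dip fit over its data
#'
#' Points are the rate-domain data the fit saw; the line is the fitted
#' baseline-plus-Lorentzian model.
#'
#' @param object A `dip_fit` from [fit_dip()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dip_fit
#' @export
autoplot.dip_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(
    offset_ppm = seq(min(d$offset_ppm), max(d$offset_ppm),
                     length.out = 400)
  )
  grid$lambda <- predict_lambda(object, grid$offset_ppm)
  ggplot2::ggplot(d, ggplot2::aes(.data$offset_ppm, .data$lambda)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "saturation offset (ppm)",
                  y = expression(hat(lambda) ~ (s^{-1}))) +
    ggplot2::theme_minimal()
}

#' Evaluate a fitted dip model
#'
#' @param fit A `dip_fit` from [fit_dip()].
#' @param offset_ppm Offsets (ppm) at which to evaluate the fitted
#'   baseline + Lorentzian model.
#' @return Modelled depolarization rates in s^-1.
#' @export
predict_lambda <- function(fit, offset_ppm) {
  stopifnot(inherits(fit, "dip_fit"))
  x <- ppm_to_rad(fit$field, offset_ppm)
  y <- rep(fit$baseline_rate_hat, length(x))
  for (j in seq_len(nrow(fit$pars))) {
    p <- fit$pars[j, ]
    if (!is.finite(p$gamma_hat)) next
    c_rad <- ppm_to_rad(fit$field, p$center_ppm)
    g2_4 <- (p$gamma_hat / 2)^2
    y <- y + p$lambda_on_hat * g2_4 / (g2_4 + (x - c_rad)^2)
  }
  y
}
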
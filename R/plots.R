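## ggplot2 figures for the main result types.

#' Plot a density profile along the membrane normal
#'
#' @param profile Tibble from [density_profile()].
#' @param fill Bar fill colour.
#' @return A ggplot.
#' @export
plot_density_profile <- function(profile, fill = "steelblue") {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$z_mid, y = .data$density)) +
    ggplot2::geom_col(width = profile$z_hi[1] - profile$z_lo[1],
                      fill = fill, colour = NA) +
    ggplot2::labs(x = "z (Å)", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a transmembrane potential fraction profile
#'
#' @param profile Tibble with `z`, `f` from [potential_fraction_profile()].
#' @return A ggplot.
#' @export
plot_f_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$z, y = .data$f)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = c(0, 1), linetype = "dotted") +
    ggplot2::labs(x = "z (Å)", y = "f(z)") +
    ggplot2::theme_minimal()
}

#' Plot per-voltage peak wavelengths with their linear trend
#'
#' @param spectra Tibble with `v_mp` and `absorption`/`emission` columns
#'   (e.g. `run_end_to_end()$spectra`).
#' @param transition `"emission"` or `"absorption"`.
#' @param fit Optional `voltage_fit` whose windowed trend line is drawn.
#' @return A ggplot.
#' @export
plot_voltage_response <- function(spectra, transition = c("emission", "absorption"),
                                  fit = NULL) {
  transition <- rlang::arg_match(transition)
  df <- tibble(v_mp = spectra$v_mp, lambda = spectra[[transition]])
  se_name <- if (transition == "emission") "se_em" else "se_ab"
  if (se_name %in% names(spectra)) df$se <- spectra[[se_name]]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$v_mp, y = .data$lambda)) +
    ggplot2::geom_point(size = 2)
  if ("se" %in% names(df) && !all(is.na(df$se))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lambda - .data$se,
                   ymax = .data$lambda + .data$se),
      width = 20
    )
  }
  if (!is.null(fit)) {
    co <- coef(fit$fit)
    p <- p + ggplot2::geom_function(
      fun = function(v) co[1] + co[2] * v,
      xlim = fit$window, colour = "black"
    )
  }
  p +
    ggplot2::labs(x = "membrane potential (mV)",
                  y = sprintf("%s peak (nm)", transition)) +
    ggplot2::theme_minimal()
}

#' Plot a fitted Lorentzian line shape over its spectrum
#' @param object A `lineshape_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lineshape_fit
#' @export
autoplot.lineshape_fit <- function(object, ...) {
  co <- coef(object$fit)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$lambda, y = .data$intensity)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_function(
      fun = function(l) co["i_max"] * co["half_width"]^2 /
        ((l - co["peak"])^2 + co["half_width"]^2),
      colour = "firebrick"
    ) +
    ggplot2::labs(x = "wavelength (nm)", y = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot a voltage-response fit with its data
#' @param object A `voltage_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot voltage_fit
#' @export
autoplot.voltage_fit <- function(object, ...) {
  plot_voltage_response(
    tibble(v_mp = object$all_points$v_mp,
           emission = object$all_points$lambda),
    "emission", fit = object
  )
}
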
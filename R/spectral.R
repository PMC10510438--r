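## Spectral mapping: energy-gap ensembles -> wavelengths, Stokes shifts,
## voltage-response fits.

gap_values <- function(series) {
  g <- if (is.data.frame(series)) series$gap else series
  if (is.null(g) || length(g) == 0L || any(!is.finite(g))) {
    abort_anepps("Energy-gap series must be nonempty finite values (a numeric vector or a tibble with a `gap` column).",
                 "bad_series")
  }
  g
}

#' Peak wavelength from an energy-gap ensemble
#'
#' Converts a per-frame excited-minus-ground energy-gap series into a peak
#' transition wavelength: the gaps are averaged first, an empirical
#' vibrational offset is subtracted, and the mean is inverted through
#' `lambda = hc_molar / (<dE> - offset)`. Sampling the gaps on the
#' ground-state trajectory with the absorption offset gives the absorption
#' peak; sampling on the excited-state trajectory with the emission offset
#' gives the emission peak. The standard error is propagated to first order
#' from the block-average SE of the mean gap,
#' `se(lambda) = lambda^2 se(<dE>) / hc_molar`.
#'
#' @param series Tibble with a `gap` column (kcal/mol) or numeric vector.
#' @param offset Voltage-independent offset, kcal/mol (see
#'   [default_offsets]). The effective energy `<dE> - offset` must stay
#'   positive.
#' @param n_blocks Blocks for the SE of the mean gap; default 10.
#' @return One-row tibble with `lambda` (nm), `se` (nm), `mean_gap`,
#'   `se_gap` (kcal/mol), `n`.
#' @examples
#' wavelength_from_gaps(rep(hc_molar / 500, 10), offset = 0)
#' @export
wavelength_from_gaps <- function(series, offset, n_blocks = 10) {
  g <- gap_values(series)
  ba <- if (length(g) == 1L) {
    tibble(mean = g, se = NA_real_, n = 1L, n_blocks = NA_integer_)
  } else {
    block_average(g, n_blocks = min(n_blocks, length(g)))
  }
  e_eff <- ba$mean - offset
  if (e_eff <= 0) {
    abort_anepps(
      sprintf("Offset %.4g leaves a non-positive effective transition energy (mean gap %.4g kcal/mol).",
              offset, ba$mean),
      "nonpositive_energy"
    )
  }
  lambda <- hc_molar / e_eff
  tibble(
    lambda = lambda,
    se = lambda^2 * ba$se / hc_molar,
    mean_gap = ba$mean,
    se_gap = ba$se,
    n = ba$n
  )
}

#' Calibrate an empirical offset against a reference wavelength
#'
#' Solves for the voltage-independent offset that makes
#' [wavelength_from_gaps()] reproduce a reference (measured) wavelength for
#' the given gap ensemble: `offset = <dE> - hc_molar / lambda_ref`. The pair
#' of operations round-trips exactly.
#'
#' @inheritParams wavelength_from_gaps
#' @param lambda_ref Reference peak wavelength, nm; positive.
#' @return Offset in kcal/mol.
#' @export
offset_from_reference <- function(series, lambda_ref) {
  if (!is.numeric(lambda_ref) || lambda_ref <= 0) {
    abort_anepps("`lambda_ref` must be a positive wavelength in nm.",
                 "bad_wavelength")
  }
  mean(gap_values(series)) - hc_molar / lambda_ref
}

#' Stokes shift
#'
#' Emission minus absorption peak wavelength, nm. Vectorized.
#'
#' @param lambda_ab,lambda_em Absorption and emission peak wavelengths, nm.
#' @return Stokes shift(s), nm.
#' @export
stokes_shift <- function(lambda_ab, lambda_em) {
  if (any(lambda_ab <= 0) || any(lambda_em <= 0)) {
    abort_anepps("Wavelengths must be positive.", "bad_wavelength")
  }
  lambda_em - lambda_ab
}

#' Linear voltage response of a peak wavelength
#'
#' Ordinary least-squares fit of peak wavelength against applied membrane
#' potential, restricted to a voltage window. Probe responses are linear
#' only in a physiological range; the default window of +/-100 mV excludes
#' the +/-500 mV extremes, which lie well outside the linear-response
#' regime.
#'
#' @param points Data frame with columns `v_mp` (mV) and `lambda` (nm).
#' @param window Length-2 voltage window `c(min, max)` in mV; at least two
#'   points must fall inside (inclusive).
#' @return Object of class `voltage_fit`: the underlying [stats::lm] plus
#'   the window and data. Use [tidy()]/[glance()] or
#'   `shift_per_100mV()` on it.
#' @export
fit_voltage_response <- function(points, window = c(-100, 100)) {
  if (is.null(points$v_mp) || is.null(points$lambda)) {
    abort_anepps("`points` must have columns `v_mp` and `lambda`.",
                 "bad_points")
  }
  if (length(window) != 2L || window[1] >= window[2]) {
    abort_anepps("`window` must be c(min, max) with min < max.", "bad_window")
  }
  sub <- points[points$v_mp >= window[1] & points$v_mp <= window[2], ]
  if (nrow(sub) < 2L || length(unique(sub$v_mp)) < 2L) {
    abort_anepps(
      sprintf("Need >= 2 distinct voltages inside [%g, %g] mV; found %d point(s).",
              window[1], window[2], nrow(sub)),
      "too_few_points"
    )
  }
  fit <- lm(lambda ~ v_mp, data = sub)
  structure(
    list(fit = fit, window = window, data = as_tibble(sub),
         all_points = as_tibble(points)),
    class = "voltage_fit"
  )
}

#' Slope of a voltage fit expressed per 100 mV
#'
#' @param x A `voltage_fit`.
#' @param signed Return the signed slope (default reports the magnitude).
#' @return Wavelength change in nm per 100 mV.
#' @export
shift_per_100mV <- function(x, signed = FALSE) {
  stopifnot(inherits(x, "voltage_fit"))
  s <- unname(coef(x$fit)["v_mp"]) * 100
  if (signed) s else abs(s)
}

#' @export
print.voltage_fit <- function(x, ...) {
  co <- coef(x$fit)
  cat(sprintf(
    "<voltage_fit> lambda = %.4f %+.6f * V_mp  (window [%g, %g] mV, %d points)\n",
    co[1], co[2], x$window[1], x$window[2], nrow(x$data)
  ))
  cat(sprintf("  |slope| = %.4f nm per 100 mV\n", shift_per_100mV(x)))
  invisible(x)
}

#' Average wavelength shift per 100 mV between voltage extremes
#'
#' Endpoint estimate over the full voltage span:
#' `|lambda(v_min) - lambda(v_max)| / (span / 100)`. Complements the
#' windowed least-squares slope of [fit_voltage_response()]; the two differ
#' when the response is nonlinear at extreme voltages.
#'
#' @inheritParams fit_voltage_response
#' @return Shift in nm per 100 mV.
#' @export
average_shift_per_100mV <- function(points) {
  if (is.null(points$v_mp) || is.null(points$lambda) || nrow(points) < 2L) {
    abort_anepps("`points` must have >= 2 rows with `v_mp` and `lambda`.",
                 "bad_points")
  }
  span <- max(points$v_mp) - min(points$v_mp)
  if (span == 0) {
    abort_anepps("All voltages are identical; no span to average over.",
                 "bad_points")
  }
  l_lo <- mean(points$lambda[points$v_mp == min(points$v_mp)])
  l_hi <- mean(points$lambda[points$v_mp == max(points$v_mp)])
  abs(l_lo - l_hi) / (span / 100)
}
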
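## broom-style tidiers for the fitted objects.

#' Tidy a voltage-response fit
#'
#' @param x A `voltage_fit` from [fit_voltage_response()].
#' @param ... Unused.
#' @return Tibble with one row per model term: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.voltage_fit <- function(x, ...) {
  co <- coef(summary(x$fit))
  tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std.error = co[, "Std. Error"],
    statistic = co[, "t value"],
    p.value = co[, "Pr(>|t|)"]
  )
}

#' Glance at a voltage-response fit
#'
#' @inheritParams tidy.voltage_fit
#' @return One-row tibble: `r.squared`, `sigma`, `nobs`, `slope_nm_per_mV`,
#'   `shift_nm_per_100mV` (magnitude), `window_lo`, `window_hi`.
#' @export
glance.voltage_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    r.squared = s$r.squared,
    sigma = s$sigma,
    nobs = nrow(x$data),
    slope_nm_per_mV = unname(coef(x$fit)["v_mp"]),
    shift_nm_per_100mV = shift_per_100mV(x),
    window_lo = x$window[1],
    window_hi = x$window[2]
  )
}

#' Tidy a Lorentzian line-shape fit
#'
#' @param x A `lineshape_fit` from [fit_lineshape()].
#' @param ... Unused.
#' @return Tibble with rows for `i_max`, `half_width`, `peak`.
#' @export
tidy.lineshape_fit <- function(x, ...) {
  co <- coef(summary(x$fit))
  tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std.error = co[, "Std. Error"],
    statistic = co[, "t value"],
    p.value = co[, "Pr(>|t|)"]
  )
}

#' Glance at a Lorentzian line-shape fit
#'
#' @inheritParams tidy.lineshape_fit
#' @return One-row tibble: `rss`, `sigma`, `nobs`, `isConv`,
#'   `finTol`.
#' @export
glance.lineshape_fit <- function(x, ...) {
  ci <- x$fit$convInfo
  tibble(
    rss = sum(stats::residuals(x$fit)^2),
    sigma = summary(x$fit)$sigma,
    nobs = nrow(x$data),
    isConv = ci$isConv,
    finTol = ci$finTol
  )
}
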
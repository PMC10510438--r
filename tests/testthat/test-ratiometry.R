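ls_pub <- kao_lineshape()

test_that("line shape peaks at i_max and halves at one half-width", {
  for (v in c(0, -100, 500)) {
    pk <- peak_position(ls_pub, v)
    expect_equal(lineshape_eval(ls_pub, pk, v), 153.4)
    expect_equal(lineshape_eval(ls_pub, pk + 51.1, v), 153.4 / 2)
    expect_equal(lineshape_eval(ls_pub, pk - 51.1, v), 153.4 / 2)
  }
  expect_equal(lineshape_eval(ls_pub, 620, 0),
               lorentz_oracle(620, 153.4, 51.1, 605.97))
  expect_equal(lineshape_eval(ls_pub, 620, 0), 142.65, tolerance = 1e-4)
})

test_that("line shape is symmetric about its peak and maximised there", {
  withr::with_seed(16, {
    for (i in 1:20) {
      d <- stats::runif(1, 0.1, 80)
      v <- stats::runif(1, -500, 500)
      pk <- peak_position(ls_pub, v)
      expect_equal(lineshape_eval(ls_pub, pk + d, v),
                   lineshape_eval(ls_pub, pk - d, v))
      expect_lt(lineshape_eval(ls_pub, pk + d, v),
                lineshape_eval(ls_pub, pk, v))
    }
  })
})

test_that("peak positions reproduce the published voltage-deduced values", {
  expect_equal(round(peak_position(ls_pub, 0), 1), 606.0)
  expect_equal(round(peak_position(ls_pub, -500), 1), 609.5)
  flat <- lorentzian_lineshape(100, 50, 600, 0)
  expect_equal(peak_position(flat, c(-500, 0, 500)), rep(600, 3))
})

test_that("dual ratio matches closed-form evaluation and ignores i_max", {
  expect_equal(dual_ratio(ls_pub, 0, 610, 610), 1)
  expect_equal(dual_ratio(ls_pub, 0), 1.6826, tolerance = 1e-4)
  expect_equal(dual_ratio(ls_pub, -100), 1.7178, tolerance = 1e-4)
  expect_equal(dual_ratio(ls_pub, 0),
               lorentz_oracle(620, 153.4, 51.1, 605.97) /
                 lorentz_oracle(560, 153.4, 51.1, 605.97))

  withr::with_seed(17, {
    for (i in 1:10) {
      scale <- stats::runif(1, 0.01, 1000)
      scaled <- lorentzian_lineshape(153.4 * scale, 51.1, 605.97, -0.0071)
      v <- stats::runif(1, -200, 200)
      expect_equal(dual_ratio(scaled, v), dual_ratio(ls_pub, v))
    }
  })
})

test_that("relative ratio change reproduces the measured calibration line", {
  expect_equal(relative_ratio_change(ls_pub, -100), 0)
  d0 <- relative_ratio_change(ls_pub, 0)
  expect_equal(signif(d0, 2), signif(-0.0352, 2))
  expect_equal(signif(abs(d0) / 100, 2), signif(0.000352, 2))
})

test_that("the half-width-at-half-maximum convention is the only one that fits", {
  fwhm <- lorentzian_lineshape(153.4, 51.1 / 2, 605.97, -0.0071)
  d_fwhm <- relative_ratio_change(fwhm, 0)
  expect_equal(d_fwhm, -0.155, tolerance = 0.01)
  expect_false(isTRUE(all.equal(signif(d_fwhm, 2), signif(-0.0352, 2))))
})

test_that("noiseless spectra are recovered exactly by the line-shape fit", {
  lam <- seq(480, 720, length.out = 50)
  spec <- tibble::tibble(lambda = lam,
                         intensity = lorentz_oracle(lam, 153.4, 51.1, 605.97))
  fit <- fit_lineshape(spec)
  co <- stats::coef(fit$fit)
  expect_equal(unname(co[c("i_max", "half_width", "peak")]),
               c(153.4, 51.1, 605.97), tolerance = 1e-6)
  expect_lt(glance(fit)$rss, 1e-10)
  ls2 <- as_lineshape(fit)
  expect_s3_class(ls2, "lorentzian_lineshape")
  expect_equal(ls2$peak0, 605.97, tolerance = 1e-6)
})

test_that("noisy spectra are recovered within three reported standard errors", {
  lam <- seq(480, 720, length.out = 50)
  truth <- c(i_max = 153.4, half_width = 51.1, peak = 605.97)
  withr::with_seed(18, {
    spec <- tibble::tibble(
      lambda = lam,
      intensity = lorentz_oracle(lam, 153.4, 51.1, 605.97) + rnorm(50, 0, 1)
    )
  })
  fit <- fit_lineshape(spec)
  td <- tidy(fit)
  for (p in names(truth)) {
    row <- td[td$term == p, ]
    expect_lt(abs(row$estimate - truth[[p]]), 3 * row$std.error)
  }
})

test_that("line-shape fit rejects underdetermined spectra", {
  spec <- tibble::tibble(lambda = c(600, 610), intensity = c(100, 120))
  expect_error(fit_lineshape(spec), class = "anepps_error_too_few_points")
})

test_that("inverting the measured ratiometric slope recovers the published peak shift", {
  ps <- invert_ratio_slope(51.1, 605.97, 3.52e-4)
  expect_equal(round(abs(ps) * 100, 3), 0.710)
  expect_equal(invert_ratio_slope(51.1, 605.97, 0), 0)
})

test_that("forward and inverse ratio-slope conversion round-trip within 1%", {
  withr::with_seed(19, {
    for (i in 1:20) {
      slope <- stats::runif(1, -0.01, 0.01)  # |slope|*100 <= 1 nm
      hw <- stats::runif(1, 30, 70)
      pk <- stats::runif(1, 580, 630)
      ls <- lorentzian_lineshape(100, hw, pk, slope)
      fd <- ratio_slope_fd(ls, -50, 50)
      got <- invert_ratio_slope(hw, pk, fd)
      if (abs(slope) > 1e-4) {
        expect_lt(abs(got - slope) / abs(slope), 0.01)
        expect_identical(sign(got), sign(slope))
      }
    }
  })
})

test_that("ratiometric calibration report matches its components", {
  cal <- calibrate_ratiometry(ls_pub, voltages = c(-100, 0, 100))
  expect_equal(cal$changes$delta_ratio[cal$changes$v_mp == 0],
               relative_ratio_change(ls_pub, 0))
  expect_equal(cal$ratio_slope_per_mV, abs(relative_ratio_change(ls_pub, 0)) / 100)
  expect_equal(round(cal$peak_shift_per_100mV, 2), 0.71)
})
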
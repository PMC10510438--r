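test_that("zero-noise gap series is exactly constant at its mean", {
  spec <- tibble::tibble(mu0 = 59.8181, kappa = 0, sigma = 0, rho = 0.5)
  g <- generate_energy_gap_series(spec, "es", 0, 100, seed = 1)
  expect_tibble_cols(g, c("frame", "gap", "state", "v_mp"))
  expect_identical(g$frame, 1:100)
  expect_true(all(g$gap == 59.8181))
})

test_that("gap series recovers stationary mean, SD and lag-1 autocorrelation", {
  spec <- tibble::tibble(mu0 = 67.0694, kappa = 0, sigma = 2, rho = 0)
  g <- generate_energy_gap_series(spec, "gs", 0, 1e5, seed = 11)
  expect_lt(abs(mean(g$gap) - 67.0694), 3 * 2 / sqrt(1e5))

  spec2 <- tibble::tibble(mu0 = 0, kappa = 0, sigma = 1, rho = 0.8)
  g2 <- generate_energy_gap_series(spec2, "gs", 0, 1e5, seed = 12)$gap
  rho_hat <- stats::cor(g2[-1], g2[-length(g2)])
  expect_lt(abs(rho_hat - 0.8), 0.02)
  expect_lt(abs(stats::sd(g2) - 1), 0.03)
})

test_that("kappa shifts the stationary mean linearly in voltage", {
  spec <- tibble::tibble(mu0 = 60, kappa = 0.002, sigma = 0, rho = 0)
  g <- generate_energy_gap_series(spec, "es", -500, 10, seed = 1)
  expect_equal(unique(g$gap), 60 - 1)
})

test_that("generators are bit-identical for a fixed seed", {
  spec <- gap_gen_defaults("es", 0)
  a <- generate_energy_gap_series(spec, "es", 0, 500, seed = 7)
  b <- generate_energy_gap_series(spec, "es", 0, 500, seed = 7)
  expect_identical(a, b)
  ta <- generate_atom_tracks(track_gen_defaults("gs", 100), "gs", 100, 200, seed = 7)
  tb <- generate_atom_tracks(track_gen_defaults("gs", 100), "gs", 100, 200, seed = 7)
  expect_identical(ta, tb)
  oa <- generate_orientation_series(48.3, 17.6, 200, seed = 7)
  ob <- generate_orientation_series(48.3, 17.6, 200, seed = 7)
  expect_identical(oa, ob)
  prof <- tibble::tibble(z = c(-20, 20), f = c(0, 1))
  ga <- generate_potential_grids(prof, 100, c(8, 8, 40), 2, noise_sd = 3, seed = 7)
  gb <- generate_potential_grids(prof, 100, c(8, 8, 40), 2, noise_sd = 3, seed = 7)
  expect_identical(ga, gb)
})

test_that("generators do not disturb the global RNG stream", {
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(generate_energy_gap_series(gap_gen_defaults("gs", 0), "gs", 0, 10, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("gap generator rejects invalid inputs with explanatory errors", {
  spec <- tibble::tibble(mu0 = 60, kappa = 0, sigma = 2, rho = 0.5)
  expect_error(generate_energy_gap_series(spec, "gs", 0, 0, 1),
               class = "anepps_error_bad_n_frames")
  bad <- tibble::tibble(mu0 = 60, kappa = 0, sigma = -1, rho = 0.5)
  expect_error(generate_energy_gap_series(bad, "gs", 0, 10, 1),
               class = "anepps_error_bad_sigma")
  badr <- tibble::tibble(mu0 = 60, kappa = 0, sigma = 1, rho = 1)
  expect_error(generate_energy_gap_series(badr, "gs", 0, 10, 1),
               class = "anepps_error_bad_rho")
  expect_error(generate_energy_gap_series(spec, "solvated", 0, 10, 1),
               class = "anepps_error_bad_state")
})

test_that("atom tracks honour per-label means and reject unknown labels", {
  spec <- track_gen_defaults("es", 0)
  spec$sd <- 0
  tr <- generate_atom_tracks(spec, "es", 0, 50, seed = 1)
  expect_true(all(tr$z[tr$label == "N2"] == 7.5))

  tr1 <- generate_atom_tracks(spec, "es", 0, 1, seed = 1)
  expect_identical(nrow(tr1[tr1$label == "S", ]), 1L)
  expect_equal(tr1$z[tr1$label == "S"], spec$mean[spec$label == "S"])

  expect_error(
    generate_atom_tracks(spec, "es", 0, 10, 1, labels = "P_headgroup"),
    class = "anepps_error_unknown_label"
  )
})

test_that("sulfur track recovers the reference ground-state mean depth", {
  tr <- generate_atom_tracks(track_gen_defaults("gs", 0), "gs", 0, 1e5,
                             seed = 21, labels = "S")
  se <- 2.5 * sqrt((1 + 0.5) / (1 - 0.5)) / sqrt(1e5)
  expect_lt(abs(mean(tr$z) - 22.1), 3 * se)
})

test_that("orientation series yields unit vectors with prescribed tilt stats", {
  o0 <- generate_orientation_series(0, 0, 20, seed = 1)
  expect_true(all(o0$x == 0 & o0$y == 0 & o0$z == 1))

  o90 <- generate_orientation_series(90, 0, 20, seed = 1)
  expect_equal(tilt_angle(o90), rep(90, 20))

  o <- generate_orientation_series(48.3, 17.6, 1e5, seed = 2)
  norms <- sqrt(o$x^2 + o$y^2 + o$z^2)
  expect_lt(max(abs(norms - 1)), 1e-9)
  tilt <- tilt_angle(o)
  expect_lt(abs(mean(tilt) - 48.3), 0.5)
  expect_lt(abs(stats::sd(tilt) - 17.6), 0.5)

  expect_error(generate_orientation_series(48.3, -1, 10, 1),
               class = "anepps_error_bad_sigma")
  expect_error(generate_orientation_series(200, 5, 10, 1),
               class = "anepps_error_bad_tilt")
})

test_that("moment-matched truncation also holds for broad low-mean tilts", {
  # naive truncation at 0 degrees would bias this cell by ~1 degree
  o <- generate_orientation_series(25.9, 14.1, 1e5, seed = 3)
  tilt <- tilt_angle(o)
  expect_lt(abs(mean(tilt) - 25.9), 0.5)
  expect_lt(abs(stats::sd(tilt) - 14.1), 0.5)
})

test_that("synthetic grid pairs encode v_mp * f(z) exactly when noiseless", {
  zs <- seq(-20, 18, by = 2)
  prof <- tibble::tibble(z = seq(-20, 20, 1),
                         f = stats::plogis(seq(-20, 20, 1) / 3))
  gr <- generate_potential_grids(prof, -500, c(10, 10, 40), 2, noise_sd = 0,
                                 seed = 1)
  rec <- potential_fraction_profile(gr$biased, gr$reference, -500)
  expect_equal(rec$z, zs)
  expect_equal(rec$f, interpolate_f(prof, zs), tolerance = 1e-12)

  flat <- tibble::tibble(z = c(-20, 20), f = c(0, 0))
  gr0 <- generate_potential_grids(flat, 100, c(40, 40, 20), c(1, 1, 2),
                                  noise_sd = 5, seed = 2)
  rec0 <- potential_fraction_profile(gr0$biased, gr0$reference, 100)
  expect_lt(max(abs(rec0$f)), 3 * (5 / 100) / sqrt(1600))
})

test_that("grid generator rejects degenerate geometry", {
  prof <- tibble::tibble(z = c(-20, 20), f = c(0, 1))
  expect_error(generate_potential_grids(prof, 0, c(10, 10, 40), 2),
               class = "anepps_error_zero_voltage")
  expect_error(generate_potential_grids(prof, 100, c(10, 10, 40), -1),
               class = "anepps_error_bad_spacing")
  expect_error(generate_potential_grids(prof, 100, c(10, 10, 41), 2),
               class = "anepps_error_bad_spacing")
})

test_that("bundled generator defaults tie back to the reference tables", {
  gd <- gap_gen_defaults("es", 0)
  expect_equal(hc_molar / (gd$mu0 - default_offsets[["emission"]]),
               reference_spectra$emission[reference_spectra$v_mp == 0])
  gd_ab <- gap_gen_defaults("gs", -500)
  expect_equal(hc_molar / (gd_ab$mu0 - default_offsets[["absorption"]]),
               reference_spectra$absorption[reference_spectra$v_mp == -500])
  td <- track_gen_defaults("es", 0)
  expect_setequal(td$label, atom_labels)
  expect_equal(td$mean[td$label == "N2"], 7.5)
  od <- orientation_gen_defaults("gs", 0)
  expect_equal(od$mean_tilt, 25.9)
  expect_error(gap_gen_defaults("gs", 250),
               class = "anepps_error_unknown_condition")
})
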
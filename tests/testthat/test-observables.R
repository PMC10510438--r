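test_that("tilt_angle handles closed-form geometries", {
  expect_equal(tilt_angle(c(0, 0, 1)), 0)
  expect_equal(tilt_angle(c(1, 0, 0)), 90)
  expect_equal(tilt_angle(c(1, 0, 1)), 45)
  expect_equal(tilt_angle(c(0, 0, -2)), 180)  # unfolded, not reflected
  expect_error(tilt_angle(c(0, 0, 0)), class = "anepps_error_zero_vector")
})

test_that("tilt_angle is invariant to positive rescaling of either vector", {
  withr::with_seed(5, {
    for (i in 1:25) {
      v <- rnorm(3)
      n <- rnorm(3)
      s <- stats::runif(2, 0.01, 100)
      expect_equal(tilt_angle(v * s[1], n * s[2]), tilt_angle(v, n),
                   tolerance = 1e-10)
    }
  })
})

test_that("density_profile conserves counts and normalises its peak", {
  same <- rep(7.5, 10)
  dp <- density_profile(same, 0.5, "unit_peak")
  expect_identical(sum(dp$density > 0), 1L)
  expect_equal(max(dp$density), 1)

  withr::with_seed(8, {
    z <- rnorm(5000, 7.5, 2.4)
    dc <- density_profile(z, 0.5, "count")
    expect_equal(sum(dc$density), 5000)
    expect_true(all(diff(dc$z_lo) > 0))
  })
  expect_error(density_profile(numeric(0)), class = "anepps_error_empty_samples")
  expect_error(density_profile(1:3, bin_width = 0), class = "anepps_error_bad_bin_width")
})

test_that("density_profile recovers the first moment of its samples", {
  withr::with_seed(9, z <- rnorm(1e5, 7.5, 2.4))
  dp <- density_profile(z, 0.5, "count")
  m <- sum(dp$z_mid * dp$density) / sum(dp$density)
  # binning adds at most bin_width/2 of quantisation on top of 3 SE
  expect_lt(abs(m - 7.5), 3 * 2.4 / sqrt(1e5) + 0.25)
})

test_that("block_average matches hand arithmetic and handles edge cases", {
  expect_equal(block_average(rep(3, 50))$se, 0)
  ba <- block_average(1:6, 3)
  expect_equal(ba$mean, 3.5)
  expect_equal(ba$se, stats::sd(c(1.5, 3.5, 5.5)) / sqrt(3))
  expect_equal(ba$se, 1.154701, tolerance = 1e-6)
  expect_error(block_average(1:5, 6), class = "anepps_error_bad_blocks")
  expect_error(block_average(1:5, 1), class = "anepps_error_bad_blocks")
})

test_that("block_average agrees with a brute-force oracle on short series", {
  withr::with_seed(10, {
    for (i in 1:40) {
      n <- sample(4:100, 1)
      x <- rnorm(n, sample(-5:5, 1), stats::runif(1, 0.1, 3))
      k <- sample(2:min(10, n), 1)
      got <- block_average(x, k)
      want <- block_oracle(x, k)
      expect_equal(got$mean, want$mean)
      expect_equal(got$se, want$se)
    }
  })
})

test_that("block_average with singleton blocks reduces to the iid formula", {
  withr::with_seed(11, x <- rnorm(64))
  ba <- block_average(x, n_blocks = 64)
  expect_equal(ba$se, stats::sd(x) / sqrt(64))
})

test_that("block SE of iid noise is near the sampling-theory value", {
  withr::with_seed(12, x <- rnorm(1e5))
  ba <- block_average(x, 10)
  expect_gt(ba$se, 0.5 / sqrt(1e5))
  expect_lt(ba$se, 2 / sqrt(1e5))
})

test_that("summarize_condition reports exact moments for noiseless input", {
  spec <- track_gen_defaults("es", 0)
  spec$sd <- 0
  tr <- generate_atom_tracks(spec, "es", 0, 100, seed = 1)
  or <- generate_orientation_series(48.3, 0, 100, seed = 1)
  sm <- summarize_condition(tr, or, "es", 0)
  expect_tibble_cols(sm, c("state", "v_mp", "quantity", "mean", "sd", "se", "n_frames"))
  expect_true(all(sm$sd[sm$quantity != "tilt"] == 0))
  expect_lt(sm$sd[sm$quantity == "tilt"], 1e-9)  # tilt recomputed from vectors
  expect_equal(sm$mean[sm$quantity == "N2"], 7.5)
  expect_equal(sm$mean[sm$quantity == "tilt"], 48.3)
  expect_true(all(sm$n_frames == 100))
})

test_that("summarize_condition records the snapshot count and checks lengths", {
  tr <- generate_atom_tracks(track_gen_defaults("gs", 0), "gs", 0, 10000, seed = 2)
  or <- generate_orientation_series(25.9, 14.1, 10000, seed = 3)
  sm <- summarize_condition(tr, or, "gs", 0)
  expect_true(all(sm$n_frames == 10000L))

  or_short <- generate_orientation_series(25.9, 14.1, 500, seed = 3)
  expect_error(summarize_condition(tr, or_short, "gs", 0),
               class = "anepps_error_length_mismatch")
})

test_that("excited-state tilt is recovered from synthetic defaults", {
  tr <- generate_atom_tracks(track_gen_defaults("es", 0), "es", 0, 1e5, seed = 4)
  od <- orientation_gen_defaults("es", 0)
  or <- generate_orientation_series(od$mean_tilt, od$tilt_sd, 1e5, seed = 5)
  sm <- summarize_condition(tr, or, "es", 0)
  expect_lt(abs(sm$mean[sm$quantity == "tilt"] - 48.3), 0.5)
})

test_that("range_of_motion reproduces the published extreme-voltage shifts", {
  ref <- reference_configuration
  es <- ref[ref$state == "es", ]
  es$quantity <- es$quantity  # columns v_mp, quantity, mean already present
  expect_equal(range_of_motion(es, "N2"), 1.3)
  gs <- ref[ref$state == "gs", ]
  expect_equal(range_of_motion(gs, "S"), 0.4)

  flat <- tibble::tibble(v_mp = c(-500, 500), quantity = "S", mean = c(22, 22))
  expect_equal(range_of_motion(flat, "S"), 0)
  expect_error(range_of_motion(flat, "N7"), class = "anepps_error_unknown_label")
})
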
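# Independent brute-force oracles used across tests.

# Block-average oracle: explicit per-block loop, remainder to the last block.
block_oracle <- function(x, k) {
  n <- length(x)
  size <- n %/% k
  bm <- numeric(k)
  for (b in seq_len(k)) {
    lo <- (b - 1L) * size + 1L
    hi <- if (b == k) n else b * size
    bm[b] <- mean(x[lo:hi])
  }
  list(mean = mean(x), se = stats::sd(bm) / sqrt(k))
}

# Lorentzian evaluated longhand (HWHM convention), independent of the
# package implementation.
lorentz_oracle <- function(lambda, i_max, hwhm, peak) {
  i_max * hwhm^2 / ((lambda - peak)^2 + hwhm^2)
}

# Finite-difference slope of the dual-wavelength ratio for a given line
# shape, via the forward model only.
ratio_slope_fd <- function(ls, v1, v2, num = 620, den = 560) {
  (dual_ratio(ls, v2, num, den) - dual_ratio(ls, v1, num, den)) / (v2 - v1)
}

expect_tibble_cols <- function(x, cols) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(cols %in% names(x)))
}
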
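## Configurational observables: tilt, density profiles, per-condition
## summaries, range of motion, and block-average uncertainties.

#' Tilt angle between a molecular axis and the membrane normal
#'
#' Unfolded angle in `[0, 180]` degrees between two directions; for the
#' probe this is the angle between the N1-N2 axis of the conjugated ring
#' system and the +z membrane normal. Invariant to positive rescaling of
#' either vector.
#'
#' @param axis Numeric length-3 vector, or an n-by-3 matrix / data frame
#'   with columns `x`, `y`, `z` for a per-frame series.
#' @param normal Membrane normal; default +z.
#' @return Angle(s) in degrees.
#' @examples
#' tilt_angle(c(1, 0, 1))  # 45
#' @export
tilt_angle <- function(axis, normal = c(0, 0, 1)) {
  if (is.data.frame(axis)) {
    axis <- as.matrix(axis[, c("x", "y", "z")])
  }
  if (is.null(dim(axis))) axis <- matrix(axis, nrow = 1L)
  if (ncol(axis) != 3L || length(normal) != 3L) {
    abort_anepps("`axis` and `normal` must be 3-component vectors.",
                 "bad_vector")
  }
  na <- sqrt(rowSums(axis^2))
  nn <- sqrt(sum(normal^2))
  if (nn == 0 || any(na == 0)) {
    abort_anepps("Zero-length vector has no direction.", "zero_vector")
  }
  cosang <- as.numeric(axis %*% normal) / (na * nn)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  if (length(ang) == 1L) ang[[1]] else ang
}

#' Density profile along the membrane normal
#'
#' Histogram of z-positions over `[min, max]` extended outward to whole
#' bins. `count` normalization keeps raw per-bin counts (their sum is the
#' number of samples); `unit_peak` scales so the most occupied bin is 1,
#' the convention used to overlay profiles of different species.
#'
#' @param samples Numeric vector of z-positions, Angstrom (or a data frame
#'   with a `z` column).
#' @param bin_width Bin width, Angstrom; default 0.5.
#' @param normalization `"count"` or `"unit_peak"`.
#' @return Tibble with columns `z_lo`, `z_hi`, `z_mid` (Angstrom) and
#'   `density`.
#' @export
density_profile <- function(samples, bin_width = 0.5,
                            normalization = c("count", "unit_peak")) {
  if (is.data.frame(samples)) samples <- samples$z
  normalization <- rlang::arg_match(normalization)
  if (length(samples) == 0L || all(!is.finite(samples))) {
    abort_anepps("`samples` must contain at least one finite value.",
                 "empty_samples")
  }
  if (!is.numeric(bin_width) || bin_width <= 0) {
    abort_anepps("`bin_width` must be positive.", "bad_bin_width")
  }
  lo <- floor(min(samples) / bin_width) * bin_width
  hi <- ceiling(max(samples) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width  # all samples on a bin edge
  edges <- seq(lo, hi, by = bin_width)
  idx <- pmin(findInterval(samples, edges, rightmost.closed = TRUE),
              length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  dens <- switch(normalization,
    count = as.numeric(counts),
    unit_peak = counts / max(counts)
  )
  tibble(
    z_lo = edges[-length(edges)],
    z_hi = edges[-1],
    z_mid = (edges[-length(edges)] + edges[-1]) / 2,
    density = dens
  )
}

#' Block-average mean and standard error
#'
#' Error estimation for a correlated stationary series: the series is split
#' into `n_blocks` contiguous blocks (trailing remainder frames joining the
#' last block), and the standard error of the overall mean is the sample SD
#' of the block means divided by `sqrt(n_blocks)`. With blocks much longer
#' than the correlation time the block means are effectively independent
#' and the SE is unbiased, unlike the iid formula.
#'
#' @param series Numeric vector (or data frame column `gap`, `z` or
#'   `value`, first match).
#' @param n_blocks Number of blocks, between 2 and `length(series)`;
#'   default 10.
#' @return Tibble with columns `mean`, `se`, `n`, `n_blocks`.
#' @examples
#' block_average(1:6, n_blocks = 3)
#' @export
block_average <- function(series, n_blocks = 10) {
  if (is.data.frame(series)) {
    col <- intersect(c("gap", "z", "value"), names(series))[1]
    if (is.na(col)) {
      abort_anepps("Data frame input needs a `gap`, `z` or `value` column.",
                   "bad_series")
    }
    series <- series[[col]]
  }
  n <- length(series)
  if (!rlang::is_scalar_integerish(n_blocks) || n_blocks < 2) {
    abort_anepps("`n_blocks` must be an integer >= 2.", "bad_blocks")
  }
  if (n_blocks > n) {
    abort_anepps(
      sprintf("`n_blocks` (%d) exceeds the series length (%d).",
              as.integer(n_blocks), n),
      "bad_blocks"
    )
  }
  size <- n %/% n_blocks
  block <- pmin((seq_len(n) - 1L) %/% size + 1L, n_blocks)
  means <- vapply(split(series, block), mean, numeric(1))
  tibble(
    mean = mean(series),
    se = sd(means) / sqrt(n_blocks),
    n = n,
    n_blocks = as.integer(n_blocks)
  )
}

#' Summarise one (state, voltage) condition
#'
#' Per-atom mean and SD of the z-position plus tilt mean and SD over all
#' frames of a condition, the row shape of the reference configuration
#' table. SDs are population SDs over frames (they describe the spread of
#' the configurational distribution, not the uncertainty of the mean);
#' block-average standard errors of each mean are reported alongside.
#'
#' @param tracks Long tibble from [generate_atom_tracks()] (columns
#'   `frame`, `label`, `z`).
#' @param orientation Tibble from [generate_orientation_series()] (columns
#'   `frame`, `x`, `y`, `z`), or `NULL` to skip the tilt row.
#' @param state,v_mp Condition labels attached to the summary.
#' @param n_blocks Blocks for the standard errors; default 10.
#' @return Tibble with columns `state`, `v_mp`, `quantity` ("tilt" or atom
#'   label), `mean`, `sd`, `se`, `n_frames`.
#' @export
summarize_condition <- function(tracks, orientation = NULL, state, v_mp,
                                n_blocks = 10) {
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  lens <- tapply(tracks$z, tracks$label, length)
  if (!is.null(orientation)) lens <- c(lens, nrow(orientation))
  if (length(unique(lens)) != 1L) {
    abort_anepps("All series in a condition must have the same length.",
                 "length_mismatch")
  }
  one <- function(values, quantity) {
    ba <- block_average(values, n_blocks = n_blocks)
    tibble(state = state, v_mp = v_mp, quantity = quantity,
           mean = mean(values), sd = pop_sd(values), se = ba$se,
           n_frames = length(values))
  }
  out <- list()
  if (!is.null(orientation)) {
    out <- c(out, list(one(tilt_angle(orientation), "tilt")))
  }
  labs <- unique(tracks$label)
  out <- c(out, lapply(labs, function(l) one(tracks$z[tracks$label == l], l)))
  dplyr::bind_rows(out)
}

#' Range of motion of an atom between the extreme voltages
#'
#' Absolute difference between the mean z-position at the most positive and
#' most negative applied potential, a measure of how strongly an atom's
#' average depth couples to the membrane potential.
#'
#' @param summaries Tibble of condition summaries (columns `v_mp`,
#'   `quantity`, `mean`), e.g. stacked [summarize_condition()] rows for one
#'   state.
#' @param label Atom label (`"S"`, `"N1"`, `"N2"`, `"C_tail"`) or `"tilt"`.
#' @return Range in the quantity's units (Angstrom for atoms).
#' @export
range_of_motion <- function(summaries, label) {
  rows <- summaries[summaries$quantity == label, ]
  if (nrow(rows) == 0L) {
    abort_anepps(sprintf("No rows with quantity `%s`.", label),
                 "unknown_label")
  }
  vlo <- min(rows$v_mp)
  vhi <- max(rows$v_mp)
  abs(mean(rows$mean[rows$v_mp == vhi]) - mean(rows$mean[rows$v_mp == vlo]))
}
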
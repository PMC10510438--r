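## Synthetic-trajectory module: stationary autocorrelated surrogates for the
## per-frame observables that microsecond MD would otherwise provide.

## Standardized stationary AR(1): x[1] ~ N(0,1),
## x[t] = rho x[t-1] + sqrt(1-rho^2) eps[t].  Exact stationary start, so the
## marginal is N(0,1) at every frame and lag-1 autocorrelation equals rho.
ar1_standardized <- function(n_frames, rho) {
  z <- rnorm(n_frames)
  if (rho == 0 || n_frames == 1L) {
    return(z)
  }
  innov <- z * sqrt(1 - rho^2)
  innov[1] <- z[1]
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

check_frames <- function(n_frames) {
  if (!rlang::is_scalar_integerish(n_frames) || n_frames < 1) {
    abort_anepps("`n_frames` must be a positive integer.", "bad_n_frames")
  }
  as.integer(n_frames)
}

check_state <- function(state) {
  if (!rlang::is_string(state) || !state %in% c("gs", "es")) {
    abort_anepps('`state` must be "gs" (ground) or "es" (excited).', "bad_state")
  }
  state
}

check_sigma <- function(sigma, what = "sigma") {
  if (!is.numeric(sigma) || any(!is.finite(sigma)) || any(sigma < 0)) {
    abort_anepps(sprintf("`%s` must be finite and >= 0.", what), "bad_sigma")
  }
  sigma
}

check_rho <- function(rho) {
  if (!rlang::is_scalar_double(rho) && !rlang::is_scalar_integerish(rho)) {
    abort_anepps("`rho` must be a single number in [0, 1).", "bad_rho")
  }
  if (!is.finite(rho) || rho < 0 || rho >= 1) {
    abort_anepps("`rho` must lie in [0, 1).", "bad_rho")
  }
  as.numeric(rho)
}

#' Default energy-gap generator specification
#'
#' Builds the generator parameters whose stationary mean reproduces the
#' reference wavelength for the requested state and voltage: the mean raw gap
#' is the reference absorption (ground state) or emission (excited state)
#' wavelength converted back to an energy via [hc_molar] plus the matching
#' empirical offset. The per-frame fluctuation defaults (`sigma` = 2
#' kcal/mol, `rho` = 0.5) give block standard errors of the derived
#' wavelengths of about 0.14 nm (emission) and 0.08 nm (absorption) at 1e5
#' frames, the uncertainty scale of the reference trajectories.
#'
#' @param state `"gs"` or `"es"`.
#' @param v_mp Applied membrane potential, mV (one of -500, -100, 0, 100, 500
#'   for the bundled defaults).
#' @param sigma Stationary SD of the per-frame gap, kcal/mol.
#' @param rho Lag-1 autocorrelation, in `[0, 1)`.
#' @param offsets Named vector as [default_offsets].
#' @return One-row tibble with columns `mu0`, `kappa`, `sigma`, `rho`.
#'   `kappa` (linear voltage sensitivity of the mean, kcal/mol/mV) is 0
#'   because the defaults carry a separate mean per voltage condition.
#' @export
gap_gen_defaults <- function(state, v_mp, sigma = 2, rho = 0.5,
                             offsets = default_offsets) {
  check_state(state)
  ref <- reference_spectra[reference_spectra$v_mp == v_mp, ]
  if (nrow(ref) != 1L) {
    abort_anepps(
      sprintf("No bundled defaults for v_mp = %s mV.", format(v_mp)),
      "unknown_condition"
    )
  }
  lambda <- if (state == "gs") ref$absorption else ref$emission
  offset <- if (state == "gs") offsets[["absorption"]] else offsets[["emission"]]
  tibble(
    mu0 = hc_molar / lambda + offset,
    kappa = 0,
    sigma = check_sigma(sigma),
    rho = check_rho(rho)
  )
}

#' Generate a synthetic energy-gap series
#'
#' Draws a stationary Gaussian AR(1) series of per-frame excited-minus-ground
#' total-energy differences (kcal/mol) with stationary mean
#' `mu0 + kappa * v_mp`, stationary SD `sigma` and lag-1 autocorrelation
#' `rho`. The emission gap series is sampled on the excited-state trajectory
#' (`state = "es"`), the absorption series on the ground-state trajectory.
#'
#' @param spec One-row data frame or list with fields `mu0`, `kappa`,
#'   `sigma`, `rho` (see [gap_gen_defaults()]).
#' @param state `"gs"` or `"es"`.
#' @param v_mp Applied membrane potential, mV.
#' @param n_frames Number of frames, >= 1.
#' @param seed Integer seed; a fixed seed gives bit-identical output.
#' @return Tibble with columns `frame`, `gap` (kcal/mol), `state`, `v_mp`.
#' @examples
#' g <- generate_energy_gap_series(gap_gen_defaults("es", 0), "es", 0, 1000, 1)
#' mean(g$gap)
#' @export
generate_energy_gap_series <- function(spec, state, v_mp, n_frames, seed) {
  spec <- as.list(spec)
  for (f in c("mu0", "kappa", "sigma", "rho")) {
    if (is.null(spec[[f]])) {
      abort_anepps(sprintf("Gap generator spec is missing field `%s`.", f),
                   "bad_spec")
    }
  }
  check_state(state)
  if (!is.finite(v_mp)) abort_anepps("`v_mp` must be finite.", "bad_voltage")
  n_frames <- check_frames(n_frames)
  check_sigma(spec$sigma)
  rho <- check_rho(spec$rho)
  mu <- spec$mu0 + spec$kappa * v_mp
  gap <- with_seed(seed, mu + spec$sigma * ar1_standardized(n_frames, rho))
  tibble(frame = seq_len(n_frames), gap = gap, state = state, v_mp = v_mp)
}

#' Default atom-track generator specification
#'
#' Per-atom mean/SD of the z-position for the requested state and voltage,
#' taken from [reference_configuration].
#'
#' @inheritParams gap_gen_defaults
#' @param rho Lag-1 autocorrelation shared by all tracks.
#' @return Tibble with columns `label`, `mean` (Angstrom), `sd` (Angstrom),
#'   `rho`.
#' @export
track_gen_defaults <- function(state, v_mp, rho = 0.5) {
  check_state(state)
  ref <- reference_configuration
  ref <- ref[ref$state == state & ref$v_mp == v_mp & ref$quantity != "tilt", ]
  if (nrow(ref) == 0L) {
    abort_anepps(
      sprintf("No bundled defaults for (%s, %s mV).", state, format(v_mp)),
      "unknown_condition"
    )
  }
  tibble(label = ref$quantity, mean = ref$mean, sd = ref$sd,
         rho = check_rho(rho))
}

#' Generate synthetic z-position tracks for labeled atoms
#'
#' One stationary Gaussian AR(1) series per atom label, with the spec's
#' per-label mean and SD. z is measured from the bilayer midplane along the
#' membrane normal (+z into the dye-bearing leaflet).
#'
#' @param spec Data frame with columns `label`, `mean`, `sd` and either a
#'   `rho` column or the `rho` argument (see [track_gen_defaults()]).
#' @param labels Labels to generate; default all rows of `spec`. Unknown
#'   labels are an error.
#' @inheritParams generate_energy_gap_series
#' @return Long tibble with columns `frame`, `label`, `z` (Angstrom),
#'   `state`, `v_mp`.
#' @export
generate_atom_tracks <- function(spec, state, v_mp, n_frames, seed,
                                 labels = NULL) {
  spec <- as_tibble(spec)
  if (!all(c("label", "mean", "sd") %in% names(spec))) {
    abort_anepps("Track spec needs columns `label`, `mean`, `sd`.", "bad_spec")
  }
  if (is.null(spec$rho)) spec$rho <- 0.5
  check_state(state)
  n_frames <- check_frames(n_frames)
  labels <- labels %||% spec$label
  unknown <- setdiff(labels, spec$label)
  if (length(unknown) > 0) {
    abort_anepps(
      sprintf("Unknown atom label(s): %s. Spec provides: %s.",
              paste(unknown, collapse = ", "),
              paste(spec$label, collapse = ", ")),
      "unknown_label"
    )
  }
  check_sigma(spec$sd, "sd")
  spec <- spec[match(labels, spec$label), ]
  with_seed(seed, {
    purrr::pmap_dfr(
      spec[c("label", "mean", "sd", "rho")],
      function(label, mean, sd, rho) {
        tibble(
          frame = seq_len(n_frames),
          label = label,
          z = mean + sd * ar1_standardized(n_frames, check_rho(rho)),
          state = state,
          v_mp = v_mp
        )
      }
    )
  })
}

## --- truncated-normal machinery for tilt sampling ------------------------

## mean/SD of N(mu, sigma) truncated to [a, b]
tnorm_moments <- function(mu, sigma, a = 0, b = 180) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  z <- pnorm(be) - pnorm(al)
  dm <- (dnorm(al) - dnorm(be)) / z
  m <- mu + sigma * dm
  v <- sigma^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / z - dm^2)
  c(mean = m, sd = sqrt(v))
}

## Solve for the underlying (mu, sigma) whose [a,b]-truncated moments equal
## the requested mean/SD, so prescribed tilt statistics are recovered exactly
## in expectation (naive truncation would bias the mean by up to ~1 degree
## for the broad ground-state distribution).
match_truncated_normal <- function(target_mean, target_sd, a = 0, b = 180) {
  obj <- function(p) {
    mo <- tnorm_moments(p[1], exp(p[2]), a, b)
    (mo[1] - target_mean)^2 + (mo[2] - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 10000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]),
       achieved = tnorm_moments(fit$par[1], exp(fit$par[2]), a, b))
}

qtnorm <- function(p, mu, sigma, a = 0, b = 180) {
  pa <- pnorm(a, mu, sigma)
  pb <- pnorm(b, mu, sigma)
  qnorm(pa + p * (pb - pa), mu, sigma)
}

#' Generate a synthetic molecular-axis orientation series
#'
#' Samples per-frame unit vectors for the N1-to-N2 axis of the probe. Tilt
#' angles (angle to the +z membrane normal) follow a normal distribution
#' truncated to `[0, 180]` degrees whose parameters are moment-matched so
#' the stationary mean and SD equal `mean_tilt` and `tilt_sd`; temporal
#' correlation is imposed through a Gaussian copula with AR(1) parameter
#' `rho`. Azimuths are independent and uniform.
#'
#' @param mean_tilt Mean tilt, degrees, in `[0, 180]`.
#' @param tilt_sd SD of the tilt, degrees (`0` gives a constant tilt).
#' @param rho Lag-1 autocorrelation of the underlying Gaussian process.
#' @inheritParams generate_energy_gap_series
#' @return Tibble with columns `frame`, `x`, `y`, `z`; each row a unit
#'   vector.
#' @export
generate_orientation_series <- function(mean_tilt, tilt_sd, n_frames, seed,
                                        rho = 0.5) {
  if (!is.finite(mean_tilt) || mean_tilt < 0 || mean_tilt > 180) {
    abort_anepps("`mean_tilt` must lie in [0, 180] degrees.", "bad_tilt")
  }
  check_sigma(tilt_sd, "tilt_sd")
  n_frames <- check_frames(n_frames)
  rho <- check_rho(rho)
  with_seed(seed, {
    if (tilt_sd == 0) {
      theta <- rep(mean_tilt, n_frames)
    } else {
      par <- match_truncated_normal(mean_tilt, tilt_sd)
      u <- pnorm(ar1_standardized(n_frames, rho))
      theta <- qtnorm(u, par$mu, par$sigma)
    }
    phi <- stats::runif(n_frames, 0, 2 * pi)
    th <- theta * pi / 180
    tibble(
      frame = seq_len(n_frames),
      x = sin(th) * cos(phi),
      y = sin(th) * sin(phi),
      z = cos(th)
    )
  })
}

#' Default orientation generator specification
#'
#' Tilt mean/SD for the requested state and voltage from
#' [reference_configuration].
#'
#' @inheritParams track_gen_defaults
#' @return One-row tibble with `mean_tilt`, `tilt_sd` (degrees), `rho`.
#' @export
orientation_gen_defaults <- function(state, v_mp, rho = 0.5) {
  check_state(state)
  ref <- reference_configuration
  ref <- ref[ref$state == state & ref$v_mp == v_mp & ref$quantity == "tilt", ]
  if (nrow(ref) != 1L) {
    abort_anepps(
      sprintf("No bundled defaults for (%s, %s mV).", state, format(v_mp)),
      "unknown_condition"
    )
  }
  tibble(mean_tilt = ref$mean, tilt_sd = ref$sd, rho = check_rho(rho))
}

#' Generate a paired set of synthetic electrostatic potential grids
#'
#' Builds two congruent 3-D potential maps emulating time-averaged
#' electrostatic maps of a membrane system: an unbiased map at 0 mV and a
#' biased map at `v_mp`, whose voxel-wise difference is
#' `v_mp * f(z)` plus independent Gaussian noise of SD `noise_sd`. The
#' smooth xy-independent background shared by both maps is arbitrary (it
#' cancels in the potential-fraction analysis and exercises the gauge
#' invariance of downstream code).
#'
#' @param f_profile Data frame with columns `z` (Angstrom) and `f`
#'   (dimensionless) giving the true potential-fraction profile; evaluated at
#'   voxel z-nodes by linear interpolation with end-value clamping.
#' @param v_mp Applied potential of the biased map, mV; must be nonzero.
#' @param box Lengths `c(Lx, Ly, Lz)` of the periodic box, Angstrom. The
#'   grid is centered so z runs from `-Lz/2` to `Lz/2 - dz`.
#' @param spacing Voxel spacing, Angstrom: one number or `c(dx, dy, dz)`.
#'   Must divide the box lengths.
#' @param noise_sd SD of the voxel noise on the difference map, mV.
#' @param seed Integer seed.
#' @return List with elements `biased` and `reference`, both
#'   [potential_grid] objects (values in mV).
#' @export
generate_potential_grids <- function(f_profile, v_mp, box, spacing,
                                     noise_sd = 0, seed = 1) {
  if (v_mp == 0) {
    abort_anepps("`v_mp` must be nonzero for the biased grid.", "zero_voltage")
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) {
    abort_anepps("`spacing` must be positive.", "bad_spacing")
  }
  if (length(box) != 3L || any(box <= 0)) {
    abort_anepps("`box` must be three positive lengths.", "bad_box")
  }
  n <- box / spacing
  if (any(abs(n - round(n)) > 1e-8)) {
    abort_anepps("`spacing` must divide the box lengths.", "bad_spacing")
  }
  n <- as.integer(round(n))
  check_sigma(noise_sd, "noise_sd")
  origin <- c(0, 0, -box[3] / 2)
  zs <- origin[3] + (seq_len(n[3]) - 1L) * spacing[3]
  fz <- approx(f_profile$z, f_profile$f, xout = zs, rule = 2)$y
  ## smooth arbitrary background, identical in both maps
  bg <- 25 * sin(2 * pi * zs / box[3])
  base <- array(rep(bg, each = n[1] * n[2]), dim = n)
  ramp <- array(rep(v_mp * fz, each = n[1] * n[2]), dim = n)
  noise <- if (noise_sd > 0) {
    with_seed(seed, array(rnorm(prod(n), 0, noise_sd), dim = n))
  } else {
    array(0, dim = n)
  }
  list(
    biased = potential_grid(base + ramp + noise, origin, spacing),
    reference = potential_grid(base, origin, spacing)
  )
}
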
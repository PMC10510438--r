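## End-to-end orchestration: one configuration in, the full set of
## configuration, spectral, fit and ratiometric reports out.

#' Default run configuration
#'
#' Bundles the published study conditions: five applied potentials, both
#' force-field states, generator defaults tied to the reference
#' configuration and spectra, the empirical offsets, the published
#' line-shape parameters with the 620/560 nm ratio pair, and the +/-100 mV
#' linear-fit window.
#'
#' @param n_frames Frames per condition; default 1e5.
#' @param seed Base seed; per-condition seeds are derived from it
#'   deterministically.
#' @param voltages Applied potentials, mV.
#' @param states Force-field states to simulate.
#' @param sigma_gap,rho Gap-series SD (kcal/mol) and shared lag-1
#'   autocorrelation for all generated series.
#' @param n_blocks Blocks for every block-average standard error.
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(n_frames = 1e5, seed = 1,
                               voltages = c(-500, -100, 0, 100, 500),
                               states = c("gs", "es"),
                               sigma_gap = 2, rho = 0.5, n_blocks = 10) {
  cfg <- list(
    voltages = voltages,
    states = states,
    n_frames = as.integer(n_frames),
    seed = as.integer(seed),
    sigma_gap = sigma_gap,
    rho = rho,
    n_blocks = as.integer(n_blocks),
    offsets = as.list(default_offsets),
    lineshape = list(i_max = 153.4, half_width = 51.1, peak0 = 605.97,
                     peak_slope = -0.0071),
    ratio = list(lambda_num = 620, lambda_den = 560, v_ref = -100),
    fit_window = c(-100, 100)
  )
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' @param cfg Named list with the fields of [default_run_config()].
#' @return The validated config, classed `run_config`.
#' @export
validate_run_config <- function(cfg) {
  if (length(cfg$voltages) == 0L) {
    abort_anepps("Config must list at least one voltage.", "bad_config")
  }
  if (is.null(cfg$n_frames) || cfg$n_frames < 1) {
    abort_anepps("Config `n_frames` must be >= 1.", "bad_config")
  }
  for (s in cfg$states) check_state(s)
  w <- cfg$fit_window
  if (length(w) != 2L || w[1] >= w[2]) {
    abort_anepps("Config `fit_window` must be c(min, max), min < max.",
                 "bad_config")
  }
  if (w[1] < min(cfg$voltages) || w[2] > max(cfg$voltages)) {
    abort_anepps(
      "Config `fit_window` must lie within the range of configured voltages.",
      "bad_config"
    )
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config()` returns a validated `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$fit_window <- unlist(cfg$fit_window)
  cfg$voltages <- unlist(cfg$voltages)
  cfg$states <- unlist(cfg$states)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

condition_seed <- function(base, i) {
  (as.integer(base) + 1009L * as.integer(i)) %% 2147483647L
}

#' Run the full analysis pipeline on synthetic trajectories
#'
#' For every configured (state, voltage) condition: generates energy-gap,
#' atom-track and orientation series with the bundled defaults, summarises
#' the probe configuration, maps the gap ensembles to absorption/emission
#' wavelengths with block-average uncertainties, computes Stokes shifts,
#' fits the linear voltage response inside the configured window, and
#' calibrates the dual-wavelength ratiometric observable from the
#' configured line shape. Deterministic for a fixed config seed.
#'
#' @param cfg A `run_config`, e.g. [default_run_config()].
#' @return Object of class `run_report`: list with `configuration`
#'   (per-condition summaries), `spectra` (per-voltage wavelengths, SEs,
#'   Stokes shifts), `fits` (`voltage_fit` per transition),
#'   `shift_per_100mV` (windowed fit and full-span endpoint estimates),
#'   `ratiometry` ([calibrate_ratiometry()] output), `range_of_motion`,
#'   and `manifest` (seed, config, config hash).
#' @export
run_end_to_end <- function(cfg = default_run_config()) {
  cfg <- validate_run_config(cfg)
  conditions <- tidyr::expand_grid(state = cfg$states, v_mp = cfg$voltages)
  conditions$idx <- seq_len(nrow(conditions))

  per_cond <- purrr::pmap(conditions, function(state, v_mp, idx) {
    sd_base <- condition_seed(cfg$seed, idx)
    gaps <- generate_energy_gap_series(
      gap_gen_defaults(state, v_mp, sigma = cfg$sigma_gap, rho = cfg$rho,
                       offsets = unlist(cfg$offsets)),
      state, v_mp, cfg$n_frames, seed = sd_base
    )
    tracks <- generate_atom_tracks(
      track_gen_defaults(state, v_mp, rho = cfg$rho),
      state, v_mp, cfg$n_frames, seed = sd_base + 1L
    )
    od <- orientation_gen_defaults(state, v_mp, rho = cfg$rho)
    orient <- generate_orientation_series(
      od$mean_tilt, od$tilt_sd, cfg$n_frames, seed = sd_base + 2L,
      rho = od$rho
    )
    list(
      state = state, v_mp = v_mp,
      summary = summarize_condition(tracks, orient, state, v_mp,
                                    n_blocks = cfg$n_blocks),
      gaps = gaps
    )
  })

  configuration <- dplyr::bind_rows(purrr::map(per_cond, "summary"))

  spectra <- purrr::map_dfr(cfg$voltages, function(v) {
    gs <- purrr::detect(per_cond, ~ .x$state == "gs" && .x$v_mp == v)
    es <- purrr::detect(per_cond, ~ .x$state == "es" && .x$v_mp == v)
    row <- tibble(v_mp = v, absorption = NA_real_, se_ab = NA_real_,
                  emission = NA_real_, se_em = NA_real_, stokes = NA_real_)
    if (!is.null(gs)) {
      ab <- wavelength_from_gaps(gs$gaps, cfg$offsets$absorption,
                                 n_blocks = cfg$n_blocks)
      row$absorption <- ab$lambda
      row$se_ab <- ab$se
    }
    if (!is.null(es)) {
      em <- wavelength_from_gaps(es$gaps, cfg$offsets$emission,
                                 n_blocks = cfg$n_blocks)
      row$emission <- em$lambda
      row$se_em <- em$se
    }
    if (!is.na(row$absorption) && !is.na(row$emission)) {
      row$stokes <- stokes_shift(row$absorption, row$emission)
    }
    row
  })

  outside <- cfg$voltages[cfg$voltages < cfg$fit_window[1] |
                            cfg$voltages > cfg$fit_window[2]]
  if (length(outside)) {
    rlang::inform(sprintf(
      "Voltages outside the linear-response window [%g, %g] mV excluded from fits: %s",
      cfg$fit_window[1], cfg$fit_window[2], paste(outside, collapse = ", ")
    ), class = "anepps_outside_window")
  }

  fits <- list()
  shifts <- list()
  for (tr in c("absorption", "emission")) {
    pts <- tibble(v_mp = spectra$v_mp, lambda = spectra[[tr]])
    pts <- pts[!is.na(pts$lambda), ]
    if (nrow(pts) >= 2L) {
      fits[[tr]] <- fit_voltage_response(pts, window = cfg$fit_window)
      shifts[[tr]] <- c(fit = shift_per_100mV(fits[[tr]]),
                        endpoint = average_shift_per_100mV(pts))
    }
  }

  ls <- lorentzian_lineshape(cfg$lineshape$i_max, cfg$lineshape$half_width,
                             cfg$lineshape$peak0, cfg$lineshape$peak_slope)
  ratio <- calibrate_ratiometry(
    ls, voltages = cfg$voltages, v_ref = cfg$ratio$v_ref,
    lambda_num = cfg$ratio$lambda_num, lambda_den = cfg$ratio$lambda_den
  )

  rom <- purrr::map_dfr(cfg$states, function(s) {
    sub <- configuration[configuration$state == s, ]
    tibble(
      state = s,
      quantity = unique(sub$quantity),
      range = vapply(unique(sub$quantity),
                     function(q) range_of_motion(sub, q), numeric(1))
    )
  })

  structure(
    list(
      configuration = configuration,
      spectra = spectra,
      fits = fits,
      shift_per_100mV = shifts,
      ratiometry = ratio,
      range_of_motion = rom,
      manifest = list(
        seed = cfg$seed,
        n_frames = cfg$n_frames,
        config = unclass(cfg),
        config_hash = rlang::hash(unclass(cfg)),
        created = format(Sys.time(), tz = "UTC", usetz = TRUE),
        package_version = as.character(utils::packageVersion("anepps"))
      )
    ),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  conditions: %d (seed %d, %d frames each)\n",
              length(unique(paste(x$configuration$state,
                                  x$configuration$v_mp))),
              x$manifest$seed, x$manifest$n_frames))
  cat("  spectra (nm):\n")
  print(as.data.frame(x$spectra), digits = 7, row.names = FALSE)
  for (tr in names(x$shift_per_100mV)) {
    s <- x$shift_per_100mV[[tr]]
    cat(sprintf("  %s shift: %.3f nm / 100 mV (windowed fit), %.3f (full-span endpoints)\n",
                tr, s[["fit"]], s[["endpoint"]]))
  }
  cat(sprintf("  ratiometry: |dR/dV| = %.3g per mV -> %.3f nm peak shift per 100 mV\n",
              x$ratiometry$ratio_slope_per_mV,
              x$ratiometry$peak_shift_per_100mV))
  invisible(x)
}

#' Write the tables of a run report to a directory
#'
#' Emits `configuration.tsv` (reference-configuration-shaped summary),
#' `spectra.tsv` (per-voltage wavelengths and Stokes shifts),
#' `ratiometry.tsv`, `range_of_motion.tsv` and `manifest.yaml` (sufficient
#' to rerun: seed and full config). Wavelengths are written with 4
#' decimals, Angstrom and degree quantities with 1.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfgtab <- report$configuration
  cfgtab$mean <- round(cfgtab$mean, 1)
  cfgtab$sd <- round(cfgtab$sd, 1)
  cfgtab$se <- signif(cfgtab$se, 3)
  write.table(cfgtab, file.path(dir, "configuration.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  sp <- report$spectra
  for (cc in c("absorption", "emission", "stokes")) {
    sp[[cc]] <- round(sp[[cc]], 4)
  }
  for (cc in c("se_ab", "se_em")) sp[[cc]] <- signif(sp[[cc]], 3)
  write.table(sp, file.path(dir, "spectra.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(report$ratiometry$changes, file.path(dir, "ratiometry.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  rom <- report$range_of_motion
  rom$range <- round(rom$range, 1)
  write.table(rom, file.path(dir, "range_of_motion.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  yaml::write_yaml(report$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
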
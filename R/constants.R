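#' Planck constant times speed of light, per mole
#'
#' Conversion constant between a molar transition energy and a wavelength:
#' \eqn{\lambda \mathrm{[nm]} = hc_{molar} / E \mathrm{[kcal/mol]}}. The value
#' uses the thermochemical kilocalorie (4184 J) and is fixed at six
#' significant figures; it is a documented constant, not a tunable.
#'
#' @format A single number, kcal nm / mol.
#' @export
hc_molar <- 2.85916e4

#' Default empirical vibrational offset constants
#'
#' Voltage-independent energies subtracted from the raw classical
#' excited-minus-ground energy gap before converting it to a wavelength.
#' They absorb the nonradiative vibrational/reorganization contributions that
#' a classical force-field gap does not resolve. The emission offset
#' (12.6 kcal/mol) was calibrated against the measured emission peak of
#' membrane-bound di-8-ANEPPS; the absorption offset (4.99 kcal/mol) comes
#' from the dye's absorption in solvents of varying polarity, as no
#' voltage-resolved absorption data exist for the membrane.
#'
#' @format Named numeric vector with elements `absorption` and `emission`,
#'   kcal/mol.
#' @export
default_offsets <- c(absorption = 4.99, emission = 12.6)

#' Reference configuration of membrane-bound di-8-ANEPPS
#'
#' Published mean and standard deviation of the probe's tilt angle and of the
#' z-positions of its labeled atoms (sulfonate sulfur `S`, pyridinium
#' nitrogen `N1`, amino nitrogen `N2`, and the average of the two terminal
#' tail carbons `C_tail`) in a DPPC bilayer, for the ground (`gs`) and
#' excited (`es`) force-field states at five applied membrane potentials.
#' Each cell summarises 10,000 snapshots of a 1 microsecond trajectory; the
#' bilayer midplane is at z = 0 and the dye occupies the upper leaflet.
#' These values seed the synthetic-trajectory generator defaults.
#'
#' @format Tibble with columns `state` ("gs"/"es"), `v_mp` (mV),
#'   `quantity` ("tilt" in degrees or an atom label in Angstrom),
#'   `mean`, `sd`.
#' @export
reference_configuration <- local({
  row <- function(state, v, tilt, S, N1, N2, C_tail) {
    vals <- list(tilt = tilt, S = S, N1 = N1, N2 = N2, C_tail = C_tail)
    tibble::tibble(
      state = state, v_mp = v,
      quantity = names(vals),
      mean = unname(vapply(vals, `[`, numeric(1), 1L)),
      sd = unname(vapply(vals, `[`, numeric(1), 2L))
    )
  }
  dplyr::bind_rows(
    row("gs", -500, c(26.2, 13.5), c(21.8, 2.5), c(17.9, 2.4), c(6.5, 2.4), c(2.1, 4.4)),
    row("gs", -100, c(24.5, 12.4), c(22.3, 2.3), c(18.4, 2.2), c(6.7, 2.3), c(2.2, 4.1)),
    row("gs",    0, c(25.9, 14.1), c(22.1, 2.5), c(18.1, 2.3), c(6.7, 2.4), c(2.2, 4.3)),
    row("gs",  100, c(26.7, 14.1), c(22.2, 2.5), c(18.3, 2.3), c(7.0, 2.3), c(2.4, 4.1)),
    row("gs",  500, c(28.2, 13.7), c(22.2, 2.6), c(18.4, 2.4), c(7.2, 2.5), c(2.8, 4.3)),
    row("es", -500, c(47.9, 17.6), c(17.8, 3.3), c(14.6, 2.9), c(6.3, 2.9), c(3.2, 5.4)),
    row("es", -100, c(50.3, 17.0), c(18.0, 3.4), c(15.0, 3.0), c(7.1, 2.5), c(3.8, 5.0)),
    row("es",    0, c(48.3, 17.6), c(18.8, 3.8), c(15.7, 3.2), c(7.5, 2.4), c(4.0, 4.9)),
    row("es",  100, c(49.2, 16.5), c(18.6, 3.5), c(15.6, 3.1), c(7.4, 2.5), c(3.8, 4.7)),
    row("es",  500, c(49.5, 15.9), c(18.7, 3.5), c(15.7, 3.0), c(7.6, 2.3), c(4.3, 4.7))
  )
})

#' Reference spectral response of di-8-ANEPPS in DPPC
#'
#' Published peak absorption and emission wavelengths and Stokes shifts of
#' membrane-bound di-8-ANEPPS as a function of the applied membrane
#' potential, together with the emission peak deduced from the Lorentzian
#' fit to measured HEK-cell spectra (`kao_peak`). Wavelengths in nm.
#'
#' @format Tibble with columns `v_mp` (mV), `absorption`, `emission`,
#'   `stokes`, `kao_peak` (nm).
#' @export
reference_spectra <- tibble::tibble(
  v_mp       = c(-500, -100, 0, 100, 500),
  absorption = c(464.8507316, 460.4470742, 460.5651479, 459.3371888, 457.4763198),
  emission   = c(608.5598257, 606.5502935, 605.5221392, 605.119289, 604.0569262),
  stokes     = c(143.709094, 146.1032194, 144.9569914, 145.7821002, 146.5806064),
  kao_peak   = c(609.5, 606.7, 606.0, 605.3, 602.4)
)

#' Atom labels tracked along the membrane normal
#' @format Character vector.
#' @export
atom_labels <- c("S", "N1", "N2", "C_tail")
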
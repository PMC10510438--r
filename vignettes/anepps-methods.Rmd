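---
title: "Methods: from energy-gap ensembles to voltage-dependent fluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from energy-gap ensembles to voltage-dependent fluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anepps)
```

## The problem

di-8-ANEPPS is an amphiphilic, zwitterionic styryl dye that anchors in one
leaflet of a lipid bilayer and reports the local electric field through
shifts of its emission spectrum (electrochromism). Quantitative use of the
dye requires a calibration chain with several links: the configurational
statistics of the membrane-bound probe (depth and tilt, and how they move
with voltage), the mapping from simulated energetics to absorption and
emission wavelengths, the conversion between the peak shifts a simulation
predicts and the dual-wavelength intensity ratios an experiment actually
measures, and the profile of how much of an applied membrane potential is
felt at each depth in the bilayer. `anepps` implements that chain as a set
of composable, tested tibble-in/tibble-out functions, plus a synthetic
trajectory module so the whole pipeline runs and is testable without
microsecond molecular-dynamics input.

## Energy-gap spectral mapping

In the classical force-field picture, the electronic transition is modelled
by evaluating two force fields — one parameterised for the ground state, one
for the first excited state — on the *same* configuration (the
Franck–Condon principle: electrons move on a timescale where nuclei are
frozen). For each frame the energy gap is
$\Delta E = E_{es} - E_{gs}$ (kcal/mol). Sampling configurations from the
ground-state trajectory gives the absorption gap; from the excited-state
trajectory, the emission gap. The peak wavelength is obtained by averaging
first and inverting once:

$$\lambda = \frac{hc_{molar}}{\langle \Delta E \rangle - c},$$

with $hc_{molar} = 2.85916 \times 10^4$ kcal·nm/mol (thermochemical
kilocalorie; fixed at six significant figures and documented as a constant,
not a tunable). Averaging before inverting is the definitional choice here;
the alternative $\langle hc/\Delta E \rangle$ differs only at second order
in the fluctuations but is not the quantity defined by the method.

The offsets $c$ are *voltage-independent empirical constants* absorbing the
nonradiative vibrational/reorganization energy that a classical gap cannot
resolve: 12.6 kcal/mol for emission (calibrated against the measured
emission peak of the membrane-bound dye) and 4.99 kcal/mol for absorption
(from solvent-series data, since no voltage-resolved absorption measurement
exists for the membrane). The sign convention — transition energy equals
raw gap *minus* offset — is the only one in which positive offsets produce
the observed red shift; `offset_from_reference()` exposes the calibration
as an exact algebraic round-trip with `wavelength_from_gaps()`.

Uncertainties are propagated to first order from the block-average standard
error of the mean gap: $\mathrm{se}(\lambda) = \lambda^2\,
\mathrm{se}(\langle\Delta E\rangle)/hc_{molar}$. The $\lambda^2$ factor is
why emission (≈ 605 nm) carries roughly twice the wavelength uncertainty of
absorption (≈ 460 nm) for the same energy noise.

## Block averaging

Per-frame series from MD (and from the AR(1) surrogates below) are strongly
autocorrelated, so the iid standard-error formula underestimates
uncertainty. `block_average()` splits a series into `n_blocks` contiguous
blocks — any remainder frames join the last block — and reports
$\mathrm{se} = \mathrm{sd}(\text{block means})/\sqrt{n_{blocks}}$. The
default is 10 blocks, a common practice for microsecond-scale windows; the
recovery test-suite uses 100 blocks of 1000 frames instead, because blocks
of 1000 frames are still two orders of magnitude longer than the surrogate
correlation time while giving the standard-error estimate enough degrees of
freedom that a 3-se tolerance has close to Gaussian coverage.

## The synthetic-trajectory module

The generator replaces the microsecond simulations with the *statistical
conditions those simulations report*, which is exactly what the downstream
analysis consumes:

* **Energy gaps and atom tracks** are stationary Gaussian AR(1) processes,
  initialised from the stationary distribution, so the prescribed mean, SD
  and lag-1 autocorrelation hold exactly at every frame. AR(1) is the
  simplest stationary autocorrelated model consistent with the reported
  mean ± SD summaries; nothing in the analysis depends on higher temporal
  structure.
* **Default gap means** per (state, voltage) are the bundled reference
  wavelengths inverted through the offsets, so the end-to-end pipeline
  reproduces the reference spectral table in expectation by construction.
* **Gap fluctuations** default to `sigma = 2` kcal/mol with `rho = 0.5`.
  These two numbers are set so that at the default $10^5$ frames the
  block standard errors of the derived wavelengths come out at the
  uncertainty scale the reference trajectories report (≈ 0.14 nm emission,
  ≈ 0.08 nm absorption). No per-frame gap SD is published, so matching the
  published uncertainty of the *means* is the available anchor.
* **Track and tilt means/SDs** default to the bundled reference
  configuration table (10 conditions × {tilt, S, N1, N2, C_tail}; the
  `C_tail` observable is the per-frame average of the two terminal tail
  carbons). The membrane normal is +z, the bilayer midplane z = 0, and the
  dye occupies the upper leaflet, so depths are positive.
* **Tilt angles** are drawn from a normal distribution truncated to
  [0°, 180°]. Naive truncation would bias the mean upward by up to ~1° for
  the broad ground-state distribution (mean ≈ 26°, SD ≈ 14°), so the
  underlying parameters are moment-matched numerically: the truncated
  distribution's mean and SD equal the requested values. Temporal
  correlation enters through a Gaussian copula (an AR(1) latent process
  mapped through the truncated-normal quantile function), which preserves
  the marginal exactly; tilt is reported unfolded in [0°, 180°]. Azimuths
  are uniform and independent, as only tilt statistics are prescribed.
* **Autocorrelation defaults** (`rho = 0.5` everywhere) are a genuinely
  open choice — no correlation times are published for these observables —
  fixed once for consistency across all series.
* **Potential grids** are built as a shared smooth background plus
  $V_{mp} f(z)$ plus voxel-independent Gaussian noise on the biased map, so
  the difference map equals $V_{mp} f(z)$ plus noise of exactly the
  requested SD. The background is arbitrary by design: it cancels in the
  analysis and exercises gauge invariance.

Every generator takes an explicit integer seed and is bit-reproducible;
seeds never leak into the caller's RNG stream. What the surrogates do *not*
emulate: non-Gaussian tails, slow conformational switching (e.g. the
transient swings of the conjugated ring toward the head groups), couplings
between observables, and any genuine voltage response beyond the prescribed
per-condition means. Passing recovery tests therefore demonstrates the
*analysis* is correct and unbiased at the study's statistical scale — not
that the generator is a substitute for sampling real membrane dynamics.

## Ratiometric calibration through a Lorentzian line shape

Experiments rarely report peak positions; they report dual-wavelength
emission ratiometry — the intensity ratio at 620 and 560 nm — because the
ratio cancels dye concentration and collection efficiency. To compare peak
shifts with ratio data, the emission line is modelled as a Lorentzian with
a voltage-dependent peak:

$$F(\lambda; V) = \frac{I_{max}\,\Delta\lambda^2}
  {(\lambda - \lambda_{max}(V))^2 + \Delta\lambda^2},
  \qquad \lambda_{max}(V) = 605.97 - 0.0071\,V \text{ nm},$$

with $I_{max} = 153.4$ and $\Delta\lambda = 51.1$ nm. A deliberate design
decision documented prominently: $\Delta\lambda$ is the **half**-width at
half-maximum. The printed width value is convention-ambiguous in
isolation, but only the HWHM reading reproduces the measured ratiometric
calibration (relative ratio change ≈ −0.035 at 0 mV referenced to −100 mV,
≈ 3.5 × 10⁻⁴ per mV); the full-width reading predicts a value ~4.4× too
large and is explicitly rejected by a test. The measured calibration line
as printed carries a sign inconsistent with its own zero at −100 mV, so
package tests assert the value at 0 mV and magnitudes, not that sign.

`invert_ratio_slope()` converts a measured ratio-vs-voltage slope into a
peak-shift slope by linearising the ratio in the peak position at the 0 mV
geometry. The linearisation is accurate to well under 1% because
physiological peak shifts (< 1 nm per 100 mV) are tiny against the ~51 nm
line width; a round-trip property test (forward finite-difference slope,
then inversion) enforces the 1% bound across randomized geometries.
`fit_lineshape()` wraps Levenberg–Marquardt nonlinear least squares and
recovers noiseless synthetic spectra to numerical precision;
non-convergence raises a classed error with the optimizer diagnostics.

## Voltage-response fits

The emission response is linear only in a physiological window;
`fit_voltage_response()` therefore fits ordinary least squares inside a
window (default ±100 mV), excluding the ±500 mV conditions, which sit well
outside the linear-response range. The complementary
`average_shift_per_100mV()` uses the full-span endpoints; on the reference
emission table the two give 0.716 and 0.45 nm per 100 mV respectively, and
the discrepancy is itself the evidence of nonlinearity at extreme voltage.

## Transmembrane potential fraction

`potential_fraction_profile()` computes
$f(z) = \overline{\phi(V) - \phi(0)}^{xy} / V_{mp}$: an unweighted average
of the map difference over every xy voxel of each z slab, divided by the
applied potential. z-binning is the grid's native spacing (no re-binning).
$f$ is dimensionless, gauge invariant, and *not* clipped to [0, 1] — real
maps can over/undershoot near interfaces, so plateau assertions are made
only on synthetic fixtures where they are true by construction. No
symmetrization across leaflets is applied. `interpolate_f()` evaluates the
profile at atom positions (linear interpolation, end-value clamping) and
`coupling_fraction()` contracts it with a charge distribution,
$\sum_i q_i f(z_i)$.

## Numerical choices and degenerate inputs

* Zero-SD generators return exactly constant series (no RNG draw).
* `density_profile()` extends [min, max] outward to whole bins; `count`
  mode conserves the sample count exactly, `unit_peak` divides by the
  modal bin. Default bin width 0.5 Å (unstated in the source material;
  chosen at the resolution of the reported depth SDs).
* Condition summaries report population SDs over frames (divisor $n$): the
  ± values they mirror describe configurational spread, not standard
  errors; block SEs are carried in a separate column.
* Truncated-normal moment matching uses Nelder–Mead on squared moment
  errors with tolerance 1e-15; the achieved moments are equal to the
  requested ones to ~1e-7, far below every recovery tolerance.
* Singleton gap series produce a wavelength with `NA` standard error
  rather than an error: a single frame has a mean but no spread estimate.
* Ties in `tilt_angle` at the poles are handled by clamping the cosine to
  [−1, 1] before `acos`.

## Problem sizes

The bundled default configuration runs 10 conditions (2 states × 5
voltages) at $10^5$ frames per condition — the scale at which the block
standard errors match the reported uncertainty of the reference means —
and completes in a few seconds. Synthetic grid fixtures use 40 × 40 xy
voxels per slab (1 Å spacing) and 2 Å z slabs over a 70 Å box, matching
the slab-averaging statistics stated for the recovery tolerances.

## Known limitations

* The analysis consumes energy gaps, tracks, orientations and potential
  maps; it does not run MD, evaluate force fields, or solve the Poisson
  equation for the maps.
* The empirical offsets subsume all vibrational/reorganization physics
  into two constants; state-dependent reorganization is out of scope.
* The Lorentzian is the only line-shape model implemented; the fitting
  interface would admit other forms, but none are provided.
* Dipole-vector orientation statistics (as opposed to the N–N axis proxy)
  require atomic charges and full coordinates and are out of scope.
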
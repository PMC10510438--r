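## Transmembrane potential fraction: f(z) from paired electrostatic maps.

#' Construct a 3-D electrostatic potential grid
#'
#' Container for a time-averaged electrostatic potential map on a regular
#' orthogonal grid, the shape produced by Poisson solvers acting on MD
#' trajectories. Values are stored in mV on voxel nodes at
#' `origin + (i-1, j-1, k-1) * spacing`.
#'
#' @param values 3-D numeric array, mV.
#' @param origin Position of the first voxel node, Angstrom (length 3).
#' @param spacing Node spacing per axis, Angstrom (length 3 or scalar).
#' @return Object of class `potential_grid`.
#' @export
potential_grid <- function(values, origin, spacing) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort_anepps("`values` must be a 3-D array.", "bad_grid")
  }
  if (length(spacing) == 1L) spacing <- rep(as.numeric(spacing), 3L)
  if (length(origin) != 3L || length(spacing) != 3L || any(spacing <= 0)) {
    abort_anepps("`origin` must have length 3 and `spacing` must be positive.",
                 "bad_grid")
  }
  structure(
    list(values = values, origin = as.numeric(origin),
         spacing = as.numeric(spacing)),
    class = "potential_grid"
  )
}

#' @export
print.potential_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<potential_grid> %d x %d x %d voxels, spacing (%g, %g, %g) A, origin (%g, %g, %g) A\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    x$origin[1], x$origin[2], x$origin[3]
  ))
  cat(sprintf("  potential range: [%.3f, %.3f] mV\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.potential_grid <- function(x) dim(x$values)

grid_z_nodes <- function(grid) {
  grid$origin[3] + (seq_len(dim(grid$values)[3]) - 1L) * grid$spacing[3]
}

grids_congruent <- function(a, b, tol = 1e-8) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$spacing - b$spacing) < tol)
}

#' Uniform applied electric field from a membrane potential
#'
#' A membrane potential is imposed in simulation as a uniform field
#' perpendicular to the membrane, `E_z = V_mp / L_z`, where `L_z` is the
#' periodic box length along the membrane normal.
#'
#' @param v_mp Membrane potential, mV.
#' @param l_z Box length along z, Angstrom; must be positive.
#' @return Field in mV / Angstrom.
#' @examples
#' applied_field(-500, 70)
#' @export
applied_field <- function(v_mp, l_z) {
  if (!is.numeric(l_z) || any(!is.finite(l_z)) || any(l_z <= 0)) {
    abort_anepps("`l_z` must be positive.", "bad_box")
  }
  v_mp / l_z
}

#' Transmembrane potential fraction profile f(z)
#'
#' The fraction of an applied membrane potential felt at depth z: the
#' voxel-wise difference between the potential map at `v_mp` and the map at
#' 0 mV, averaged (unweighted) over each xy plane and divided by `v_mp`.
#' f(z) is dimensionless; in bulk water it plateaus at 0 on one side of the
#' membrane and 1 on the other, and it is invariant to any xy-independent
#' gauge shift common to both maps.
#'
#' @param grid_v [potential_grid] at applied potential `v_mp`, mV.
#' @param grid_0 Congruent [potential_grid] at 0 mV.
#' @param v_mp Applied potential of `grid_v`, mV; nonzero.
#' @return Tibble with columns `z` (Angstrom, strictly increasing) and `f`
#'   (dimensionless).
#' @export
potential_fraction_profile <- function(grid_v, grid_0, v_mp) {
  if (!inherits(grid_v, "potential_grid") || !inherits(grid_0, "potential_grid")) {
    abort_anepps("Inputs must be `potential_grid` objects.", "bad_grid")
  }
  if (v_mp == 0) {
    abort_anepps("`v_mp` must be nonzero.", "zero_voltage")
  }
  if (!grids_congruent(grid_v, grid_0)) {
    abort_anepps(
      "Grids are not congruent (dimensions, origin and spacing must match).",
      "incongruent_grids"
    )
  }
  diff <- grid_v$values - grid_0$values
  f <- apply(diff, 3, mean) / v_mp
  tibble(z = grid_z_nodes(grid_v), f = f)
}

#' Interpolate a potential-fraction profile
#'
#' Linear interpolation between profile nodes, clamped to the end values
#' outside the node range (bulk plateaus extend unchanged).
#'
#' @param profile Data frame with columns `z` and `f`.
#' @param z Positions at which to evaluate, Angstrom (vectorized).
#' @return Numeric vector of f values.
#' @export
interpolate_f <- function(profile, z) {
  if (is.null(profile$z) || is.null(profile$f) || length(profile$z) == 0L) {
    abort_anepps("`profile` must have nonempty `z` and `f` columns.",
                 "bad_profile")
  }
  if (length(profile$z) == 1L) {
    return(rep(profile$f[1], length(z)))
  }
  approx(profile$z, profile$f, xout = z, rule = 2)$y
}

#' Coupling of a charge distribution to the transmembrane potential
#'
#' The dimensionless coupling `sum_i q_i f(z_i)` of point charges to the
#' applied potential; the gradient of the charging energy with respect to
#' the membrane potential in units of elementary charge.
#'
#' @param charges Data frame with columns `q` (elementary charges) and `z`
#'   (Angstrom).
#' @param profile Data frame with columns `z`, `f`.
#' @return Single dimensionless number; linear in the charges.
#' @examples
#' prof <- tibble::tibble(z = c(-10, 10), f = c(0, 1))
#' coupling_fraction(tibble::tibble(q = c(1, -1), z = c(-5, 5)), prof)
#' @export
coupling_fraction <- function(charges, profile) {
  if (is.null(charges$q) || is.null(charges$z)) {
    abort_anepps("`charges` must have columns `q` and `z`.", "bad_charges")
  }
  sum(charges$q * interpolate_f(profile, charges$z))
}
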
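#' Double wall-ring (DWR) geometry
#'
#' Describes the annular double-gap channel and the diamond cross-section
#' ring probe of a DWR interfacial shear cell.  The sheared interface lies
#' in the two annular gaps `[R_i, R4]` and `[R5, R_o]`; the ring touches the
#' interface at the contact-line radii `R4` and `R5`, which are separated by
#' the horizontal diagonal of the diamond cross section.
#'
#' The probe length scale `a` is the wetted area-to-perimeter ratio of the
#' ring.  For a diamond cross section of side `L` the conventional choice is
#' `a = L` (two contact lines, wetted area `2 L` per unit contact-line
#' length), with `L = diagonal / sqrt(2)`.
#'
#' @param R_i inner cup wall radius (m).
#' @param R_o outer cup wall radius (m).
#' @param R4 inner contact-line radius of the ring (m).
#' @param R5 outer contact-line radius of the ring (m).  `R5 - R4` must
#'   equal the horizontal diagonal of the diamond.
#' @param diagonal diamond cross-section diagonal (m).
#' @param depth channel depth below the interface (m).
#' @param a probe area-to-perimeter length scale (m); defaults to
#'   `diagonal / sqrt(2)` (the diamond side length).
#' @return object of class `dwr_geometry`.
#' @examples
#' geom <- dwr_geometry()
#' geom$L * 1e3  # diamond side length in mm, ~0.707
#' @export
dwr_geometry <- function(R_i = 20e-3, R_o = 28.79e-3,
                         R4 = 23.0e-3, R5 = 24.0e-3,
                         diagonal = 1e-3, depth = 5e-3, a = NULL) {
  stopifnot(R_i > 0, R_o > R_i, depth > 0, diagonal > 0)
  if (!(R_i < R4 && R4 < R5 && R5 < R_o)) {
    stop("radii must satisfy R_i < R4 < R5 < R_o")
  }
  if (abs((R5 - R4) - diagonal) > 1e-9 * diagonal) {
    stop("R5 - R4 must equal the diamond diagonal")
  }
  L <- diagonal / sqrt(2)
  if (is.null(a)) a <- L
  stopifnot(a > 0)
  structure(
    list(R_i = R_i, R_o = R_o, R4 = R4, R5 = R5,
         diagonal = diagonal, L = L, depth = depth, a = a),
    class = "dwr_geometry"
  )
}

#' @export
print.dwr_geometry <- function(x, ...) {
  cat("DWR geometry (radii in mm):\n")
  cat(sprintf("  R_i = %.3f  R4 = %.3f  R5 = %.3f  R_o = %.3f\n",
              1e3 * x$R_i, 1e3 * x$R4, 1e3 * x$R5, 1e3 * x$R_o))
  cat(sprintf("  diamond diagonal = %.3f mm (side L = %.3f mm), depth = %.2f mm, a = %.3f mm\n",
              1e3 * x$diagonal, 1e3 * x$L, 1e3 * x$depth, 1e3 * x$a))
  invisible(x)
}

#' Rotor + probe dynamic parameters
#'
#' @param I moment of inertia of rotor plus DWR probe assembly (kg m^2).
#'   The default is a placeholder typical of an air-bearing rotational
#'   rheometer head with a titanium ring; calibrate against a clean
#'   interface with [calibrate_inertia()].
#' @param g1 high-Boussinesq geometric drag coefficient; computed from the
#'   geometry with [g1_coefficient()] when `NULL`.
#' @param geom `dwr_geometry`, used when `g1` is `NULL`.
#' @return object of class `probe_dynamics`.
#' @export
probe_dynamics <- function(I = 1.0e-5, g1 = NULL, geom = dwr_geometry()) {
  stopifnot(I > 0)
  if (is.null(g1)) g1 <- g1_coefficient(geom)
  stopifnot(g1 > 0)
  structure(list(I = I, g1 = g1), class = "probe_dynamics")
}

#' Bulk fluid phase
#'
#' @param eta dynamic viscosity (Pa s).
#' @param rho density (kg/m^3).
#' @param surface_tension interfacial tension against air (N/m), optional.
#' @return object of class `fluid_phase`.
#' @export
fluid_phase <- function(eta = 1.0e-3, rho = 998, surface_tension = 72e-3) {
  stopifnot(eta >= 0, rho > 0)
  structure(list(eta = eta, rho = rho, surface_tension = surface_tension),
            class = "fluid_phase")
}

#' Air as the upper phase (drag usually negligible)
#' @rdname fluid_phase
#' @export
air_phase <- function() fluid_phase(eta = 1.8e-5, rho = 1.2, surface_tension = NULL)

#' Average interfacial strain in the DWR gaps
#'
#' In the high-Boussinesq limit the interfacial displacement field in each
#' annular gap is the annular-Couette profile `A r + B / r` pinned at the
#' wall and moving with the ring at the contact line.  The local strain is
#' `gamma(r) = r d(u/r)/dr = -2 B / r^2`; this returns its area-weighted
#' average over both gaps, the strain value used to label oscillatory
#' measurements.
#'
#' @param theta0 angular displacement amplitude (rad).
#' @param geom `dwr_geometry`.
#' @return dimensionless average strain (linear in `theta0`).
#' @export
average_strain <- function(theta0, geom = dwr_geometry()) {
  stopifnot(theta0 >= 0)
  .check_gaps(geom)
  with(geom, {
    # inner gap: u(R_i) = 0, u(R4) = theta0 R4
    g_in <- 4 * R4^2 * R_i^2 * log(R4 / R_i) / (R4^2 - R_i^2)^2
    # outer gap: u(R5) = theta0 R5, u(R_o) = 0
    g_out <- 4 * R5^2 * R_o^2 * log(R_o / R5) / (R_o^2 - R5^2)^2
    A_in <- R4^2 - R_i^2
    A_out <- R_o^2 - R5^2
    theta0 * (g_in * A_in + g_out * A_out) / (A_in + A_out)
  })
}

#' High-Boussinesq geometric drag coefficient g1
#'
#' Torque exerted on the ring per unit interfacial modulus per radian of
#' displacement in the limit where the interface behaves as an elastic
#' (or viscous) plate spanning each gap with an annular-Couette profile:
#' `g1 = 4 pi (R_i^2 R4^2 / (R4^2 - R_i^2) + R5^2 R_o^2 / (R_o^2 - R5^2))`.
#' The closed form is validated against the flow-field solver's high-Bo
#' elastic limit in the package tests.
#'
#' @param geom `dwr_geometry`.
#' @return g1 (m^2 torque-per-modulus coefficient), strictly positive.
#' @export
g1_coefficient <- function(geom = dwr_geometry()) {
  .check_gaps(geom)
  with(geom, 4 * pi * (R_i^2 * R4^2 / (R4^2 - R_i^2) +
                       R5^2 * R_o^2 / (R_o^2 - R5^2)))
}

#' Inertia-limited modulus floor
#'
#' Below `G_lim = I omega^2 / g1` the rotor+probe inertia dominates the
#' torque balance and masks the interfacial response; moduli measured below
#' this floor are unreliable.  This is the dotted "inertia" sensitivity line
#' in operating-window plots, and equals the storage modulus at which the
#' amplitude-ratio resonance minimum occurs.
#'
#' @param I rotor+probe moment of inertia (kg m^2).
#' @param omega angular frequency (rad/s).
#' @param g1 geometric drag coefficient, see [g1_coefficient()].
#' @return modulus floor (N/m).
#' @export
inertia_limit <- function(I, omega, g1) {
  stopifnot(I > 0, omega >= 0, g1 > 0)
  I * omega^2 / g1
}

#' Capillary length of a fluid against air
#'
#' `sqrt(sigma / (rho g))` with `g = 9.81 m/s^2`; the length below which
#' surface tension dominates gravity.  Clean water gives about 2.7 mm,
#' which sets the minimum ring-to-wall distance for meniscus-free operation.
#'
#' @param sigma surface tension (N/m).
#' @param rho density (kg/m^3).
#' @return capillary length (m).
#' @export
capillary_length <- function(sigma, rho) {
  if (!(sigma > 0) || !(rho > 0)) stop("sigma and rho must be positive")
  sqrt(sigma / (rho * 9.81))
}

.check_gaps <- function(geom) {
  if (geom$R4 <= geom$R_i || geom$R_o <= geom$R5) {
    stop("degenerate geometry: zero-width gap (R4 = R_i or R5 = R_o)")
  }
  invisible(TRUE)
}
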
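# Shared fixtures: default instrument configuration and memoised meshes so
# repeated tests do not rebuild/resolve identical flow problems.

default_geom <- dwr_geometry()
default_dyn <- probe_dynamics(geom = default_geom)
water <- fluid_phase()

.mesh_memo <- new.env(parent = emptyenv())
test_mesh <- function(resolution = 16, geom = default_geom, two_phase = FALSE) {
  key <- paste(resolution, two_phase, signif(geom$R_i, 12), signif(geom$R_o, 12),
               signif(geom$R4, 12), signif(geom$depth, 12))
  m <- .mesh_memo[[key]]
  if (is.null(m)) {
    m <- build_mesh(geom, resolution, two_phase = two_phase)
    assign(key, m, envir = .mesh_memo)
  }
  m
}

# Boussinesq number of a purely elastic / purely viscous interface
bo_elastic <- function(Gp, omega, geom = default_geom, sub = water) {
  -1i * Gp / (omega * sub$eta * geom$a)
}
bo_viscous <- function(Gpp, omega, geom = default_geom, sub = water) {
  complex(real = Gpp / (omega * sub$eta * geom$a))
}

# Area-weighted average of the annular-Couette strain profile by quadrature;
# independent oracle for average_strain().
strain_quadrature <- function(theta0, geom) {
  gap_avg <- function(Ra, Rb, u_a, u_b) {
    # displacement u(r) = A r + B / r with u(Ra) = u_a, u(Rb) = u_b
    M <- matrix(c(Ra, 1 / Ra, Rb, 1 / Rb), 2, 2, byrow = TRUE)
    ab <- solve(M, c(u_a, u_b))
    gam <- function(r) abs(-2 * ab[2] / r^2)   # r d(u/r)/dr
    num <- stats::integrate(function(r) gam(r) * 2 * pi * r, Ra, Rb,
                            rel.tol = 1e-12)$value
    c(num = num, area = pi * (Rb^2 - Ra^2))
  }
  g1v <- gap_avg(geom$R_i, geom$R4, 0, theta0 * geom$R4)
  g2v <- gap_avg(geom$R5, geom$R_o, theta0 * geom$R5, 0)
  (g1v["num"] + g2v["num"]) / (g1v["area"] + g2v["area"])
}
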
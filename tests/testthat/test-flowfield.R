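test_that("mesh snaps nodes onto the key radii and scales with resolution", {
  m8 <- build_mesh(default_geom, 8)
  expect_true(all(c(default_geom$R_i, default_geom$R4, default_geom$R5,
                    default_geom$R_o) %in% m8$r))
  expect_gte(m8$i4, 9)                      # >= 8 intervals across [R_i, R4]
  m16 <- build_mesh(default_geom, 16)
  dr8 <- diff(m8$r[1:2]); dr16 <- diff(m16$r[1:2])
  expect_equal(dr16, dr8 / 2, tolerance = 1e-12)
  expect_error(build_mesh(default_geom, 4), "too coarse")
  # contact-line nodes are probe nodes on the interface row
  expect_identical(m8$mask[m8$i4, m8$jz0], 2L)
  expect_identical(m8$mask[m8$i5, m8$jz0], 2L)
  # interface row is interface or wall outside the ring band
  expect_true(all(m8$mask[2:(m8$i4 - 1L), m8$jz0] == 3L))
})

test_that("high-Bo limit reproduces the annular-Couette interface profile", {
  omega <- 2 * pi * 0.5
  mesh <- test_mesh(16)
  Bo <- bo_elastic(1e6 * omega * water$eta * default_geom$a, omega)
  sol <- solve_field(mesh, Bo, omega, include_fluid_inertia = FALSE)
  i4 <- mesh$i4
  rr <- mesh$r[2:(i4 - 1L)]
  A <- default_geom$R4^2 / (default_geom$R4^2 - default_geom$R_i^2)
  B <- -A * default_geom$R_i^2
  u_exact <- A * rr + B / rr
  expect_lt(max(Mod(sol$u[2:(i4 - 1L), mesh$jz0] - u_exact) / abs(u_exact)),
            0.005)
})

test_that("g1 closed form matches the solver's high-Bo elastic limit on three geometries", {
  geoms <- list(
    default_geom,
    dwr_geometry(R_i = 15e-3, R_o = 30e-3, R4 = 21e-3, R5 = 23e-3, diagonal = 2e-3),
    dwr_geometry(R_i = 22e-3, R_o = 32e-3, R4 = 26e-3, R5 = 26.5e-3,
                 diagonal = 0.5e-3, depth = 6e-3)
  )
  omega <- 2 * pi * 0.5
  for (g in geoms) {
    Gp <- 1e6 * omega * water$eta * g$a
    mesh <- build_mesh(g, 16)
    sol <- solve_field(mesh, bo_elastic(Gp, omega, g), omega,
                       include_fluid_inertia = FALSE)
    K <- compute_drags(sol, mesh)
    g1_num <- Re(1i * omega * K$K_i / Gp)
    expect_equal(g1_num, g1_coefficient(g), tolerance = 0.01)
  }
})

test_that("drag coefficients converge at second order under mesh refinement", {
  omega <- 2 * pi * 0.5
  Bo <- 1e4 + 0i
  Ks <- lapply(c(12, 24, 48), function(res) {
    mesh <- build_mesh(default_geom, res)
    sol <- solve_field(mesh, Bo, omega)
    compute_drags(sol, mesh)
  })
  rat <- function(get) {
    v <- vapply(Ks, get, complex(1))
    Mod(v[1] - v[2]) / Mod(v[2] - v[3])
  }
  expect_gt(rat(function(K) K$K_i), 3.5)
  expect_lt(rat(function(K) K$K_i), 4.5)
  expect_gt(rat(function(K) K$K_b), 3.5)
  expect_lt(rat(function(K) K$K_b), 4.5)
})

test_that("interfacial drag magnitude is monotone in |Bo|", {
  omega <- 2 * pi * 0.5
  mesh <- test_mesh(12)
  mods <- vapply(c(0, 1e-2, 1, 1e2, 1e4, 1e6), function(bo) {
    Mod(flow_drags(mesh, bo + 0i, omega)$K_i)
  }, numeric(1))
  expect_true(all(diff(mods) >= 0))
})

test_that("drags are real for viscous interfaces when fluid inertia is off", {
  omega <- 2 * pi * 0.5
  mesh <- test_mesh(12)
  sol <- solve_field(mesh, 10 + 0i, omega, include_fluid_inertia = FALSE)
  K <- compute_drags(sol, mesh)
  expect_lt(abs(Arg(K$K_i)), 1e-8)
  expect_lt(abs(Arg(K$K_b)), 1e-8)
  expect_gt(Re(K$K_b), 0)
  # with inertia on, the phases shrink as omega -> 0
  ph <- vapply(2 * pi * c(1, 0.1, 0.01), function(om) {
    Arg(flow_drags(mesh, 10 + 0i, om)$K_b)
  }, numeric(1))
  expect_true(all(diff(abs(ph)) < 0))
})

test_that("zero interfacial viscosity gives zero interfacial drag", {
  mesh <- test_mesh(12)
  K <- flow_drags(mesh, 0 + 0i, 2 * pi * 0.5)
  expect_identical(Mod(K$K_i), 0)
  expect_gt(Re(K$K_b), 0)
})

test_that("two-phase solve runs and adds a small upper-phase drag", {
  omega <- 2 * pi * 0.5
  mesh1 <- test_mesh(12)
  mesh2 <- test_mesh(12, two_phase = TRUE)
  K1 <- flow_drags(mesh1, 10 + 0i, omega)
  K2 <- flow_drags(mesh2, 10 + 0i, omega, top = air_phase())
  expect_gt(Re(K2$K_b), Re(K1$K_b))          # air adds drag ...
  expect_lt(Re(K2$K_b - K1$K_b) / Re(K1$K_b), 0.05)  # ... but a tiny one
})

test_that("flow-field dump writes a readable r-z table", {
  mesh <- test_mesh(12)
  sol <- solve_field(mesh, 1 + 0i, 2 * pi * 0.5)
  path <- tempfile(fileext = ".tsv")
  write_flow_field(sol, mesh, path)
  df <- read.delim(path)
  expect_named(df, c("r", "z", "Re_u", "Im_u"))
  expect_equal(nrow(df), mesh$nr * mesh$nz)
})
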
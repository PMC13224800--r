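test_that("momentum transfer follows 4 pi sin(theta) / lambda", {
  expect_identical(qz_from_angle(0, 2), 0)
  expect_equal(qz_from_angle(0.62, 2), 0.0680, tolerance = 1e-3)
  expect_equal(qz_from_angle(1, 4), qz_from_angle(1, 2) / 2, tolerance = 1e-12)
})

test_that("the molecular constraints reproduce the tail thickness and head hydration", {
  for (case in list(list(A = 46.66, d = 16.27, solv = 18),
                    list(A = 44.42, d = 17.09, solv = 14),
                    list(A = 43.60, d = 17.41, solv = 12))) {
    m <- lipid_monolayer(A_mol = case$A)
    s <- lipid_to_slabs(m, "D2O")
    expect_equal(round(s[[2]]$thickness, 2), case$d)
    expect_equal(round(100 * s[[3]]$solvent_fraction), case$solv)
    expect_identical(s[[2]]$solvent_fraction, 0)
    # tail-volume constraint holds exactly
    expect_equal(s[[2]]$thickness * case$A, 759, tolerance = 1e-9)
  }
  # complete head filling at A_mol = V_head / d_head
  m0 <- lipid_monolayer(A_mol = 344 / 9)
  expect_equal(lipid_to_slabs(m0, "D2O")[[3]]$solvent_fraction, 0, tolerance = 1e-12)
  expect_error(lipid_monolayer(A_mol = 30), "over-packed")
})

test_that("Abeles model matches Fresnel and the critical edge of bare D2O", {
  qz <- seq(0.004, 0.06, by = 5e-5)
  stack <- list(nr_slab(0, 0), nr_slab(0, 6.36))
  R <- abeles_reflectivity(stack, qz)
  # Fresnel closed form for a single sharp interface
  k0 <- qz / 2
  k1 <- sqrt(as.complex(k0^2 - 4 * pi * 6.36e-6))
  expect_equal(R, Mod((k0 - k1) / (k0 + k1))^2, tolerance = 1e-12)
  # total reflection below the critical edge
  Qc <- sqrt(16 * pi * 6.36e-6)
  expect_true(all(R[qz < Qc] > 1 - 1e-10))
  edge <- max(qz[R > 0.999])
  expect_lt(abs(edge - Qc), 2 * 5e-5)
  # no contrast, no reflection
  Ru <- abeles_reflectivity(list(nr_slab(0, 3), nr_slab(25, 3), nr_slab(0, 3)), qz)
  expect_lt(max(Ru), 1e-20)
  expect_error(abeles_reflectivity(list(nr_slab(0, 0), nr_slab(-1, 2), nr_slab(0, 4)), qz),
               "negative slab thickness")
})

test_that("resolution smearing is the identity at zero width and preserves plateaus", {
  qz <- exp(seq(log(0.008), log(0.2), length.out = 200))
  stack <- list(nr_slab(0, 0), nr_slab(0, 6.36))
  fn <- function(q) abeles_reflectivity(stack, q)
  expect_equal(smear_resolution(fn, qz, 0), fn(qz), tolerance = 1e-14)
  Rs <- smear_resolution(fn, qz, 0.07)
  expect_equal(Rs[qz < 0.012], rep(1, sum(qz < 0.012)), tolerance = 1e-6)
})

test_that("smearing damps Kiessig fringes, matching a quadrature oracle", {
  stack <- list(nr_slab(0, 0), nr_slab(200, 4), nr_slab(0, 6.36))
  fn <- function(q) abeles_reflectivity(stack, q)
  qz <- seq(0.05, 0.12, by = 2e-4)
  R0 <- fn(qz)
  Rs <- smear_resolution(fn, qz, 0.05)
  contrast <- function(R) (max(R) - min(R)) / (max(R) + min(R))
  expect_lt(contrast(Rs), contrast(R0))
  # independent oracle: dense trapezoid convolution at one point
  q0 <- 0.08
  sig <- 0.05 * q0 / (2 * sqrt(2 * log(2)))
  qq <- seq(q0 - 6 * sig, q0 + 6 * sig, length.out = 4001)
  w <- exp(-(qq - q0)^2 / (2 * sig^2))
  oracle <- sum(w * fn(qq)) / sum(w)
  ours <- smear_resolution(fn, q0, 0.05)
  expect_equal(ours, oracle, tolerance = 1e-3)
})

test_that("volume fractions sum to one and have the right asymptotics", {
  m <- lipid_monolayer()
  z <- seq(-30, 60, by = 0.2)
  vf <- volume_fraction_profile(m, z)
  expect_lt(max(abs(rowSums(vf[, -1]) - 1)), 1e-10)
  expect_equal(vf$air[1], 1, tolerance = 1e-6)
  expect_equal(vf$water[length(z)], 1, tolerance = 1e-6)
  # SLD profile reconstructed from fractions matches the broadened slab model
  for (cn in c("D2O", "ACMW")) {
    sp <- sld_profile(m, cn, z)
    slabs <- lipid_to_slabs(m, cn)
    # slab SLD profile with the same erf broadening
    zi <- c(0, slabs[[2]]$thickness, slabs[[2]]$thickness + slabs[[3]]$thickness)
    occ <- vapply(1:3, function(k) stats::pnorm((z - zi[k]) / m$sigma), numeric(length(z)))
    slab_sld <- (occ[, 1] - occ[, 2]) * Re(slabs[[2]]$sld) +
      (occ[, 2] - occ[, 3]) * Re(slabs[[3]]$sld) +
      occ[, 3] * m$contrasts[[cn]]$sld_subphase
    scale <- max(abs(slab_sld))
    expect_lt(max(abs(sp$sld - slab_sld)) / scale, 0.005)
  }
})

test_that("ACMW composition solves the zero-SLD mixing rule", {
  x <- acmw_fraction(6.36, -0.56)
  expect_equal(x$volume_fraction, 0.0809, tolerance = 1e-3)
  expect_equal(acmw_fraction(6.36, 0 - 1e-12)$volume_fraction, 0, tolerance = 1e-10)
  # invariant under common scaling
  expect_equal(acmw_fraction(2 * 6.36, 2 * -0.56)$volume_fraction,
               x$volume_fraction, tolerance = 1e-12)
  expect_error(acmw_fraction(6.36, 0.56), "contrast-match")
})

test_that("co-refinement recovers the area per molecule from two contrasts", {
  truth <- lipid_monolayer(A_mol = 46.66)
  curves <- simulate_reflectivity(truth, c("ACMW", "D2O"), noise = 0.05, seed = 21)
  start <- lipid_monolayer(A_mol = 50)
  fit <- corefine(curves, start)
  expect_lt(abs(fit$par["A_mol"] - 46.66) / 46.66, 0.01)
  expect_lt(fit$chisq_total / fit$dof, 2)
  # noiseless single curve: chi-square at the numerical floor
  clean <- simulate_reflectivity(truth, "D2O", noise = 0, seed = 1)
  fit0 <- corefine(clean, truth, free = "A_mol")
  expect_lt(fit0$chisq_total, 1e-10)
  # with A_mol fixed at truth, only background-level residuals remain
  fitbg <- corefine(clean, truth, free = "background:D2O")
  expect_lt(fitbg$chisq_total, 1e-6)
})

test_that("ORSO-style files round-trip and malformed files carry line numbers", {
  qz <- exp(seq(log(0.01), log(0.3), length.out = 40))
  cv <- reflectivity_curve(qz, exp(-qz * 50), 0.05 * exp(-qz * 50),
                           dq = 0.07 * qz, contrast = "D2O")
  path <- tempfile(fileext = ".ort")
  write_ort(cv, path)
  back <- read_ort(path)
  expect_equal(back$qz, cv$qz, tolerance = 1e-8)
  expect_equal(back$R, cv$R, tolerance = 1e-8)
  expect_identical(back$contrast, "D2O")
  bad <- tempfile(fileext = ".ort")
  writeLines(c("# hdr", "0.01 1.0 0.05", "0.02 bad 0.05"), bad)
  expect_error(read_ort(bad), "line 3")
})
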
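# Specular neutron reflectivity: Abeles transfer-matrix forward model with
# Nevot-Croce roughness, constant dQ/Q Gaussian resolution smearing, a
# molecularly constrained two-layer lipid-monolayer model, and co-refinement
# of several isotopic contrasts against a shared structural model.
#
# Units follow reflectometry convention: lengths in Angstrom, SLD in
# 1e-6 A^-2 (the factor is applied internally), Qz in A^-1.

#' Momentum transfer from incidence angle and wavelength
#'
#' `Qz = 4 pi sin(theta) / lambda` for specular reflection.
#'
#' @param theta angle of incidence (degrees).
#' @param lam neutron wavelength (Angstrom).
#' @return Qz (1/Angstrom).
#' @export
qz_from_angle <- function(theta, lam) {
  stopifnot(lam > 0)
  4 * pi * sin(theta * pi / 180) / lam
}

#' A slab of the interfacial model
#'
#' @param thickness slab thickness (Angstrom, >= 0).
#' @param sld scattering length density (1e-6 A^-2), complex allowed.
#' @param roughness Gaussian roughness of the interface to the slab above
#'   (Angstrom).
#' @param solvent_fraction volume fraction of solvent mixed into the slab.
#' @return list of class `nr_slab`.
#' @export
nr_slab <- function(thickness, sld, roughness = 0, solvent_fraction = 0) {
  if (thickness < 0) stop("negative slab thickness")
  stopifnot(roughness >= 0, solvent_fraction >= 0, solvent_fraction <= 1)
  structure(list(thickness = thickness, sld = sld, roughness = roughness,
                 solvent_fraction = solvent_fraction), class = "nr_slab")
}

#' Constrained two-layer lipid monolayer model
#'
#' Tail (acyl chain) and headgroup layers sharing one area per molecule:
#' the tail layer is fully occupied, so its thickness is
#' `d_AC = V_AC / A_mol`; the headgroup layer of fixed thickness `d_head`
#' is filled up with solvent, `phi_solv = 1 - V_head / (A_mol d_head)`.
#' The same structural parameters describe every isotopic contrast; only
#' the subphase SLD and background differ per contrast.
#'
#' Defaults describe a chain-deuterated DPPC monolayer: tail volume for the
#' condensed phase, phosphatidylcholine head volume, literature component
#' SLDs.
#'
#' @param A_mol area per molecule (A^2).
#' @param V_AC acyl-chain (tail) volume (A^3).
#' @param V_head headgroup volume (A^3).
#' @param d_head headgroup layer thickness (A).
#' @param sld_AC,sld_head component SLDs (1e-6 A^-2).
#' @param sigma interfacial roughness (A), applied at all interfaces
#'   (capillary-wave value; per-interface override via `sigma_each`).
#' @param sigma_each optional length-3 vector: roughness at the air/tail,
#'   tail/head and head/subphase interfaces.
#' @param contrasts named list per contrast: each a list with `sld_subphase`
#'   (1e-6 A^-2) and `background`.
#' @return object of class `lipid_monolayer`.
#' @export
lipid_monolayer <- function(A_mol = 46.66, V_AC = 759, V_head = 344,
                            d_head = 9, sld_AC = 8.08, sld_head = 1.74,
                            sigma = 3.45, sigma_each = NULL,
                            contrasts = list(
                              D2O = list(sld_subphase = 6.36, background = 5e-7),
                              ACMW = list(sld_subphase = 0, background = 5e-6))) {
  stopifnot(A_mol > 0, V_AC > 0, V_head > 0, d_head > 0, sigma >= 0)
  phi_solv <- 1 - V_head / (A_mol * d_head)
  if (phi_solv < 0 || phi_solv > 1) {
    stop("headgroup solvent fraction outside [0, 1] (over-packed heads)")
  }
  structure(
    list(A_mol = A_mol, V_AC = V_AC, V_head = V_head, d_head = d_head,
         sld_AC = sld_AC, sld_head = sld_head, sigma = sigma,
         sigma_each = sigma_each, contrasts = contrasts),
    class = "lipid_monolayer"
  )
}

#' @export
print.lipid_monolayer <- function(x, ...) {
  cat(sprintf("lipid monolayer: A_mol = %.2f A^2, d_AC = %.2f A, head solvent = %.1f%%\n",
              x$A_mol, x$V_AC / x$A_mol, 100 * (1 - x$V_head / (x$A_mol * x$d_head))))
  invisible(x)
}

#' Expand the lipid model into a slab stack for one contrast
#'
#' Stack order from the incident medium: air | tails | heads | subphase.
#' The tail slab has thickness `V_AC / A_mol` and no solvent (full
#' occupancy); the head slab of thickness `d_head` carries solvent fraction
#' `1 - V_head / (A_mol d_head)` and its effective SLD is the volume mix of
#' headgroup and subphase SLDs.
#'
#' @param model `lipid_monolayer`.
#' @param contrast contrast name (must exist in `model$contrasts`).
#' @return list of `nr_slab` (air and subphase as semi-infinite slabs of
#'   zero thickness at the ends) with attributes `background` and
#'   `contrast`.
#' @export
lipid_to_slabs <- function(model, contrast = names(model$contrasts)[1]) {
  cc <- model$contrasts[[contrast]]
  if (is.null(cc)) stop("unknown contrast: ", contrast)
  d_AC <- model$V_AC / model$A_mol
  phi_solv <- 1 - model$V_head / (model$A_mol * model$d_head)
  if (phi_solv < 0 || phi_solv > 1) {
    stop("headgroup solvent fraction outside [0, 1] (over-packed heads)")
  }
  sig <- model$sigma_each %||% rep(model$sigma, 3)
  sld_head_eff <- (1 - phi_solv) * model$sld_head + phi_solv * cc$sld_subphase
  out <- list(
    nr_slab(0, 0),                                        # air
    nr_slab(d_AC, model$sld_AC, roughness = sig[1]),      # tails
    nr_slab(model$d_head, sld_head_eff, roughness = sig[2],
            solvent_fraction = phi_solv),                 # heads
    nr_slab(0, cc$sld_subphase, roughness = sig[3])       # subphase
  )
  attr(out, "background") <- cc$background %||% 0
  attr(out, "contrast") <- contrast
  out
}

#' Abeles (optical transfer-matrix) specular reflectivity
#'
#' Standard slab-model reflectivity with Nevot-Croce Gaussian-roughness
#' damping of the interfacial Fresnel coefficients.
#'
#' @param stack list of `nr_slab` ordered from the incident medium; first
#'   and last are the semi-infinite media (their thicknesses are ignored).
#' @param qz momentum-transfer grid (1/A), strictly positive.
#' @return reflectivity R(qz) in `[0, 1]`.
#' @export
abeles_reflectivity <- function(stack, qz) {
  stopifnot(all(qz > 0))
  nlay <- length(stack)
  if (nlay < 2) stop("need at least incident medium and substrate")
  th <- vapply(stack, function(s) s$thickness, numeric(1))
  if (any(th < 0)) stop("negative slab thickness")
  sld <- vapply(stack, function(s) as.complex(s$sld), complex(1)) * 1e-6
  rough <- vapply(stack, function(s) s$roughness, numeric(1))
  nq <- length(qz)
  k0 <- qz / 2
  # kz in each layer relative to the incident medium
  kz <- matrix(0+0i, nq, nlay)
  for (n in seq_len(nlay)) {
    kz[, n] <- sqrt(as.complex(k0^2 - 4 * pi * (sld[n] - sld[1])))
  }
  M11 <- rep(1+0i, nq); M12 <- rep(0i, nq)
  M21 <- rep(0i, nq); M22 <- rep(1+0i, nq)
  for (n in 1:(nlay - 1L)) {
    kn <- kz[, n]; knn <- kz[, n + 1L]
    rr <- (kn - knn) / (kn + knn) * exp(-2 * kn * knn * rough[n + 1L]^2)
    beta <- if (n == 1L) rep(0+0i, nq) else 1i * kn * th[n]
    e <- exp(beta)
    # layer matrix [[e, r e], [r/e, 1/e]]
    a11 <- e; a12 <- rr * e; a21 <- rr / e; a22 <- 1 / e
    n11 <- M11 * a11 + M12 * a21
    n12 <- M11 * a12 + M12 * a22
    n21 <- M21 * a11 + M22 * a21
    n22 <- M21 * a12 + M22 * a22
    M11 <- n11; M12 <- n12; M21 <- n21; M22 <- n22
  }
  R <- Mod(M21 / M11)^2
  pmin(R, 1)
}

#' Constant-relative-resolution Gaussian smearing
#'
#' Convolves a model reflectivity with a Gaussian of FWHM
#' `dq_over_q * Qz` at each point (time-of-flight wavelength resolution,
#' e.g. 7 percent), by Gauss-Hermite quadrature on the model function.
#'
#' @param R_model function of qz returning reflectivity (e.g. a closure
#'   over [abeles_reflectivity()]), or a numeric vector on `qz` (then
#'   interpolated).
#' @param qz evaluation grid (1/A).
#' @param dq_over_q relative FWHM of the resolution function; 0 = identity.
#' @param n_nodes quadrature nodes.
#' @return smeared reflectivity on `qz`.
#' @export
smear_resolution <- function(R_model, qz, dq_over_q, n_nodes = 17) {
  stopifnot(dq_over_q >= 0)
  fn <- if (is.function(R_model)) {
    R_model
  } else {
    stopifnot(length(R_model) == length(qz))
    function(q) exp(stats::approx(log(qz), log(pmax(R_model, 1e-300)),
                                  xout = log(q), rule = 2)$y)
  }
  if (dq_over_q == 0) return(fn(qz))
  gh <- .gauss_hermite(n_nodes)
  sigma <- dq_over_q * qz / (2 * sqrt(2 * log(2)))
  out <- numeric(length(qz))
  wsum <- sum(gh$w)
  for (k in seq_along(gh$x)) {
    qk <- qz + sqrt(2) * sigma * gh$x[k]
    qk <- pmax(qk, 1e-6)
    out <- out + gh$w[k] * fn(qk)
  }
  out / wsum
}

# Gauss-Hermite nodes/weights via the Golub-Welsch eigenvalue method.
.gauss_hermite <- function(n) {
  od <- sqrt(seq_len(n - 1) / 2)
  J <- diag(0, n)
  J[cbind(1:(n - 1), 2:n)] <- od
  J[cbind(2:n, 1:(n - 1))] <- od
  ev <- eigen(J, symmetric = TRUE)
  list(x = ev$values, w = sqrt(pi) * ev$vectors[1, ]^2)
}

#' Forward reflectivity of a lipid model for one contrast
#'
#' @param model `lipid_monolayer`.
#' @param contrast contrast name.
#' @param qz grid (1/A).
#' @param dq_over_q resolution FWHM fraction.
#' @return reflectivity including the contrast's constant background.
#' @export
lipid_reflectivity <- function(model, contrast, qz, dq_over_q = 0.07) {
  stack <- lipid_to_slabs(model, contrast)
  Rfun <- function(q) abeles_reflectivity(stack, q)
  smear_resolution(Rfun, qz, dq_over_q) + attr(stack, "background")
}

#' Simulate reflectivity curves with counting noise
#'
#' Generates ORSO-style curves from a lipid model: relative Gaussian noise
#' (a proxy for Poisson counting statistics at moderate count rates) on
#' the smeared model curve.
#'
#' @param model `lipid_monolayer`.
#' @param contrasts contrast names; default all in the model.
#' @param qz grid; default logarithmic 0.01-0.35 1/A, 120 points.
#' @param noise relative noise level (e.g. 0.05 for 5 percent).
#' @param dq_over_q resolution FWHM fraction.
#' @param seed RNG seed.
#' @return named list of `reflectivity_curve` objects.
#' @export
simulate_reflectivity <- function(model, contrasts = names(model$contrasts),
                                  qz = exp(seq(log(0.01), log(0.35),
                                               length.out = 120)),
                                  noise = 0.05, dq_over_q = 0.07, seed = 1) {
  set.seed(seed)
  out <- lapply(contrasts, function(cn) {
    R <- lipid_reflectivity(model, cn, qz, dq_over_q)
    dR <- pmax(noise * R, 1e-12)
    Robs <- R * (1 + if (noise > 0) stats::rnorm(length(R), 0, noise) else 0)
    reflectivity_curve(qz, pmax(Robs, 0), dR, dq = dq_over_q * qz, contrast = cn)
  })
  stats::setNames(out, contrasts)
}

#' Reduced specular reflectivity curve
#'
#' @param qz momentum transfer grid (1/A), strictly increasing.
#' @param R reflectivity (>= 0).
#' @param dR uncertainties (>= 0).
#' @param dq resolution widths (1/A), optional.
#' @param contrast label.
#' @return object of class `reflectivity_curve`.
#' @export
reflectivity_curve <- function(qz, R, dR, dq = NULL, contrast = "") {
  stopifnot(length(qz) == length(R), length(R) == length(dR))
  if (any(qz <= 0) || any(diff(qz) <= 0)) stop("qz must be positive and strictly increasing")
  if (any(R < 0)) stop("negative reflectivity")
  if (any(dR < 0)) stop("negative uncertainty")
  structure(list(qz = qz, R = R, dR = dR, dq = dq, contrast = contrast),
            class = "reflectivity_curve")
}

#' Co-refine a lipid model against one or more contrasts
#'
#' Minimizes the pooled chi-square
#' `sum_curves sum_q ((R_model - R) / dR)^2` over the free parameters,
#' sharing the structural parameters across contrasts.  By default the
#' area per molecule and each contrast's subphase SLD are free while the
#' molecular volumes, head thickness, roughness and backgrounds stay fixed
#' at their literature/capillary-wave values.  Levenberg-Marquardt with a
#' small multi-start on `A_mol` guards against fringe-aliasing minima.
#'
#' @param curves named list of `reflectivity_curve`s; names must match
#'   model contrasts.
#' @param model starting `lipid_monolayer`.
#' @param free character vector of free parameters among
#'   `"A_mol"`, `"sigma"`, `"d_head"`, `"sld_subphase:<contrast>"`,
#'   `"background:<contrast>"`.
#' @param dq_over_q resolution used for the model curves.
#' @param n_starts multi-start count (perturbs `A_mol`).
#' @return list: fitted `model`, `par` (named estimates), `se` (from the
#'   local quadratic approximation), `chisq` per curve, `chisq_total`,
#'   `dof`, convergence `info`.
#' @export
corefine <- function(curves, model,
                     free = c("A_mol",
                              paste0("sld_subphase:",
                                     intersect(names(curves), "D2O"))),
                     dq_over_q = 0.07, n_starts = 3) {
  stopifnot(length(curves) >= 1)
  if (is.null(names(curves)) || any(!nzchar(names(curves)))) {
    stop("curves must be a named list (names = contrasts)")
  }
  free <- free[nzchar(free)]

  apply_par <- function(model, p) {
    for (nm in names(p)) {
      if (nm %in% c("A_mol", "sigma", "d_head")) {
        model[[nm]] <- p[[nm]]
      } else if (grepl("^sld_subphase:", nm)) {
        cn <- sub("^sld_subphase:", "", nm)
        model$contrasts[[cn]]$sld_subphase <- p[[nm]]
      } else if (grepl("^background:", nm)) {
        cn <- sub("^background:", "", nm)
        model$contrasts[[cn]]$background <- p[[nm]]
      } else stop("unknown free parameter: ", nm)
    }
    model
  }
  start_of <- function(nm) {
    if (nm %in% c("A_mol", "sigma", "d_head")) model[[nm]]
    else if (grepl("^sld_subphase:", nm)) {
      model$contrasts[[sub("^sld_subphase:", "", nm)]]$sld_subphase
    } else model$contrasts[[sub("^background:", "", nm)]]$background
  }
  p0 <- stats::setNames(vapply(free, start_of, numeric(1)), free)

  resid_fn <- function(pvec) {
    p <- stats::setNames(as.list(pvec), free)
    m <- tryCatch(apply_par(model, p), error = function(e) NULL)
    if (is.null(m)) return(rep(1e6, sum(vapply(curves, function(cv) length(cv$qz), 1L))))
    unlist(lapply(names(curves), function(cn) {
      cv <- curves[[cn]]
      Rm <- tryCatch(lipid_reflectivity(m, cn, cv$qz, dq_over_q),
                     error = function(e) NULL)
      if (is.null(Rm)) return(rep(1e6, length(cv$qz)))
      (Rm - cv$R) / pmax(cv$dR, 1e-300)
    }))
  }

  starts <- list(p0)
  if (n_starts > 1 && "A_mol" %in% free) {
    for (fct in c(0.9, 1.1)[seq_len(min(2, n_starts - 1))]) {
      pk <- p0; pk["A_mol"] <- p0["A_mol"] * fct
      starts <- c(starts, list(pk))
    }
  }
  best <- NULL
  for (ps in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = ps, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("co-refinement failed to converge from any start")

  par <- stats::setNames(as.numeric(best$par), free)
  fitted_model <- apply_par(model, as.list(par))
  n_obs <- sum(vapply(curves, function(cv) length(cv$qz), 1L))
  dof <- n_obs - length(free)
  # standard errors from the local quadratic approximation (J'J)
  se <- tryCatch({
    covm <- solve(best$hessian) * best$deviance / max(dof, 1)
    stats::setNames(sqrt(pmax(diag(covm), 0)), free)
  }, error = function(e) stats::setNames(rep(NA_real_, length(free)), free))
  chisq <- vapply(names(curves), function(cn) {
    cv <- curves[[cn]]
    Rm <- lipid_reflectivity(fitted_model, cn, cv$qz, dq_over_q)
    sum(((Rm - cv$R) / pmax(cv$dR, 1e-300))^2)
  }, numeric(1))
  list(model = fitted_model, par = par, se = se, chisq = chisq,
       chisq_total = sum(chisq), dof = dof,
       info = list(niter = best$niter, message = best$message,
                   deviance = best$deviance))
}

#' Volume-fraction depth profiles of the monolayer components
#'
#' Error-function-broadened (roughness sigma) profiles of air, tails,
#' heads and water versus depth; the origin of `z` is the air-tails
#' dividing surface and `z` increases into the subphase.  The fractions
#' sum to one at every depth by construction.
#'
#' @param model `lipid_monolayer`.
#' @param z_grid depths (A).
#' @return data.frame with columns `z, air, tails, heads, water`.
#' @export
volume_fraction_profile <- function(model, z_grid = seq(-20, 40, by = 0.25)) {
  d_AC <- model$V_AC / model$A_mol
  phi_solv <- 1 - model$V_head / (model$A_mol * model$d_head)
  sig <- model$sigma_each %||% rep(model$sigma, 3)
  # interface positions: air|tails at 0, tails|heads at d_AC,
  # heads|subphase at d_AC + d_head
  zi <- c(0, d_AC, d_AC + model$d_head)
  step <- function(z, z0, s) 0.5 * (1 + .erf((z - z0) / (s * sqrt(2))))
  occ1 <- step(z_grid, zi[1], sig[1])       # below air|tails surface
  occ2 <- step(z_grid, zi[2], sig[2])       # below tails|heads surface
  occ3 <- step(z_grid, zi[3], sig[3])       # below heads|subphase surface
  air <- 1 - occ1
  tails <- occ1 - occ2
  heads <- (occ2 - occ3) * (1 - phi_solv)
  water <- (occ2 - occ3) * phi_solv + occ3
  data.frame(z = z_grid, air = air, tails = tails, heads = heads, water = water)
}

.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' SLD depth profile of the monolayer for one contrast
#'
#' Component volume fractions weighted by component SLDs; consistent with
#' the slab model in the limit of the same roughness convention.
#'
#' @param model `lipid_monolayer`.
#' @param contrast contrast name.
#' @param z_grid depths (A).
#' @return data.frame with columns `z, sld` (1e-6 A^-2).
#' @export
sld_profile <- function(model, contrast, z_grid = seq(-20, 40, by = 0.25)) {
  vf <- volume_fraction_profile(model, z_grid)
  sld_w <- model$contrasts[[contrast]]$sld_subphase
  data.frame(z = z_grid,
             sld = vf$tails * model$sld_AC + vf$heads * model$sld_head +
               vf$water * sld_w)
}

#' D2O fraction of air contrast matched water (ACMW)
#'
#' Solves `x sld_D2O + (1 - x) sld_H2O = 0` for the D2O volume fraction
#' making the water SLD vanish; also reports the corresponding mass
#' fraction (densities 1.107 and 0.997 g/cm^3).
#'
#' @param sld_d2o D2O scattering length density (1e-6 A^-2, positive).
#' @param sld_h2o H2O scattering length density (1e-6 A^-2, negative).
#' @return list with `volume_fraction` and `mass_fraction` of D2O.
#' @export
acmw_fraction <- function(sld_d2o = 6.36, sld_h2o = -0.56) {
  if (!(sld_d2o > 0) || !(sld_h2o < 0)) {
    stop("need sld_d2o > 0 > sld_h2o to contrast-match")
  }
  x <- -sld_h2o / (sld_d2o - sld_h2o)
  rho_d <- 1.107; rho_h <- 0.997
  w <- x * rho_d / (x * rho_d + (1 - x) * rho_h)
  list(volume_fraction = x, mass_fraction = w)
}

#' Read / write ORSO-style reflectivity ASCII files
#'
#' Plain-text `.ort`-compatible tables: `#` header lines preserved,
#' whitespace-separated columns `Qz R dR [dQz]`.
#'
#' @param path file path.
#' @param contrast label attached to the curve on read.
#' @export
read_ort <- function(path, contrast = NULL) {
  lines <- readLines(path)
  hdr <- grepl("^\\s*#", lines)
  body <- which(!hdr & nzchar(trimws(lines)))
  if (!length(body)) stop("no data rows in ", path)
  rows <- lapply(body, function(ln) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[ln]), "\\s+")[[1]]))
    if (length(v) < 3 || anyNA(v)) {
      stop(sprintf("malformed reflectivity data at %s line %d", path, ln))
    }
    v
  })
  ncol <- min(vapply(rows, length, 1L))
  mat <- do.call(rbind, lapply(rows, `[`, seq_len(ncol)))
  if (is.null(contrast)) {
    cl <- grep("contrast", lines[hdr], value = TRUE)
    contrast <- if (length(cl)) trimws(sub(".*contrast[:=]", "", cl[1])) else ""
  }
  reflectivity_curve(mat[, 1], mat[, 2], mat[, 3],
                     dq = if (ncol >= 4) mat[, 4] else NULL,
                     contrast = contrast)
}

#' @rdname read_ort
#' @param curve `reflectivity_curve`.
#' @param header extra `#` header lines.
#' @export
write_ort <- function(curve, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# ORSO-style reflectivity data",
               sprintf("# contrast: %s", curve$contrast),
               header,
               "# columns: Qz_1/A R dR dQz_1/A"), con)
  dq <- curve$dq %||% rep(0, length(curve$qz))
  utils::write.table(
    data.frame(format(curve$qz, digits = 10), format(curve$R, digits = 10),
               format(curve$dR, digits = 10), format(dq, digits = 10)),
    con, sep = "  ", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
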
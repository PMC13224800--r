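# Forward model and inversion of the complex amplitude ratio.
#
# Conventions (time factor e^{+i omega t}, angular displacement as phase
# reference): the frequency-domain equation of motion of the rotor+probe is
#
#   AR * theta0 = -I omega^2 theta0 + i omega (K_i + K_b) theta0
#
# so AR = -I omega^2 + i omega (K_i + K_b), where K_i and K_b are the drag
# torque coefficients per unit angular velocity from the flow solution.
# The interfacial moduli follow from G* = G' + i G'' = i omega eta_s* and
# Bo* = eta_s* / (eta a).  A purely elastic interface then produces torque
# in phase opposition to the displacement (AR real, sign opposite to
# -I omega^2 at small omega) and a purely viscous one in quadrature.

#' Interface state at a single frequency
#'
#' Bundles the equivalent descriptions of a linear viscoelastic interface:
#' storage and loss moduli `(G', G'')` in N/m, complex interfacial
#' viscosity `eta_s* = (G'' - i G') / omega`, and Boussinesq number
#' `Bo* = eta_s* / (eta a)`.
#'
#' @param omega angular frequency (rad/s).
#' @param G_storage storage modulus G' (N/m).
#' @param G_loss loss modulus G'' (N/m).
#' @param geom `dwr_geometry` (supplies the length scale `a`).
#' @param sub subphase `fluid_phase` (supplies `eta`).
#' @return object of class `interface_state`.
#' @export
interface_state <- function(omega, G_storage = 0, G_loss = 0,
                            geom = dwr_geometry(), sub = fluid_phase()) {
  stopifnot(omega > 0)
  Gstar <- complex(real = G_storage, imaginary = G_loss)
  eta_s <- Gstar / (1i * omega)
  Bo <- eta_s / (sub$eta * geom$a)
  structure(list(omega = omega, Bo = Bo, eta_s = eta_s,
                 G_storage = G_storage, G_loss = G_loss,
                 inertia_limited = NA),
            class = "interface_state")
}

#' @export
print.interface_state <- function(x, ...) {
  cat(sprintf("interface state @ f = %.4g Hz: G' = %.4g N/m, G'' = %.4g N/m, |Bo| = %.4g%s\n",
              x$omega / (2 * pi), x$G_storage, x$G_loss, Mod(x$Bo),
              if (isTRUE(x$inertia_limited)) "  [inertia limited]" else ""))
  invisible(x)
}

#' Forward-model the complex amplitude ratio
#'
#' Solves the flow field at the state's Boussinesq number and assembles
#' `AR = -I omega^2 + i omega (K_i + K_b)`.
#'
#' @param state `interface_state` (or anything with `omega` and `Bo`).
#' @param dyn `probe_dynamics`.
#' @param geom `dwr_geometry`.
#' @param sub,top fluid phases.
#' @param resolution mesh resolution (see [build_mesh()]).
#' @param mesh optional prebuilt mesh (overrides `resolution`).
#' @param include_fluid_inertia passed to [solve_field()].
#' @return complex amplitude ratio (N m / rad).
#' @export
ar_forward <- function(state, dyn, geom = dwr_geometry(), sub = fluid_phase(),
                       top = air_phase(), resolution = 24, mesh = NULL,
                       include_fluid_inertia = TRUE) {
  if (is.null(mesh)) mesh <- build_mesh(geom, resolution)
  K <- flow_drags(mesh, state$Bo, state$omega, sub, top, include_fluid_inertia)
  -dyn$I * state$omega^2 + 1i * state$omega * (K$K_i + K$K_b)
}

#' High-Boussinesq closed-form amplitude ratio
#'
#' In the regime where interfacial drag and rotor inertia dominate
#' (`|Bo|` of order 100 and above, bulk drag negligible) the amplitude
#' ratio reduces to `AR = -I omega^2 + g1 (G' + i G'')`, with modulus
#' `|AR| = sqrt((g1 G' - I omega^2)^2 + (g1 G'')^2)`.  `|AR|` therefore has
#' a resonance minimum in G' exactly at `G' = I omega^2 / g1`.
#'
#' @param state `interface_state`.
#' @param dyn `probe_dynamics`.
#' @return complex amplitude ratio (N m / rad).
#' @export
ar_highBo <- function(state, dyn) {
  -dyn$I * state$omega^2 +
    dyn$g1 * complex(real = state$G_storage, imaginary = state$G_loss)
}

#' Invert a measured amplitude ratio into interfacial moduli
#'
#' Flow-field-based inversion: starting from the high-Bo closed-form seed,
#' iterate the fixed point
#' `Bo_{k+1} = Bo_k (AR + I w^2 - i w K_b(Bo_k)) / (i w K_i(Bo_k))`
#' until the Boussinesq number is stationary.  The multiplicative update
#' exploits that `K_i` is asymptotically linear in `Bo` at frozen flow
#' field, making the map contractive over the operating window.
#'
#' @param meas list with at least `omega` (rad/s) and complex `AR`
#'   (N m/rad); optionally `sigma_AR` (modulus uncertainty) and `strain`.
#'   See [amplitude_ratio()].
#' @param dyn `probe_dynamics`.
#' @param geom,sub,top geometry and fluid phases.
#' @param resolution mesh resolution.
#' @param mesh optional prebuilt mesh.
#' @param tol relative convergence tolerance on Bo.
#' @param max_iter maximum fixed-point iterations.
#' @param include_fluid_inertia passed to the solver.
#' @return `interface_state` with recovered `Bo`, `eta_s`, `G_storage`,
#'   `G_loss`, the `inertia_limited` flag, iteration count `n_iter`, and
#'   first-order modulus uncertainties when `meas$sigma_AR` is present.
#' @export
invert_ar <- function(meas, dyn, geom = dwr_geometry(), sub = fluid_phase(),
                      top = air_phase(), resolution = 24, mesh = NULL,
                      tol = 1e-6, max_iter = 100,
                      include_fluid_inertia = TRUE) {
  stopifnot(meas$omega > 0)
  omega <- meas$omega
  AR <- meas$AR
  if (is.null(mesh)) mesh <- build_mesh(geom, resolution)

  # seed from the analytic high-Bo inversion
  Gstar0 <- (AR + dyn$I * omega^2) / dyn$g1
  Bo0 <- Gstar0 / (1i * omega * sub$eta * geom$a)
  if (!is.finite(Bo0) || Mod(Bo0) < 1e-6) Bo0 <- 1 + 0i

  Bo <- Bo0
  trace <- complex(0)
  converged <- FALSE
  K <- NULL
  for (k in seq_len(max_iter)) {
    K <- flow_drags(mesh, Bo, omega, sub, top, include_fluid_inertia)
    if (Mod(K$K_i) == 0) {                # can only happen at Bo = 0
      Bo_new <- 0+0i
    } else {
      Bo_new <- Bo * (AR + dyn$I * omega^2 - 1i * omega * K$K_b) /
        (1i * omega * K$K_i)
    }
    trace <- c(trace, Bo_new)
    if (Mod(Bo_new - Bo) <= tol * Mod(Bo) || Mod(Bo_new) < 1e-6) {
      Bo <- Bo_new
      converged <- TRUE
      break
    }
    Bo <- Bo_new
  }
  if (!converged) {
    err <- simpleError(sprintf(
      "FFBDA fixed point did not converge in %d iterations (last |Bo| = %.3g)",
      max_iter, Mod(Bo)))
    attr(err, "trace") <- trace
    stop(err)
  }

  eta_s <- Bo * sub$eta * geom$a
  Gstar <- 1i * omega * eta_s
  Glim <- inertia_limit(dyn$I, omega, dyn$g1)
  st <- interface_state(omega, Re(Gstar), Im(Gstar), geom, sub)
  st$inertia_limited <- Mod(Gstar) < Glim
  st$n_iter <- k
  noise_floor <- if (!is.null(meas$sigma_AR)) 3 * Mod(meas$sigma_AR) / dyn$g1 else Glim
  st$unphysical <- Im(Gstar) < 0 && abs(Im(Gstar)) > noise_floor
  if (isTRUE(st$unphysical)) {
    warning("recovered loss modulus is negative beyond the noise level")
  }
  if (!is.null(meas$sigma_AR) && !is.null(K)) {
    # first-order: dG*/dAR = G* / (i omega K_i)
    scale <- if (Mod(K$K_i) > 0) Mod(Gstar) / (omega * Mod(K$K_i)) else 1 / dyn$g1
    st$sigma_G_storage <- Mod(meas$sigma_AR) * scale
    st$sigma_G_loss <- Mod(meas$sigma_AR) * scale
  }
  st
}

#' Calibrate the rotor+probe inertia from a clean-interface sweep
#'
#' For a clean interface (`Bo = 0`) the model is
#' `AR(omega) = -I omega^2 + i omega K_b(omega)`; given measured amplitude
#' ratios at three or more frequencies this least-squares fits `I` and
#' reports residual diagnostics.  Interfacial contamination (nonzero Bo)
#' biases `I` upward and shows up as large structured residuals.
#'
#' @param clean_sweep list of measurements, each with `omega` and `AR`.
#' @param geom,sub,top geometry and phases.
#' @param resolution mesh resolution.
#' @return list with `I`, per-frequency complex `residuals`, and
#'   `rel_residual` (residual norm relative to the inertial signal).
#' @export
calibrate_inertia <- function(clean_sweep, geom = dwr_geometry(),
                              sub = fluid_phase(), top = air_phase(),
                              resolution = 24) {
  if (length(clean_sweep) < 3) stop("need at least 3 frequencies to calibrate inertia")
  omegas <- vapply(clean_sweep, function(m) m$omega, numeric(1))
  if (max(omegas) / min(omegas) < 1.5) {
    stop("frequency range too narrow for a well-conditioned inertia fit")
  }
  mesh <- build_mesh(geom, resolution)
  ARs <- vapply(clean_sweep, function(m) m$AR, complex(1))
  Kb <- vapply(omegas, function(w) {
    flow_drags(mesh, 0+0i, w, sub, top)$K_b
  }, complex(1))
  cc <- ARs - 1i * omegas * Kb               # should equal -I omega^2
  I_hat <- -sum(omegas^2 * Re(cc)) / sum(omegas^4)
  resid <- cc + I_hat * omegas^2
  list(I = I_hat, residuals = resid,
       rel_residual = sqrt(sum(Mod(resid)^2) / sum((I_hat * omegas^2)^2)))
}
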
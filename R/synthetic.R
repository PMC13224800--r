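# Forward simulation of the instrument: second-order rotor dynamics
# (inertia + interfacial + bulk drag), channel gains, Gaussian noise and
# 16-bit quantization.  Every downstream stage of the analysis chain can be
# exercised against known ground truth without an instrument.

#' Specification of a simulated oscillatory measurement run
#'
#' @param G_storage,G_loss interfacial moduli (N/m); scalars or vectors
#'   matched to `f_list`.
#' @param f_list oscillation frequencies (Hz), one waveform per entry.
#' @param strain_target average interfacial strain per waveform (sets the
#'   angular amplitude through [average_strain()]).
#' @param n_periods periods per waveform (>= 4).
#' @param fs sampling rate (Hz); must exceed `10 * max(f_list)`.
#' @param noise_sd per-channel Gaussian noise s.d. in volts, list with
#'   `theta`, `torque_lo`, `torque_hi`; alternatively give `snr` to set
#'   each channel's noise to (signal amplitude)/snr.
#' @param snr amplitude signal-to-noise ratio applied per channel when
#'   `noise_sd` is `NULL`; `Inf` for noiseless.
#' @param seed RNG seed recorded in all outputs.
#' @param geom,dyn,sub,top instrument configuration.
#' @param gains,adc_bits,v_range DAQ calibration (see [raw_record()]).
#' @param resolution flow-solver mesh resolution used for the forward AR.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(G_storage = 0, G_loss = 5e-4,
                            f_list = c(0.3, 0.5, 1, 3),
                            strain_target = 0.03, n_periods = 16,
                            fs = 500, noise_sd = NULL, snr = Inf, seed = 1,
                            geom = dwr_geometry(), dyn = probe_dynamics(geom = geom),
                            sub = fluid_phase(), top = air_phase(),
                            gains = list(theta = 600, torque_lo = 1e4, torque_hi = 1e6),
                            adc_bits = 16, v_range = 10, resolution = 24) {
  stopifnot(fs > 10 * max(f_list), n_periods >= 4)
  structure(
    list(G_storage = rep_len(G_storage, length(f_list)),
         G_loss = rep_len(G_loss, length(f_list)),
         f_list = f_list, strain_target = strain_target,
         n_periods = n_periods, fs = fs, noise_sd = noise_sd, snr = snr,
         seed = seed, geom = geom, dyn = dyn, sub = sub, top = top,
         gains = gains, adc_bits = adc_bits, v_range = v_range,
         resolution = resolution),
    class = "simulation_spec"
  )
}

#' Noiseless amplitude-ratio sweep with ground truth attached
#'
#' Evaluates the forward model [ar_forward()] at each frequency of the
#' spec; the returned objects carry the generating `interface_state` as
#' `$truth`.
#'
#' @param spec `simulation_spec`.
#' @return list of `amplitude_ratio`-like lists (`omega`, `f`, `AR`,
#'   `strain`, `truth`).
#' @export
simulate_ar_sweep <- function(spec) {
  mesh <- build_mesh(spec$geom, spec$resolution)
  lapply(seq_along(spec$f_list), function(k) {
    f <- spec$f_list[k]
    st <- interface_state(2 * pi * f, spec$G_storage[k], spec$G_loss[k],
                          spec$geom, spec$sub)
    AR <- ar_forward(st, spec$dyn, spec$geom, spec$sub, spec$top, mesh = mesh)
    structure(list(omega = 2 * pi * f, f = f, AR = AR,
                   strain = spec$strain_target, truth = st),
              class = "amplitude_ratio")
  })
}

#' Simulate a raw multi-channel DAQ record
#'
#' For each frequency, synthesizes the steady-state response of the
#' second-order rotor model: `theta(t) = theta0 cos(w t)` and
#' `T(t) = |AR| theta0 cos(w t + arg AR)`, with `theta0` chosen so the
#' average interfacial strain equals the target.  Channels are scaled by
#' their gains, Gaussian noise is added, all channels are quantized to the
#' ADC resolution, and a trigger edge marks each waveform start.
#' Reproducible: the record is a deterministic function of the spec
#' (including its `seed`).
#'
#' @param spec `simulation_spec`.
#' @return list: `record` (a [raw_record()]) and `truth` (data frame of
#'   per-waveform ground truth: f, G', G'', theta0, complex AR).
#' @export
simulate_record <- function(spec) {
  sweep <- simulate_ar_sweep(spec)
  theta0 <- spec$strain_target / average_strain(1, spec$geom)
  set.seed(spec$seed)
  lsb <- 2 * spec$v_range / 2^spec$adc_bits
  quantize <- function(v) lsb * round(v / lsb)

  t_all <- v_th <- v_lo <- v_hi <- v_tr <- numeric(0)
  t0 <- 0
  for (k in seq_along(sweep)) {
    f <- sweep[[k]]$f
    AR <- sweep[[k]]$AR
    n <- round(spec$n_periods * spec$fs / f)
    tt <- (seq_len(n) - 1L) / spec$fs
    w <- 2 * pi * f
    theta <- theta0 * cos(w * tt)
    torque <- Mod(AR) * theta0 * cos(w * tt + Arg(AR))
    ch <- list(th = spec$gains$theta * theta,
               lo = spec$gains$torque_lo * torque,
               hi = spec$gains$torque_hi * torque)
    over <- vapply(ch, function(v) max(abs(v)) > spec$v_range, logical(1))
    # the high-gain torque channel is allowed to rail (that is what the
    # dual-gain scheme is for), every other channel must stay in range
    if (over[["th"]] || over[["lo"]]) {
      stop("channel overrange after gain; lower the gain or the strain target")
    }
    sd_of <- function(name, amp) {
      if (!is.null(spec$noise_sd)) spec$noise_sd[[name]]
      else if (is.finite(spec$snr)) amp / spec$snr else 0
    }
    add_noise <- function(v, sd) if (sd > 0) v + stats::rnorm(length(v), 0, sd) else v
    vth <- add_noise(ch$th, sd_of("theta", spec$gains$theta * theta0))
    vlo <- add_noise(ch$lo, sd_of("torque_lo", spec$gains$torque_lo * Mod(AR) * theta0))
    vhi <- add_noise(ch$hi, sd_of("torque_hi", min(spec$v_range,
                                                   spec$gains$torque_hi * Mod(AR) * theta0)))
    clip <- function(v) pmin(pmax(v, -spec$v_range), spec$v_range)
    trig <- numeric(n)
    trig[seq_len(max(1L, n %/% 10))] <- 5
    t_all <- c(t_all, t0 + tt)
    v_th <- c(v_th, quantize(clip(vth)))
    v_lo <- c(v_lo, quantize(clip(vlo)))
    v_hi <- c(v_hi, quantize(clip(vhi)))
    v_tr <- c(v_tr, trig)
    t0 <- t0 + n / spec$fs
  }
  truth <- data.frame(
    f = spec$f_list, G_storage = spec$G_storage, G_loss = spec$G_loss,
    theta0 = theta0, strain = spec$strain_target,
    Re_AR = vapply(sweep, function(s) Re(s$AR), numeric(1)),
    Im_AR = vapply(sweep, function(s) Im(s$AR), numeric(1)),
    seed = spec$seed
  )
  list(record = raw_record(t_all, v_th, v_lo, v_hi, v_tr, fs = spec$fs,
                           gains = spec$gains, adc_bits = spec$adc_bits,
                           v_range = spec$v_range),
       truth = truth)
}

#' Resonance curve of the high-Bo closed form
#'
#' `|AR|(G') = sqrt((g1 G' - I w^2)^2 + (g1 G'')^2)` at fixed loss modulus:
#' the modulus of the amplitude ratio has its minimum exactly at
#' `G' = I w^2 / g1`, where the interfacial elasticity cancels the rotor
#' inertia.
#'
#' @param dyn `probe_dynamics` (supplies `I` and `g1`).
#' @param omega angular frequency (rad/s).
#' @param Gpp fixed loss modulus G'' (N/m).
#' @param Gp_grid storage-modulus grid; default spans the minimum.
#' @return list: `table` (data.frame G_prime, mod_AR), `G_min` (analytic
#'   minimizer `I w^2 / g1`), `min_depth` (`g1 G''`, the value of |AR| at
#'   the minimum).
#' @export
resonance_curve <- function(dyn, omega, Gpp, Gp_grid = NULL) {
  stopifnot(omega > 0)
  G_min <- dyn$I * omega^2 / dyn$g1
  if (is.null(Gp_grid)) Gp_grid <- seq(0, 2 * G_min, length.out = 201)
  modAR <- sqrt((dyn$g1 * Gp_grid - dyn$I * omega^2)^2 + (dyn$g1 * Gpp)^2)
  list(table = data.frame(G_prime = Gp_grid, mod_AR = modAR),
       G_min = G_min, min_depth = dyn$g1 * Gpp)
}
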
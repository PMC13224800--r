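# Digitization of raw oscillatory rheometry records: trigger splitting,
# integer-period selection, single-bin discrete Fourier transforms, and
# spectral uncertainty estimation.

#' Raw multi-channel DAQ record
#'
#' Four simultaneously sampled analogue channels: angular displacement,
#' two torque channels read through amplifiers of different gain (so that
#' torques across several orders of magnitude stay within the ADC range),
#' and a trigger marking the start of each measurement waveform.
#'
#' @param t sample times (s), uniform step `1/fs`.
#' @param v_theta angle channel (V).
#' @param v_torque_lo,v_torque_hi torque channels (V).
#' @param v_trigger trigger channel (V).
#' @param fs sampling rate (Hz).
#' @param gains list with `theta` (V/rad), `torque_lo`, `torque_hi`
#'   (V/(N m)).
#' @param adc_bits ADC resolution (bits).
#' @param v_range ADC full scale, i.e. inputs span `[-v_range, v_range]` (V).
#' @return object of class `raw_record`.
#' @export
raw_record <- function(t, v_theta, v_torque_lo, v_torque_hi, v_trigger, fs,
                       gains = list(theta = 600, torque_lo = 1e4, torque_hi = 1e6),
                       adc_bits = 16, v_range = 10) {
  n <- length(t)
  stopifnot(length(v_theta) == n, length(v_torque_lo) == n,
            length(v_torque_hi) == n, length(v_trigger) == n, fs > 0)
  if (n > 1) {
    dt <- diff(t)
    if (any(abs(dt - 1 / fs) > 1e-6 / fs)) {
      stop("sample times must be uniform with step 1/fs")
    }
  }
  structure(
    list(t = t, v_theta = v_theta, v_torque_lo = v_torque_lo,
         v_torque_hi = v_torque_hi, v_trigger = v_trigger, fs = fs,
         gains = gains, adc_bits = adc_bits, v_range = v_range),
    class = "raw_record"
  )
}

#' Split a raw record into per-measurement waveform segments
#'
#' One segment per rising edge of the trigger channel, each ending at the
#' next rising edge or at the end of the record.
#'
#' @param rec `raw_record`.
#' @param threshold trigger threshold (V).
#' @return list of segments; each a list with the channel slices, `fs`,
#'   `gains`, `v_range` and the segment `start_time`.
#' @export
split_by_trigger <- function(rec, threshold = 2.5) {
  v <- rec$v_trigger
  edges <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  if (v[1] >= threshold) edges <- c(1L, edges)
  if (!length(edges)) stop("no trigger edges found above threshold")
  ends <- c(edges[-1] - 1L, length(v))
  lapply(seq_along(edges), function(k) {
    sel <- edges[k]:ends[k]
    list(t = rec$t[sel], v_theta = rec$v_theta[sel],
         v_torque_lo = rec$v_torque_lo[sel],
         v_torque_hi = rec$v_torque_hi[sel],
         fs = rec$fs, gains = rec$gains, v_range = rec$v_range,
         start_time = rec$t[edges[k]])
  })
}

#' Select an integer number of periods from a waveform segment
#'
#' Discards the leading `discard_fraction` of the segment (which may
#' contain the start-up transient) and keeps the longest suffix spanning a
#' whole number of periods of frequency `f`.
#'
#' @param seg a segment from [split_by_trigger()] (or any list of equal
#'   length channel vectors plus `fs`).
#' @param f oscillation frequency (Hz).
#' @param discard_fraction fraction of the segment to drop from the front.
#' @return the trimmed segment, with `n_periods` and `f` recorded.
#' @export
select_periods <- function(seg, f, discard_fraction = 0.2) {
  stopifnot(f > 0, discard_fraction >= 0, discard_fraction < 1)
  n <- length(seg$t)
  spp <- seg$fs / f                       # samples per period
  avail <- floor(n * (1 - discard_fraction))
  if (avail + 0.5 < spp) {
    stop("segment shorter than one period after transient discard")
  }
  n_per <- max(1, floor(avail / spp + 1e-9))
  keep <- min(n, round(n_per * spp))
  sel <- (n - keep + 1L):n
  out <- seg
  for (ch in intersect(names(seg), c("t", "v_theta", "v_torque_lo", "v_torque_hi"))) {
    out[[ch]] <- seg[[ch]][sel]
  }
  out$n_periods <- as.integer(n_per)
  out$f <- f
  out
}

#' Amplitude and phase of the fundamental by single-bin DFT
#'
#' For a segment holding an integer number of periods, the DFT bin at the
#' oscillation frequency gives amplitude and phase exactly (to machine
#' precision for a pure sinusoid).  The convention is
#' `x(t) = A cos(2 pi f t + phase)` with `t = 0` at the first retained
#' sample.
#'
#' @param seg trimmed segment from [select_periods()].
#' @param channel which channel to transform.
#' @param f frequency (Hz); defaults to the segment's.
#' @param gain volts per physical unit; the returned amplitude is
#'   volts/gain (rad or N m).
#' @return object of class `harmonic_component`: `f`, `amplitude`, `phase`
#'   (in `(-pi, pi]`), `n_periods`, raw peak voltage `raw_peak`, and the
#'   complex spectrum metadata needed for [estimate_uncertainty()].
#' @export
dft_fundamental <- function(seg, channel = "v_theta", f = seg$f, gain = 1) {
  x <- seg[[channel]]
  N <- length(x)
  n_per <- seg$n_periods %||% round(N * f / seg$fs)
  if (seg$fs / f < 4) stop("fewer than 4 samples per period; frequency not resolvable")
  X <- stats::fft(x)
  k <- n_per + 1L                          # bin of the fundamental
  amp <- 2 * Mod(X[k]) / N
  ph <- wrap_phase(Arg(X[k]))
  # higher harmonics kept for diagnostics (unused by the inversion)
  hk <- n_per * (2:4) + 1L
  hk <- hk[hk <= N %/% 2]
  harmonics <- data.frame(order = (hk - 1L) / n_per,
                          amplitude = 2 * Mod(X[hk]) / (N * gain),
                          phase = wrap_phase(Arg(X[hk])))
  structure(
    list(f = f, amplitude = amp / gain, phase = ph, n_periods = as.integer(n_per),
         gain = gain, N = N, raw_peak = max(abs(x)), spectrum_bin = X[k],
         harmonics = harmonics, channel = channel),
    class = "harmonic_component"
  )
}

#' Merge the dual-gain torque channels
#'
#' Uses the high-gain channel unless its raw signal approaches the ADC
#' limit (saturation), in which case the low-gain channel is used.
#'
#' @param lo,hi `harmonic_component`s of the same fundamental from the
#'   low- and high-gain torque channels (already scaled to N m via their
#'   gains).
#' @param lo_raw_peak,hi_raw_peak raw channel peaks (V); default from the
#'   components.
#' @param v_range ADC full scale (V).
#' @param saturation_fraction fraction of `v_range` above which a channel
#'   is considered saturated.
#' @return the selected `harmonic_component` with a `source` field
#'   (`"hi"` or `"lo"`).
#' @export
merge_dual_gain <- function(lo, hi, lo_raw_peak = lo$raw_peak,
                            hi_raw_peak = hi$raw_peak, v_range = 10,
                            saturation_fraction = 0.95) {
  stopifnot(abs(lo$f - hi$f) <= 1e-9 * hi$f)
  hi_sat <- hi_raw_peak > saturation_fraction * v_range
  lo_sat <- lo_raw_peak > saturation_fraction * v_range
  if (hi_sat && lo_sat) stop("both torque channels saturated")
  out <- if (hi_sat) lo else hi
  out$source <- if (hi_sat) "lo" else "hi"
  out
}

#' Complex amplitude ratio from torque and angle harmonics
#'
#' `AR = (T0 / theta0) exp(i (phi_T - phi_theta))`; the common time origin
#' of the two channels cancels in the phase difference.
#'
#' @param torque `harmonic_component` in N m.
#' @param angle `harmonic_component` in rad.
#' @param sigma_torque,sigma_angle optional `(sigma_amplitude, sigma_phase)`
#'   pairs from [estimate_uncertainty()] for first-order propagation.
#' @return list of class `amplitude_ratio`: `omega`, complex `AR`,
#'   `sigma_AR` (modulus uncertainty), `sigma_phase`, and the inputs.
#' @export
amplitude_ratio <- function(torque, angle, sigma_torque = NULL, sigma_angle = NULL) {
  stopifnot(abs(torque$f - angle$f) <= 1e-9 * angle$f)
  if (angle$amplitude == 0) stop("zero angular amplitude")
  modAR <- torque$amplitude / angle$amplitude
  phase <- wrap_phase(torque$phase - angle$phase)
  sigma_AR <- sigma_phase <- NULL
  if (!is.null(sigma_torque) && !is.null(sigma_angle)) {
    sigma_AR <- modAR * sqrt((sigma_torque[1] / torque$amplitude)^2 +
                             (sigma_angle[1] / angle$amplitude)^2)
    sigma_phase <- sqrt(sigma_torque[2]^2 + sigma_angle[2]^2)
  }
  structure(
    list(omega = 2 * pi * torque$f, f = torque$f,
         AR = complex(modulus = modAR, argument = phase),
         sigma_AR = sigma_AR, sigma_phase = sigma_phase,
         T0 = torque$amplitude, theta0 = angle$amplitude),
    class = "amplitude_ratio"
  )
}

#' Spectral uncertainty of a harmonic component
#'
#' Estimates the channel noise power spectral density from the DFT bins
#' excluding DC, the fundamental and its first three harmonics, and
#' propagates it to the amplitude and phase of the fundamental:
#' `sigma_amplitude = sqrt(2 P_noise / N)` (same units as the amplitude)
#' and `sigma_phase = sigma_amplitude / amplitude`.
#'
#' @param seg the trimmed segment the component was computed from.
#' @param comp `harmonic_component` from [dft_fundamental()].
#' @return numeric vector `c(sigma_amplitude, sigma_phase)`, with
#'   attribute `below_noise_floor` flagging amplitudes within 3 sigma of
#'   the noise.
#' @export
estimate_uncertainty <- function(seg, comp) {
  x <- seg[[comp$channel]]
  N <- length(x)
  X <- stats::fft(x)
  k0 <- comp$n_periods
  excl <- c(0L, k0 * (1:4))                       # DC, fundamental, 3 harmonics
  excl <- unique(c(excl, N - excl[excl > 0]))     # and their mirror bins
  bins <- setdiff(seq_len(N) - 1L, excl)
  P_noise <- mean(Mod(X[bins + 1L])^2) / N        # per-sample noise variance est.
  sigma_amp <- sqrt(2 * P_noise / N) / comp$gain
  sigma_phase <- if (comp$amplitude > 0) sigma_amp / comp$amplitude else Inf
  out <- c(sigma_amplitude = sigma_amp, sigma_phase = sigma_phase)
  attr(out, "below_noise_floor") <- comp$amplitude < 3 * sigma_amp
  out
}

#' Process a raw record into per-segment amplitude ratios
#'
#' Full digitization chain: trigger split, transient discard and
#' integer-period selection, single-bin DFTs of angle and both torque
#' channels, dual-gain merge, amplitude ratio with propagated
#' uncertainties.
#'
#' @param rec `raw_record`.
#' @param f_list oscillation frequency of each segment (Hz); recycled or,
#'   if `NULL`, auto-detected from the dominant spectral bin per segment.
#' @param discard_fraction transient fraction dropped per segment.
#' @param threshold trigger threshold (V).
#' @return list of `amplitude_ratio` objects.
#' @export
process_record <- function(rec, f_list = NULL, discard_fraction = 0.2,
                           threshold = 2.5) {
  segs <- split_by_trigger(rec, threshold)
  if (!is.null(f_list)) f_list <- rep_len(f_list, length(segs))
  lapply(seq_along(segs), function(k) {
    seg <- segs[[k]]
    f <- if (is.null(f_list)) detect_frequency(seg) else f_list[k]
    seg <- select_periods(seg, f, discard_fraction)
    ang <- dft_fundamental(seg, "v_theta", gain = rec$gains$theta)
    tlo <- dft_fundamental(seg, "v_torque_lo", gain = rec$gains$torque_lo)
    thi <- dft_fundamental(seg, "v_torque_hi", gain = rec$gains$torque_hi)
    trq <- merge_dual_gain(tlo, thi, v_range = rec$v_range)
    s_ang <- estimate_uncertainty(seg, ang)
    s_trq <- estimate_uncertainty(seg, trq)
    amplitude_ratio(trq, ang, s_trq, s_ang)
  })
}

#' Dominant oscillation frequency of a segment (spectral peak)
#' @param seg waveform segment (uses the angle channel).
#' @return frequency (Hz).
#' @export
detect_frequency <- function(seg) {
  x <- seg$v_theta - mean(seg$v_theta)
  N <- length(x)
  X <- Mod(stats::fft(x))[2:(N %/% 2)]
  (which.max(X)) * seg$fs / N
}

#' Read / write raw records as delimited text
#'
#' Files are tab- or comma-separated tables with a `#`-comment header and
#' columns `t, v_theta, v_torque_lo, v_torque_hi, v_trigger`.
#'
#' @param rec `raw_record`.
#' @param path file path.
#' @param gains,adc_bits,v_range calibration used when reading.
#' @export
write_raw_record <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dwrnr raw record  fs=%.10g  gains=%s  adc_bits=%d  v_range=%.10g",
                     rec$fs,
                     paste(sprintf("%s:%.10g", names(rec$gains), unlist(rec$gains)),
                           collapse = ","),
                     rec$adc_bits, rec$v_range), con)
  utils::write.table(
    data.frame(t = rec$t, v_theta = rec$v_theta, v_torque_lo = rec$v_torque_lo,
               v_torque_hi = rec$v_torque_hi, v_trigger = rec$v_trigger),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raw_record
#' @export
read_raw_record <- function(path, gains = NULL, adc_bits = 16, v_range = 10) {
  first <- readLines(path, n = 1L)
  fs <- NA_real_
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("fs=([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 2) fs <- as.numeric(m[2])
    if (is.null(gains)) {
      gm <- regmatches(first, regexec("gains=([^ ]+)", first))[[1]]
      if (length(gm) == 2) {
        kv <- strsplit(strsplit(gm[2], ",")[[1]], ":")
        gains <- stats::setNames(lapply(kv, function(p) as.numeric(p[2])),
                                 vapply(kv, `[`, "", 1))
      }
    }
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  need <- c("t", "v_theta", "v_torque_lo", "v_torque_hi", "v_trigger")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("raw record missing columns: ", paste(miss, collapse = ", "))
  if (is.na(fs)) fs <- 1 / stats::median(diff(df$t))
  if (is.null(gains)) gains <- list(theta = 600, torque_lo = 1e4, torque_hi = 1e6)
  raw_record(df$t, df$v_theta, df$v_torque_lo, df$v_torque_hi, df$v_trigger,
             fs = fs, gains = gains, adc_bits = adc_bits, v_range = v_range)
}
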
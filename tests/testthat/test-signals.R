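# Synthetic segments for the digitization chain
make_segment <- function(f = 0.5, fs = 500, periods = 8, A = 1, phase = 0.3,
                         noise = 0, seed = 1) {
  set.seed(seed)
  n <- round(periods * fs / f)
  tt <- (seq_len(n) - 1L) / fs
  x <- A * cos(2 * pi * f * tt + phase) + rnorm(n, 0, noise)
  list(t = tt, v_theta = x, v_torque_lo = x, v_torque_hi = x, fs = fs,
       n_periods = as.integer(periods), f = f)
}

test_that("trigger splitting finds every rising edge within one sample", {
  fs <- 100
  n <- 1000
  edges_at <- c(1, 201, 401, 601, 801)
  trig <- numeric(n)
  for (e in edges_at) trig[e:(e + 20)] <- 5
  rec <- raw_record(t = (0:(n - 1)) / fs, v_theta = numeric(n),
                    v_torque_lo = numeric(n), v_torque_hi = numeric(n),
                    v_trigger = trig, fs = fs)
  segs <- split_by_trigger(rec)
  expect_length(segs, 5)
  starts <- vapply(segs, function(s) s$t[1], numeric(1))
  expect_equal(starts, (edges_at - 1) / fs, tolerance = 1e-12)
  rec$v_trigger <- numeric(n)
  expect_error(split_by_trigger(rec), "no trigger edges")
})

test_that("integer-period selection discards transients and keeps whole periods", {
  seg <- make_segment(f = 1, fs = 100, periods = 10.6)
  out <- select_periods(seg, f = 1, discard_fraction = 0.2)
  expect_identical(out$n_periods, 8L)
  expect_equal(length(out$t), 800)
  # exactly one period with no discard is unchanged
  seg1 <- make_segment(f = 1, fs = 100, periods = 1)
  out1 <- select_periods(seg1, f = 1, discard_fraction = 0)
  expect_identical(out1$n_periods, 1L)
  expect_equal(out1$v_theta, seg1$v_theta)
  # half a period cannot be used
  expect_error(select_periods(make_segment(f = 1, fs = 100, periods = 0.5), 1),
               "shorter than one period")
})

test_that("single-bin DFT is exact for a pure sinusoid and phase-shift invariant", {
  for (ph in c(-2.5, 0, 0.3, 3.0)) {
    seg <- make_segment(A = 0.7, phase = ph)
    comp <- dft_fundamental(seg, gain = 1)
    expect_equal(comp$amplitude, 0.7, tolerance = 1e-12)
    expect_equal(comp$phase, ph, tolerance = 1e-10)
  }
  # amplitude invariant under phase shift
  a1 <- dft_fundamental(make_segment(phase = 0.1))$amplitude
  a2 <- dft_fundamental(make_segment(phase = 2.9))$amplitude
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_error(dft_fundamental(make_segment(f = 200, fs = 500)), "4 samples")
})

test_that("DFT amplitude error stays within the white-noise bound (Monte Carlo)", {
  N <- 4096
  fs <- N / 8
  f <- 1
  sd <- 0.1
  n_mc <- 1000
  tt <- (0:(N - 1)) / fs
  carrier <- cos(2 * pi * f * tt)
  e <- exp(-2i * pi * (0:(N - 1)) * 8 / N)    # 8 periods -> bin 8
  set.seed(99)
  noise <- matrix(rnorm(N * n_mc, 0, sd), n_mc, N, byrow = TRUE)
  X <- (noise %*% e) + sum(carrier * e)
  amps <- 2 * Mod(X) / N
  bound <- 3 * sd * sqrt(2 / N)
  expect_gt(mean(abs(amps - 1) < bound), 0.985)
})

test_that("dual-gain merge prefers the high-gain channel until it saturates", {
  lo <- dft_fundamental(make_segment(A = 0.002), gain = 1e4)
  hi <- dft_fundamental(make_segment(A = 0.2), gain = 1e6)
  m1 <- merge_dual_gain(lo, hi, v_range = 10)
  expect_identical(m1$source, "hi")
  # consistent channels agree on the merged (physical) amplitude
  expect_equal(m1$amplitude, lo$amplitude, tolerance = 1e-9)
  hi_sat <- dft_fundamental(make_segment(A = 9.9), gain = 1e6)
  m2 <- merge_dual_gain(lo, hi_sat, v_range = 10)
  expect_identical(m2$source, "lo")
  lo_sat <- dft_fundamental(make_segment(A = 9.9), gain = 1e4)
  expect_error(merge_dual_gain(lo_sat, hi_sat, v_range = 10), "both torque channels")
})

test_that("amplitude ratio arithmetic and time-shift invariance", {
  trq <- list(f = 0.5, amplitude = 2, phase = pi)
  ang <- list(f = 0.5, amplitude = 1, phase = 0)
  ar <- amplitude_ratio(trq, ang)
  expect_equal(ar$AR, -2 + 0i, tolerance = 1e-12)
  same <- amplitude_ratio(list(f = 0.5, amplitude = 1, phase = 0.7),
                          list(f = 0.5, amplitude = 1, phase = 0.7))
  expect_equal(same$AR, 1 + 0i, tolerance = 1e-12)
  # a common time shift of both channels cancels in the ratio
  shift <- 1.234
  ar2 <- amplitude_ratio(list(f = 0.5, amplitude = 2, phase = pi + shift),
                         list(f = 0.5, amplitude = 1, phase = 0 + shift))
  expect_equal(ar2$AR, ar$AR, tolerance = 1e-12)
  expect_error(amplitude_ratio(trq, list(f = 0.5, amplitude = 0, phase = 0)),
               "zero angular amplitude")
})

test_that("spectral uncertainty tracks the Monte-Carlo spread", {
  f <- 1; fs <- 512; periods <- 8
  sd <- 0.05
  n_mc <- 300
  set.seed(7)
  amps <- numeric(n_mc)
  sig_pred <- numeric(n_mc)
  for (k in seq_len(n_mc)) {
    seg <- make_segment(f = f, fs = fs, periods = periods, A = 1, noise = sd,
                        seed = 1000 + k)
    comp <- dft_fundamental(seg)
    amps[k] <- comp$amplitude
    sig_pred[k] <- estimate_uncertainty(seg, comp)[1]
  }
  expect_equal(mean(sig_pred), sd(amps), tolerance = 0.2 * sd(amps) / mean(sig_pred))
  expect_lt(abs(mean(sig_pred) / sd(amps) - 1), 0.25)
  # noiseless signal: sigma at numerical floor; phase error diverges with 1/amplitude
  seg0 <- make_segment(noise = 0)
  c0 <- dft_fundamental(seg0)
  s0 <- estimate_uncertainty(seg0, c0)
  expect_lt(s0[1], 1e-12)
  # sigma_phase ~ sigma_amplitude / amplitude: shrinking the signal 100x
  # inflates the phase uncertainty ~100x at fixed noise
  big <- make_segment(A = 1, noise = 0.1, seed = 5)
  small <- make_segment(A = 0.01, noise = 0.1, seed = 5)
  sp_big <- estimate_uncertainty(big, dft_fundamental(big))[2]
  sp_small <- estimate_uncertainty(small, dft_fundamental(small))[2]
  ratio <- unname(sp_small / sp_big)
  expect_gt(ratio, 50)
  expect_lt(ratio, 200)
  tiny <- make_segment(A = 1e-9, noise = 0.1)
  st <- estimate_uncertainty(tiny, dft_fundamental(tiny))
  expect_true(attr(st, "below_noise_floor"))
})
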
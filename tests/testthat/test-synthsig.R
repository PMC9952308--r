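# Chest-wall displacement generator and contact-sensor channels.

test_that("zero amplitudes give a constant-zero trace with empty labels", {
  tr <- simulate_displacement(quiet_params(), 5)
  expect_equal(tr$samples, rep(0, 5000))
  expect_equal(n_cycles(tr$labels), 0L)
})

test_that("60 bpm over 60 s yields exactly 60 labeled cycles", {
  p <- cardiac_sim_params(heart_rate = 60)
  tr <- simulate_displacement(p, 60)
  expect_equal(n_cycles(tr$labels), 60L)
})

test_that("S1 burst peak equals the requested amplitude at each onset", {
  p <- cardiac_sim_params(resp_amp = 0, beat_amp = 0, s2_amp = 0,
                          s1_amp = 5e-6, damping = 1, cycle_jitter_sd = 0)
  tr <- simulate_displacement(p, 10, rate = 4000) # fine grid for the peak
  expect_rel_error(max(abs(tr$samples)), 5e-6, 1e-3)
  # the peak sits shortly after each s1_delay (envelope maximum of the
  # damped sinusoid at atan(w/d)/w after onset)
  w <- 2 * pi * p$s1_freq
  tstar <- atan(w / p$burst_decay) / w
  i_peak <- which.max(abs(tr$samples[1:2000]))
  expect_lt(abs((i_peak - 1) / 4000 - (p$s1_delay + tstar)), 2e-3)
})

test_that("identical parameters and seed give bit-identical traces", {
  p <- cardiac_sim_params(seed = 42L)
  tr1 <- simulate_displacement(p, 8)
  tr2 <- simulate_displacement(p, 8)
  expect_identical(tr1$samples, tr2$samples)
  expect_identical(tr1$labels$cycles, tr2$labels$cycles)
  p2 <- cardiac_sim_params(seed = 43L)
  expect_false(identical(simulate_displacement(p2, 8)$samples, tr1$samples))
})

test_that("displacement is additive in its three components", {
  mk <- function(...) simulate_displacement(
    cardiac_sim_params(seed = 7L, ...), 10)$samples
  joint <- mk()
  resp_only <- mk(beat_amp = 0, s1_amp = 0, s2_amp = 0)
  beat_only <- mk(resp_amp = 0, s1_amp = 0, s2_amp = 0)
  burst_only <- mk(resp_amp = 0, beat_amp = 0)
  expect_equal(resp_only + beat_only + burst_only, joint, tolerance = 1e-12)
})

test_that("at least 95% of burst energy lies inside the labeled intervals", {
  tr <- simulate_displacement(cardiac_sim_params(seed = 3L), 30)
  for (comp in c("s1", "s2")) {
    x <- tr$components[[comp]]
    total <- sum(x^2)
    cyc <- tr$labels$cycles
    inside <- sum(vapply(seq_len(nrow(cyc)), function(i) {
      i0 <- floor(cyc[[paste0(comp, "_start")]][i] * tr$rate) + 1L
      i1 <- floor(cyc[[paste0(comp, "_end")]][i] * tr$rate)
      sum(x[i0:i1]^2)
    }, numeric(1)))
    expect_gt(inside / total, 0.95)
  }
})

test_that("non-finite or inconsistent parameters are rejected by name", {
  expect_error(cardiac_sim_params(s1_amp = NaN), "s1_amp")
  expect_error(cardiac_sim_params(heart_rate = Inf), "heart_rate")
  expect_error(cardiac_sim_params(s1_delay = 0.5, s2_delay = 0.4),
               "s1_delay < s2_delay")
  expect_error(cardiac_sim_params(s2_delay = 1.2, heart_rate = 60),
               "60/heart_rate")
  expect_error(simulate_displacement(cardiac_sim_params(), 10, rate = 100),
               "rate")
})

test_that("accelerometer model is the second derivative of displacement", {
  # pure sinusoid: acceleration amplitude (2 pi f)^2 a within discretization
  f <- 35; a <- 5e-6
  tr <- waveform_trace(a * sin(2 * pi * f * (0:9999) / 1000))
  acc <- simulate_accelerometer(tr, noise_accel = 0)
  expect_rel_error(max(abs(acc$samples)), (2 * pi * f)^2 * a, 0.01)
  # zero trace, zero noise: zero output
  z <- simulate_accelerometer(waveform_trace(numeric(1000)), noise_accel = 0)
  expect_equal(z$samples, rep(0, 1000))
  # fixed seed: identical noise realization
  n1 <- simulate_accelerometer(tr, noise_accel = 0.05, seed = 9L)
  n2 <- simulate_accelerometer(tr, noise_accel = 0.05, seed = 9L)
  expect_identical(n1$samples, n2$samples)
  expect_error(simulate_accelerometer(waveform_trace(numeric(2), rate = 1000)),
               "3 samples")
})

test_that("noise-free stethoscope equals the high-passed micro-vibration", {
  tr <- simulate_displacement(cardiac_sim_params(seed = 5L), 10)
  st <- simulate_stethoscope(tr, hf_gain = 0, noise_stetho = 0,
                             background_level = 0)
  expected <- 1e6 * highpass_zero_phase(tr$samples, tr$rate, 20)
  expect_equal(st$samples, expected, tolerance = 1e-12)
})

test_that("doubling the S1 amplitude doubles the S1-segment RMS", {
  seg_rms <- function(amp) {
    tr <- simulate_displacement(
      cardiac_sim_params(s1_amp = amp, seed = 11L), 20)
    st <- simulate_stethoscope(tr, hf_gain = 0.3, noise_stetho = 0)
    cyc <- tr$labels$cycles
    vals <- unlist(lapply(seq_len(nrow(cyc)), function(i) {
      i0 <- floor(cyc$s1_start[i] * 1000) + 1L
      st$samples[i0:floor(cyc$s1_end[i] * 1000)]
    }))
    rms(vals)
  }
  expect_rel_error(seg_rms(1e-5) / seg_rms(5e-6), 2, 0.02)
})

test_that("dominant background sound drives stethoscope SNR below 3 dB", {
  tr <- simulate_displacement(cardiac_sim_params(seed = 13L), 30)
  st <- simulate_stethoscope(tr, background_level = 50, seed = 13L)
  hs <- process_stethoscope(st)
  rep <- segment_snr(hs, tr$labels)
  expect_lt(rep$s1_snr_db, 3)
  expect_lt(rep$s2_snr_db, 3)
})

test_that("stronger damping / background monotonically degrades the affected channel", {
  tr <- simulate_displacement(cardiac_sim_params(seed = 17L), 30)
  accel_snr <- vapply(c(1, 0.5, 0.2), function(dmp) {
    rec <- simulate_accelerometer(damp_bursts(tr, dmp), seed = 17L)
    segment_snr(process_accelerometer(rec), tr$labels)$s1_snr_db
  }, numeric(1))
  expect_true(all(diff(accel_snr) < 0))
  steth_snr <- vapply(c(0, 1, 4), function(bg) {
    rec <- simulate_stethoscope(tr, background_level = bg, seed = 17L)
    segment_snr(process_stethoscope(rec), tr$labels)$s1_snr_db
  }, numeric(1))
  expect_true(all(diff(steth_snr) < 0))
})
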
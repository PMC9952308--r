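# Beamforming, range processing, phase demodulation, heart-sound filtering.

test_that("steering vector matches its closed form", {
  expect_equal(steering_vector(0, 4)$weights, rep(1 + 0i, 4))
  # 30 degrees at half-wavelength spacing: phase step pi/2
  expect_equal(steering_vector(30, 4, 0.5)$weights,
               c(1 + 0i, 0 + 1i, -1 + 0i, 0 - 1i), tolerance = 1e-12)
  expect_equal(steering_vector(72, 1)$weights, 1 + 0i)
  expect_error(steering_vector(90, 4), "90")
})

test_that("matched beamforming gains a factor N in amplitude", {
  tr <- waveform_trace(numeric(20))
  cfg <- radar_config(fast_samples = 32)
  for (theta in c(0, 25)) {
    cube <- synthesize_cube(tr, sim_target(angle_theta = theta), cfg, 0)
    bf <- beamform(cube, steering_vector(theta, 12))
    expect_equal(mean(Mod(bf$samples)), 12 * mean(Mod(cube$data[, 1, ])),
                 tolerance = 1e-9)
  }
  # single-channel identity pass-through
  cfg1 <- radar_config(n_tx = 1, n_rx = 1, fast_samples = 32)
  cube1 <- synthesize_cube(tr, sim_target(), cfg1, 0)
  bf1 <- beamform(cube1, steering_vector(0, 1))
  expect_equal(bf1$samples, cube1$data[, 1, ], tolerance = 1e-12)
  expect_error(beamform(cube1, steering_vector(0, 12)), "does not match")
})

test_that("beamforming SNR gain over one channel approaches 10 log10(N) dB", {
  tr <- waveform_trace(numeric(40))
  cfg <- radar_config(fast_samples = 32)
  w <- steering_vector(0, 12)
  clean <- synthesize_cube(tr, sim_target(), cfg, 0)
  bfc <- beamform(clean, w)$samples
  set.seed(101)
  gains <- vapply(seq_len(60), function(i) {
    noisy <- synthesize_cube(tr, sim_target(), cfg, 1,
                             seed = sample.int(2^30, 1))
    noise <- noisy$data - clean$data
    noise_cube <- noisy; noise_cube$data <- noise
    bfn <- beamform(noise_cube, w)$samples
    snr_multi <- mean(Mod(bfc)^2) / mean(Mod(bfn)^2)
    snr_single <- mean(Mod(clean$data[, 1, ])^2) / mean(Mod(noise[, 1, ])^2)
    10 * log10(snr_multi / snr_single)
  }, numeric(1))
  expect_lt(abs(mean(gains) - 10 * log10(12)), 1)
})

test_that("two static reflectors two bins apart give two resolvable peaks", {
  cfg <- radar_config()
  bw <- cfg$range_bin_width
  expect_equal(bw, 299792458 / (2 * 3.6e9), tolerance = 1e-12) # c/(2B)
  tr <- waveform_trace(numeric(100))
  cube <- synthesize_cube(
    tr, list(sim_target(), sim_target(standoff = 0.5 + 2 * bw)), cfg, 0)
  rp <- range_profile(beamform(cube, steering_vector(0, 12)),
                      window = "rectangular")
  pw <- colMeans(Mod(rp$spectrum)^2)
  maxima <- which(diff(sign(diff(pw))) == -2) + 1
  maxima <- maxima[pw[maxima] > max(pw) / 100]
  expect_length(maxima, 2)
  # each peak sits in the bin nearest its reflector's range
  expect_equal(maxima, vapply(c(0.5, 0.5 + 2 * bw), function(r)
    which.min(abs(rp$range_axis - r)), integer(1)))
})

test_that("strongest-bin selection respects guard region and tie-break", {
  tr <- waveform_trace(numeric(50))
  cube <- synthesize_cube(tr, sim_target(), radar_config(), 0)
  rp <- range_profile(beamform(cube, steering_vector(0, 12)))
  bin <- select_strongest_bin(rp)
  expect_equal(rp$freq_axis[bin], 2e5) # the 200 kHz target
  # all-zero profile -> no target
  rp0 <- rp; rp0$spectrum[] <- 0
  expect_error(select_strongest_bin(rp0), "no target")
  # energy only inside the guard region -> no target
  rp1 <- rp0; rp1$spectrum[, 1:2] <- 1
  expect_error(select_strongest_bin(rp1, guard_bins = 2), "no target")
  # equal twin peaks: the nearer bin wins
  rp2 <- rp0; rp2$spectrum[, 10] <- 1; rp2$spectrum[, 20] <- 1
  expect_equal(select_strongest_bin(rp2), 10L)
  expect_error(extract_phase(rp, 1e4), "out of range")
})

test_that("unwrapped phase amplitude matches 4 pi a / lambda for a 5 um tone", {
  a <- 5e-6
  dp <- a * sin(2 * pi * 35 * (0:2999) / 1000)
  # modest sweep bandwidth keeps the effective carrier within 0.6% of f0,
  # isolating the first-order phase relation
  cfg <- radar_config(bandwidth_b = 0.9e9)
  cube <- synthesize_cube(waveform_trace(dp), sim_target(), cfg, 0)
  res <- process_radar_cube(cube)
  phi <- res$phase$samples - mean(res$phase$samples)
  amp <- (max(phi) - min(phi)) / 2
  expect_rel_error(amp, 4 * pi * a / (299792458 / 77e9), 0.01)
})

test_that("recovered displacement matches the simulated motion to < 1%", {
  p <- cardiac_sim_params(seed = 23L)
  tr <- simulate_displacement(p, 10)
  cube <- synthesize_cube(tr, sim_target(), radar_config(fast_samples = 64), 0)
  res <- process_radar_cube(cube)
  d <- res$phase$displacement - mean(res$phase$displacement)
  truth <- tr$samples - mean(tr$samples)
  expect_lt(rms(d - truth) / rms(truth), 0.01)
})

test_that("frame-to-frame phase advances by 4 pi dDp / lambda_eff", {
  dp <- cumsum(rep(1e-7, 100)) # steady 0.1 um/frame ramp
  cube <- synthesize_cube(waveform_trace(dp), sim_target(),
                          radar_config(fast_samples = 64), 0)
  res <- process_radar_cube(cube)
  steps <- diff(res$phase$samples)
  expect_equal(steps, rep(4 * pi * 1e-7 / res$phase$lambda_eff, 99),
               tolerance = 1e-6)
  # constant displacement: zero phase variance
  cube0 <- synthesize_cube(waveform_trace(rep(0, 100)), sim_target(),
                           radar_config(fast_samples = 64), 0)
  expect_equal(stats::var(process_radar_cube(cube0)$phase$samples), 0)
})

test_that("unwrapping stays continuous across a lambda/4 displacement ramp", {
  lam <- 299792458 / 77e9
  dp <- seq(0, lam / 2, length.out = 400) # phase sweep of 2 pi
  cube <- synthesize_cube(waveform_trace(dp), sim_target(),
                          radar_config(fast_samples = 64), 0)
  phi <- process_radar_cube(cube)$phase$samples
  expect_lt(max(abs(diff(phi))), pi)
  expect_gt(max(phi), 1.9 * pi) # total unwrapped travel, no 2 pi loss
})

test_that("integer-bin shifts of D0 leave the heart sound unchanged", {
  p <- cardiac_sim_params(seed = 29L)
  cfg <- radar_config(fast_samples = 64)
  hs <- lapply(c(0.5, 0.5 + 3 * cfg$range_bin_width), function(d0) {
    tr <- simulate_displacement(p, 8, d0 = d0)
    process_radar_cube(synthesize_cube(tr, sim_target(), cfg, 0))$heart_sound
  })
  expect_gt(stats::cor(hs[[1]]$samples, hs[[2]]$samples), 0.999)
})

test_that("heart-sound high-pass removes respiration and passes the S1/S2 band", {
  rate <- 1000
  t <- (0:9999) / rate
  resp <- sin(2 * pi * 0.25 * t)
  hp <- highpass_zero_phase(resp, rate, 20)
  expect_lt(rms(hp) / rms(resp), 0.01)
  burst <- sin(2 * pi * 40 * t)
  hp40 <- highpass_zero_phase(burst, rate, 20)
  expect_gt(20 * log10(rms(hp40) / rms(burst)), -1)
  hp30 <- highpass_zero_phase(sin(2 * pi * 30 * t), rate, 20)
  expect_gt(20 * log10(rms(hp30) / rms(sin(2 * pi * 30 * t))), -1)
  expect_equal(highpass_zero_phase(numeric(1000), rate, 20), numeric(1000))
  expect_error(highpass_zero_phase(numeric(10), rate, 20), "warm-up")
})

test_that("recovered heart sound has zero mean", {
  r <- cached_scenario("reference", 1L, 30)
  hs <- r$heart_sounds$radar
  expect_lt(abs(mean(hs$samples)), 1e-6 * rms(hs$samples))
})

test_that("angle estimation recovers the synthesis angle", {
  tr <- waveform_trace(numeric(20))
  for (theta in c(-30, 0, 15)) {
    cube <- synthesize_cube(tr, sim_target(angle_theta = theta),
                            radar_config(fast_samples = 32), 0.01, seed = 3L)
    expect_lt(abs(estimate_angle(cube) - theta), 1)
  }
})
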
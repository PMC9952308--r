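# Contact-sensor chains and file I/O.

test_that("stethoscope chain resamples 44.1 kHz to 1000 Hz preserving duration", {
  t <- seq(0, 10, by = 1 / 44100)[1:441000]
  rec <- sensor_record(sin(2 * pi * 100 * t), 44100, "stethoscope")
  hs <- process_stethoscope(rec)
  expect_equal(hs$rate, 1000)
  expect_lt(abs(length(hs$samples) - 10000), 2)
})

test_that("stethoscope chain stops 5 Hz and passes 100 Hz within 1 dB", {
  t <- (0:99999) / 10000
  low <- sensor_record(sin(2 * pi * 5 * t), 10000, "stethoscope")
  expect_lt(rms(process_stethoscope(low)$samples) / rms(low$samples), 0.01)
  hi <- sensor_record(sin(2 * pi * 100 * t), 10000, "stethoscope")
  expect_gt(20 * log10(rms(process_stethoscope(hi)$samples) /
                         rms(hi$samples)), -1)
})

test_that("accelerometer chain nulls 50 Hz and follows the boxcar gain at 35 Hz", {
  t <- (0:19999) / 1000
  const <- sensor_record(rep(2.5, 20000), 1000, "accelerometer")
  expect_lt(rms(process_accelerometer(const)$samples), 1e-8 * 2.5)
  x50 <- sensor_record(sin(2 * pi * 50 * t), 1000, "accelerometer")
  atten <- 20 * log10(rms(x50$samples) /
                        rms(process_accelerometer(x50)$samples))
  expect_gt(atten, 30)
  x35 <- sensor_record(sin(2 * pi * 35 * t), 1000, "accelerometer")
  gain <- rms(process_accelerometer(x35)$samples) / rms(x35$samples)
  boxcar <- abs(sin(pi * 35 * 20 / 1000) / (20 * sin(pi * 35 / 1000)))
  expect_rel_error(gain, boxcar, 0.02) # within the HPF's 35 Hz droop
  expect_error(process_accelerometer(
    sensor_record(numeric(10), 1000, "accelerometer")), "too short")
})

test_that("both chains are linear in the input", {
  set.seed(31)
  x <- stats::rnorm(5000)
  st1 <- process_stethoscope(sensor_record(x, 2000, "stethoscope"))
  st3 <- process_stethoscope(sensor_record(3 * x, 2000, "stethoscope"))
  expect_equal(st3$samples, 3 * st1$samples, tolerance = 1e-9)
  ac1 <- process_accelerometer(sensor_record(x, 1000, "accelerometer"))
  ac3 <- process_accelerometer(sensor_record(3 * x, 1000, "accelerometer"))
  expect_equal(ac3$samples, 3 * ac1$samples, tolerance = 1e-9)
})

test_that("processed channels of one scenario share a common time base", {
  # noise-free synthesis: the S1 peak must line up across all three chains
  tr <- simulate_displacement(cardiac_sim_params(seed = 37L), 20)
  cube <- synthesize_cube(tr, sim_target(), radar_config(fast_samples = 32), 0)
  chans <- list(
    radar = process_radar_cube(cube)$heart_sound,
    stethoscope = process_stethoscope(
      simulate_stethoscope(tr, noise_stetho = 0)),
    accelerometer = process_accelerometer(
      simulate_accelerometer(tr, noise_accel = 0)))
  first_s1 <- tr$labels$cycles[1, ]
  peak_lag <- vapply(chans, function(hs) {
    i0 <- floor(first_s1$s1_start * hs$rate) - 30L
    i1 <- floor(first_s1$s1_end * hs$rate) + 30L
    (i0 + which.max(abs(hs$samples[i0:i1])) - 1) / hs$rate
  }, numeric(1))
  expect_lt(max(peak_lag) - min(peak_lag), 0.020)
})

test_that("PCM16 WAV files round-trip bit-exactly", {
  path <- withr::local_tempfile(fileext = ".wav")
  x <- round(32767 * sin(2 * pi * 40 * (0:999) / 1000)) / 32767
  write_wav(x, 1000, path)
  bytes <- readBin(path, "raw", file.size(path))
  rec <- read_wav(path)
  expect_equal(rec$rate, 1000)
  expect_equal(rec$samples, x, tolerance = 1e-12)
  write_wav(rec$samples, rec$rate, path)
  expect_identical(readBin(path, "raw", file.size(path)), bytes)
  # float32 path preserves rate and length
  write_wav(x, 1000, path, format = "float32")
  expect_equal(read_wav(path)$samples, x, tolerance = 1e-7)
})

test_that("accelerometer CSV reading infers rate and rejects bad timestamps", {
  path <- withr::local_tempfile(fileext = ".csv")
  tm <- (0:999) / 1000
  utils::write.csv(data.frame(time_s = tm, accel_mps2 = sin(tm)), path,
                   row.names = FALSE)
  rec <- read_accel_csv(path)
  expect_equal(rec$rate, 1000)
  expect_equal(rec$samples, sin(tm))
  # shuffled rows: not strictly increasing
  set.seed(4)
  utils::write.csv(data.frame(time_s = sample(tm), accel_mps2 = sin(tm)),
                   path, row.names = FALSE)
  expect_error(read_accel_csv(path), "not strictly increasing")
  # irregular spacing beyond 1%
  tj <- tm + c(0, cumsum(stats::runif(999, -2e-4, 2e-4)))
  utils::write.csv(data.frame(time_s = sort(tj), accel_mps2 = sin(tm)), path,
                   row.names = FALSE)
  expect_error(read_accel_csv(path), "irregular")
  # round trip through the writer
  rec2 <- sensor_record(sin(tm), 1000, "accelerometer")
  write_accel_csv(rec2, path)
  expect_equal(read_accel_csv(path)$samples, rec2$samples)
})
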
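# Synthesis of raw complex-baseband TDM-MIMO FMCW data from a displacement
# trace.
#
# The dechirped per-channel baseband model for a point target at standoff
# D0 + Dp(t) and spatial angle theta is
#
#   s_n(tau, t) = A exp(j 2 pi [alpha tau_d(t) tau + fc tau_d(t)])
#                   * exp(j 2 pi (d0/lambda) (n-1) sin(theta)),
#
# with round-trip delay tau_d(t) = 2 (D0 + Dp(t)) / c, chirp slope
# alpha = B / T_chirp, fast time tau within a chirp, and slow time t the
# frame index. All chirps of one frame share one tau_d (the displacement
# change over the ~120 us TDM offset is negligible at cardiac velocities).

#' FMCW MIMO radar configuration
#'
#' Defaults follow a 77 GHz automotive-band sensor: 3.6 GHz sweep bandwidth,
#' 60 us chirps, 1 ms frame interval (slow-time rate 1000 Hz), 3 TX x 4 RX
#' TDM-MIMO giving a 12-element virtual uniform linear array at half-
#' wavelength spacing.
#'
#' @param f0 Sweep start frequency in Hz.
#' @param bandwidth_b Sweep bandwidth B in Hz.
#' @param chirp_time Chirp duration in seconds.
#' @param frame_interval Frame interval T_FI in seconds (slow-time period).
#' @param n_tx,n_rx Transmit and receive channel counts.
#' @param fast_samples Complex fast-time samples per chirp.
#' @param adc_rate Complex ADC rate in Hz (default `fast_samples/chirp_time`,
#'   i.e. sampling spans the whole chirp).
#' @param d0_spacing Array element spacing as a fraction of the wavelength.
#' @return Object of class `radar_config` with derived fields `slope`
#'   (alpha, Hz/s), `wavelength` (m), `slow_rate` (Hz), `n_virtual`,
#'   `range_bin_width` (m).
#' @export
radar_config <- function(f0 = 77e9, bandwidth_b = 3.6e9, chirp_time = 60e-6,
                         frame_interval = 1e-3, n_tx = 3, n_rx = 4,
                         fast_samples = 256,
                         adc_rate = fast_samples / chirp_time,
                         d0_spacing = 0.5) {
  check_finite_scalar(f0, "f0", min = 1)
  check_finite_scalar(bandwidth_b, "bandwidth_b", min = 1)
  check_finite_scalar(chirp_time, "chirp_time", min = .Machine$double.eps)
  check_finite_scalar(frame_interval, "frame_interval",
                      min = .Machine$double.eps)
  check_finite_scalar(n_tx, "n_tx", min = 1)
  check_finite_scalar(n_rx, "n_rx", min = 1)
  check_finite_scalar(fast_samples, "fast_samples", min = 2)
  check_finite_scalar(adc_rate, "adc_rate", min = 1)
  check_finite_scalar(d0_spacing, "d0_spacing", min = .Machine$double.eps)
  if (n_tx * chirp_time > frame_interval)
    stop("TDM chirps do not fit in one frame: n_tx * chirp_time > frame_interval",
         call. = FALSE)
  cfg <- list(f0 = f0, bandwidth_b = bandwidth_b, chirp_time = chirp_time,
              frame_interval = frame_interval,
              n_tx = as.integer(n_tx), n_rx = as.integer(n_rx),
              fast_samples = as.integer(fast_samples), adc_rate = adc_rate,
              d0_spacing = d0_spacing)
  cfg$slope <- bandwidth_b / chirp_time
  cfg$wavelength <- SPEED_OF_LIGHT / f0
  cfg$slow_rate <- 1 / frame_interval
  cfg$n_virtual <- cfg$n_tx * cfg$n_rx
  cfg$range_bin_width <- SPEED_OF_LIGHT * (adc_rate / fast_samples) /
    (2 * cfg$slope)
  structure(cfg, class = "radar_config")
}

#' @export
print.radar_config <- function(x, ...) {
  cat("FMCW MIMO radar configuration\n")
  cat(sprintf("  f0 = %.3g GHz, B = %.3g GHz, chirp %g us, slope %.3g Hz/s\n",
              x$f0 / 1e9, x$bandwidth_b / 1e9, x$chirp_time * 1e6, x$slope))
  cat(sprintf("  frame interval %g ms (slow-time rate %g Hz)\n",
              x$frame_interval * 1e3, x$slow_rate))
  cat(sprintf("  %d TX x %d RX = %d virtual elements at %.2f lambda spacing\n",
              x$n_tx, x$n_rx, x$n_virtual, x$d0_spacing))
  cat(sprintf("  %d fast-time samples at %.3g MHz, range bin %.1f mm\n",
              x$fast_samples, x$adc_rate / 1e6, x$range_bin_width * 1e3))
  invisible(x)
}

#' Point target for radar synthesis
#'
#' @param reflectivity Complex round-trip path-loss coefficient A
#'   (`|reflectivity| > 0`).
#' @param angle_theta Target spatial angle in degrees (broadside = 0).
#' @param standoff Optional static standoff in metres; `NULL` (default)
#'   uses the displacement trace's `d0`. Useful for synthesizing secondary
#'   static reflectors at other ranges.
#' @return Object of class `sim_target`.
#' @export
sim_target <- function(reflectivity = 1 + 0i, angle_theta = 0,
                       standoff = NULL) {
  if (length(reflectivity) != 1L || !is.finite(Mod(reflectivity)) ||
      Mod(reflectivity) <= 0)
    stop("parameter 'reflectivity' must have positive finite magnitude",
         call. = FALSE)
  check_finite_scalar(angle_theta, "angle_theta", min = -90, max = 90)
  if (!is.null(standoff))
    check_finite_scalar(standoff, "standoff", min = .Machine$double.eps)
  structure(list(reflectivity = as.complex(reflectivity),
                 angle_theta = angle_theta, standoff = standoff),
            class = "sim_target")
}

#' Synthesize a raw MIMO FMCW data cube from a displacement trace
#'
#' @param trace A [simulate_displacement()] trace sampled at the slow-time
#'   rate `1/config$frame_interval`; its `d0` is the static standoff D0.
#' @param target A [sim_target()] or a list of them (signals add linearly).
#' @param config A [radar_config()].
#' @param noise_rms Complex receiver-noise RMS per channel sample (total
#'   complex power; 0 disables noise).
#' @param seed Integer seed for the noise realization.
#' @return A `raw_data_cube`: complex array `data[frame, channel, sample]`
#'   plus `config`, `geometry` (0-based virtual element indices), `d0`.
#' @export
synthesize_cube <- function(trace, target, config, noise_rms = 0,
                            seed = NULL) {
  stopifnot(inherits(trace, "displacement_trace"),
            inherits(config, "radar_config"))
  if (inherits(target, "sim_target")) target <- list(target)
  stopifnot(all(vapply(target, inherits, TRUE, "sim_target")))
  check_finite_scalar(noise_rms, "noise_rms", min = 0)
  if (abs(trace$rate - config$slow_rate) > 1e-6 * config$slow_rate)
    stop(sprintf(
      "trace rate (%g Hz) does not match the radar slow-time rate (%g Hz)",
      trace$rate, config$slow_rate), call. = FALSE)
  max_range <- SPEED_OF_LIGHT * config$adc_rate / (4 * config$slope)
  if (trace$d0 <= 0 || trace$d0 >= max_range)
    stop(sprintf("standoff D0 = %g m outside the unambiguous range (0, %g m)",
                 trace$d0, max_range), call. = FALSE)

  n_frames <- length(trace$samples)
  n_chan <- config$n_virtual
  k <- config$fast_samples
  tau <- (0:(k - 1)) / config$adc_rate

  cube <- array(0 + 0i, dim = c(n_frames, n_chan, k))
  for (tg in target) {
    # targets with an explicit standoff are static reflectors; the chest
    # target (standoff NULL) carries the displacement Dp(t)
    disp <- if (is.null(tg$standoff)) trace$d0 + trace$samples
            else rep(tg$standoff, n_frames)
    taud <- 2 * disp / SPEED_OF_LIGHT
    sig <- tg$reflectivity *
      exp(1i * 2 * pi * (config$slope * outer(taud, tau) + config$f0 * taud))
    steer <- exp(1i * 2 * pi * config$d0_spacing * (0:(n_chan - 1)) *
                   sin(tg$angle_theta * pi / 180))
    for (n in seq_len(n_chan))
      cube[, n, ] <- cube[, n, ] + sig * steer[n]
  }
  if (noise_rms > 0) {
    cube <- cube + with_seed(seed, {
      sd1 <- noise_rms / sqrt(2)
      array(complex(real = stats::rnorm(length(cube), sd = sd1),
                    imaginary = stats::rnorm(length(cube), sd = sd1)),
            dim = dim(cube))
    })
  }
  structure(list(data = cube, config = config,
                 geometry = 0:(n_chan - 1), d0 = trace$d0),
            class = "raw_data_cube")
}

#' @export
print.raw_data_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Raw FMCW data cube: %d frames x %d virtual channels x %d fast-time samples\n",
              d[1], d[2], d[3]))
  cat(sprintf("  %.1f s of slow time at %g Hz, D0 = %.3g m\n",
              d[1] / x$config$slow_rate, x$config$slow_rate, x$d0))
  invisible(x)
}

cube_dtype_size <- c(complex64 = 4L, complex128 = 8L)

#' Save a raw data cube as flat binary plus JSON sidecar
#'
#' The binary file holds interleaved (re, im) little-endian floats in
#' `[frame, channel, sample]` C order; the sidecar (`<path>.json`) records
#' the shape, dtype, radar configuration, channel geometry and standoff.
#'
#' @param cube A `raw_data_cube`.
#' @param path Output path for the binary file.
#' @param dtype `"complex64"` (float32 pairs, default) or `"complex128"`.
#' @return `path`, invisibly.
#' @export
save_cube <- function(cube, path, dtype = c("complex64", "complex128")) {
  stopifnot(inherits(cube, "raw_data_cube"))
  dtype <- match.arg(dtype)
  d <- dim(cube$data)
  flat <- as.vector(aperm(cube$data, c(3, 2, 1))) # C order, last index fastest
  inter <- numeric(2 * length(flat))
  inter[c(TRUE, FALSE)] <- Re(flat)
  inter[c(FALSE, TRUE)] <- Im(flat)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(inter, con, size = cube_dtype_size[[dtype]], endian = "little")
  sidecar <- list(
    format = "radarsteth-cube", version = 1L,
    shape = d, order = "frame,channel,sample", dtype = dtype,
    byte_order = "little", d0 = cube$d0, geometry = cube$geometry,
    config = unclass(cube$config)[c("f0", "bandwidth_b", "chirp_time",
                                    "frame_interval", "n_tx", "n_rx",
                                    "fast_samples", "adc_rate", "d0_spacing")])
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a raw data cube saved by [save_cube()]
#'
#' @param path Path to the binary file (the sidecar `<path>.json` must be
#'   present and consistent).
#' @return A `raw_data_cube`.
#' @export
load_cube <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(path)) stop("cube file not found: ", path, call. = FALSE)
  if (!file.exists(side_path))
    stop("sidecar metadata not found: ", side_path, call. = FALSE)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  shape <- as.integer(side$shape)
  if (length(shape) != 3L)
    stop("sidecar shape must have 3 entries, found ", length(shape),
         call. = FALSE)
  cfg <- do.call(radar_config, as.list(side$config))
  if (shape[2] != cfg$n_virtual)
    stop(sprintf(
      "sidecar channel count (%d) does not match config n_tx*n_rx (%d)",
      shape[2], cfg$n_virtual), call. = FALSE)
  size <- cube_dtype_size[[side$dtype]]
  expected <- prod(shape) * 2 * size
  actual <- file.size(path)
  if (actual != expected)
    stop(sprintf("cube file has %d bytes, expected %d (missing %d)",
                 actual, expected, expected - actual), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  inter <- readBin(con, "numeric", n = prod(shape) * 2, size = size,
                   endian = "little")
  flat <- complex(real = inter[c(TRUE, FALSE)],
                  imaginary = inter[c(FALSE, TRUE)])
  data <- aperm(array(flat, dim = rev(shape)), c(3, 2, 1))
  structure(list(data = data, config = cfg,
                 geometry = as.integer(side$geometry), d0 = side$d0),
            class = "raw_data_cube")
}
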
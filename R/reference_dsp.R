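# Contact-sensor processing chains: stethoscope and accelerometer.

#' Raw contact-sensor record
#'
#' @param samples Numeric vector of samples.
#' @param rate Sampling rate in Hz.
#' @param kind Either `"stethoscope"` or `"accelerometer"`.
#' @param units Sample units (`"a.u."` or `"m/s^2"`).
#' @return Object of class `sensor_record`.
#' @export
sensor_record <- function(samples, rate,
                          kind = c("stethoscope", "accelerometer"),
                          units = NULL) {
  kind <- match.arg(kind)
  check_finite_scalar(rate, "rate", min = .Machine$double.eps)
  if (!all(is.finite(samples)))
    stop("sensor record contains non-finite samples", call. = FALSE)
  units <- units %||% if (kind == "accelerometer") "m/s^2" else "a.u."
  structure(list(samples = as.numeric(samples), rate = rate,
                 kind = kind, units = units), class = "sensor_record")
}

#' @export
print.sensor_record <- function(x, ...) {
  cat(sprintf("%s record: %d samples at %g Hz (%s)\n",
              x$kind, length(x$samples), x$rate, x$units))
  invisible(x)
}

#' Stethoscope processing chain
#'
#' 20 Hz zero-phase high-pass (the digital converter's built-in filter),
#' then polyphase resampling to the radar slow-time rate so all channels
#' share a common time base.
#'
#' @param rec A `sensor_record` of kind `"stethoscope"`.
#' @param target_rate Output rate in Hz (default 1000, the radar slow-time
#'   rate).
#' @param cutoff High-pass corner in Hz (default 20).
#' @return A [heart_sound()] signal at `target_rate`.
#' @export
process_stethoscope <- function(rec, target_rate = 1000, cutoff = 20) {
  stopifnot(inherits(rec, "sensor_record"))
  if (rec$kind != "stethoscope")
    stop("record kind must be 'stethoscope', got '", rec$kind, "'",
         call. = FALSE)
  check_finite_scalar(target_rate, "target_rate", min = 2 * cutoff)
  x <- highpass_zero_phase(rec$samples, rec$rate, cutoff)
  if (rec$rate != target_rate) {
    frac <- rational_ratio(target_rate, rec$rate)
    x <- as.numeric(signal::resample(x, frac[1], frac[2]))
  }
  heart_sound(x - mean(x), target_rate, units = "a.u.",
              channel = "stethoscope", band_low = cutoff)
}

# Reduce target_rate/input_rate to an integer p/q ratio for the polyphase
# resampler.
rational_ratio <- function(p, q) {
  scale <- 10^max(0, -min(floor(log10(c(p, q)))))
  p <- round(p * scale); q <- round(q * scale)
  g <- gcd_int(p, q)
  c(p / g, q / g)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Accelerometer (seismocardiogram) processing chain
#'
#' 20 Hz zero-phase high-pass to remove respiration and the fundamental
#' heart beat, then a centered moving average over `ma_window` samples to
#' denoise. At 1000 Hz a 20-sample boxcar has spectral nulls at multiples of
#' 50 Hz, which bounds the chain's effective passband to roughly 20-50 Hz.
#'
#' @param rec A `sensor_record` of kind `"accelerometer"`.
#' @param cutoff High-pass corner frequency in Hz (default 20).
#' @param ma_window Moving-average length in samples (default 20).
#' @return A [heart_sound()] signal at the input rate.
#' @export
process_accelerometer <- function(rec, cutoff = 20, ma_window = 20) {
  stopifnot(inherits(rec, "sensor_record"))
  if (rec$kind != "accelerometer")
    stop("record kind must be 'accelerometer', got '", rec$kind, "'",
         call. = FALSE)
  if (length(rec$samples) <= ma_window)
    stop(sprintf("record of %d samples too short (moving average window %d)",
                 length(rec$samples), ma_window), call. = FALSE)
  x <- highpass_zero_phase(rec$samples, rec$rate, cutoff)
  x <- moving_average(x, ma_window)
  heart_sound(x - mean(x), rec$rate, units = rec$units,
              channel = "accelerometer", band_low = cutoff)
}

#' Read an accelerometer CSV (time_s, accel_mps2)
#'
#' The rate is inferred from the median timestamp spacing; timestamps must be
#' strictly increasing with less than 1% jitter.
#'
#' @param path Path to a 2-column CSV with a header.
#' @return A `sensor_record` of kind `"accelerometer"`.
#' @export
read_accel_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop("accelerometer CSV needs 2 columns (time_s, accel)",
                        call. = FALSE)
  tm <- as.numeric(d[[1]]); x <- as.numeric(d[[2]])
  dt <- diff(tm)
  if (length(dt) < 2 || any(!is.finite(dt)))
    stop("accelerometer CSV too short or non-numeric", call. = FALSE)
  if (any(dt <= 0))
    stop("timestamps are not strictly increasing (rows out of order?)",
         call. = FALSE)
  med <- stats::median(dt)
  if (max(abs(dt - med)) > 0.01 * med)
    stop(sprintf("irregular timestamps: jitter %.2f%% exceeds 1%%",
                 100 * max(abs(dt - med)) / med), call. = FALSE)
  sensor_record(x, 1 / med, kind = "accelerometer")
}

#' Write an accelerometer record as a 2-column CSV
#'
#' @param rec A `sensor_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(rec, path) {
  stopifnot(inherits(rec, "sensor_record"))
  tm <- (seq_along(rec$samples) - 1L) / rec$rate
  utils::write.csv(data.frame(time_s = tm, accel_mps2 = rec$samples),
                   path, row.names = FALSE)
  invisible(path)
}
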
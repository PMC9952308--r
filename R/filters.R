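# Shared filtering primitives.
#
# The same zero-phase 20 Hz high-pass is used by the radar, stethoscope and
# accelerometer chains so that S1/S2 timing is directly comparable across
# channels (forward-backward filtering has zero group delay).

#' Zero-phase Butterworth high-pass filter
#'
#' Applies an order-`order` Butterworth high-pass forward and backward
#' (`signal::filtfilt`), giving zero phase distortion and an effective
#' magnitude response of the squared one-pass response.
#'
#' @param x Numeric vector to filter.
#' @param rate Sampling rate in Hz; must exceed `2 * cutoff`.
#' @param cutoff High-pass corner frequency in Hz (default 20, below the
#'   S1/S2 band but above respiration and the fundamental heart beat).
#' @param order Butterworth order of the one-pass prototype (default 4).
#' @return Filtered numeric vector of the same length as `x`.
#' @export
highpass_zero_phase <- function(x, rate, cutoff = 20, order = 4L) {
  check_finite_scalar(rate, "rate", min = .Machine$double.eps)
  check_finite_scalar(cutoff, "cutoff", min = 0)
  if (rate <= 2 * cutoff)
    stop(sprintf("sampling rate %g Hz must exceed twice the cutoff (%g Hz)",
                 rate, cutoff), call. = FALSE)
  if (!all(is.finite(x))) stop("input signal contains non-finite samples",
                               call. = FALSE)
  # filtfilt needs a few filter lengths of data to settle its edge handling
  warmup <- 6L * (order + 1L)
  if (length(x) <= warmup)
    stop(sprintf("record of %d samples shorter than filter warm-up (%d samples)",
                 length(x), warmup), call. = FALSE)
  flt <- signal::butter(order, cutoff / (rate / 2), type = "high")
  filtfilt_padded(flt, x)
}

# Forward-backward filtering with odd-reflection end padding, which
# suppresses the start-up transients filtfilt otherwise leaves on signals
# with non-zero ends (e.g. a DC offset).
#' @noRd
filtfilt_padded <- function(flt, x) {
  n <- length(x)
  pad <- min(n - 1L, 300L)
  left <- 2 * x[1] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- as.numeric(signal::filtfilt(flt, c(left, x, right)))
  y[(pad + 1L):(pad + n)]
}

#' Zero-phase Butterworth low-pass filter (internal, envelope smoothing)
#' @noRd
lowpass_zero_phase <- function(x, rate, cutoff, order = 2L) {
  flt <- signal::butter(order, cutoff / (rate / 2), type = "low")
  filtfilt_padded(flt, x)
}

#' Centered moving-average (boxcar) smoother
#'
#' Length-preserving centered moving average; edges are handled by
#' replicating the first/last sample. For an even window the kernel extends
#' one sample further into the past than into the future.
#'
#' @param x Numeric vector.
#' @param window Window length in samples.
#' @return Smoothed vector, same length as `x`.
#' @export
moving_average <- function(x, window) {
  check_finite_scalar(window, "window", min = 1)
  window <- as.integer(window)
  n <- length(x)
  if (n <= window)
    stop(sprintf("record of %d samples too short for a %d-sample moving average",
                 n, window), call. = FALSE)
  lead <- (window - 1L) %/% 2L
  lag <- window - 1L - lead
  xp <- c(rep(x[1L], lag), x, rep(x[n], lead))
  y <- as.numeric(stats::filter(xp, rep(1 / window, window), sides = 1))
  y[window:(window + n - 1L)]
}
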
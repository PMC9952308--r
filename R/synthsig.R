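# Synthetic cardiorespiratory chest-wall motion and contact-sensor channels.
#
# The displacement model is additive in three components:
#   (i)  a respiration sinusoid (mm scale, ~0.25 Hz),
#   (ii) a raised-cosine heart-beat pulse train (sub-mm, band-limited < 20 Hz),
#   (iii) exponentially damped sinusoid bursts for the first (S1) and second
#        (S2) heart sounds (micrometer scale, 20-75 Hz band).
# Only component (iii) survives the 20 Hz high-pass of the processing chains,
# which is exactly the separation the radar pipeline relies on.

STETH_GAIN <- 1e6 # stethoscope arbitrary units per metre of skin vibration

#' Parameters of the synthetic cardiac motion model
#'
#' @param heart_rate Heart rate in beats/min.
#' @param resp_rate Respiration rate in breaths/min.
#' @param resp_amp Respiration chest excursion amplitude in metres.
#' @param beat_amp Heart-beat pulse amplitude in metres.
#' @param s1_amp,s2_amp Peak displacement of the S1/S2 bursts in metres
#'   (micrometer scale; the burst envelope is normalized so the waveform peak
#'   equals the stated amplitude).
#' @param s1_freq,s2_freq Burst centre frequencies in Hz (20-75 Hz band).
#' @param s1_delay,s2_delay Burst onset delays after each cycle onset, seconds.
#' @param burst_decay Exponential envelope decay rate, 1/s.
#' @param damping Unitless multiplier in \[0,1\] applied to both burst
#'   amplitudes (models chest-band pressure damping in the challenge cases).
#' @param cycle_jitter_sd Standard deviation of Gaussian jitter on cycle
#'   onsets, seconds (default 10 ms; 0 disables jitter).
#' @param noise_accel Accelerometer white-noise RMS, m/s^2.
#' @param noise_stetho Stethoscope sensor-noise RMS, arbitrary units.
#' @param seed Integer seed controlling cycle jitter (NULL for unseeded).
#' @return An object of class `cardiac_sim_params`.
#' @export
cardiac_sim_params <- function(heart_rate = 60, resp_rate = 15,
                               resp_amp = 2e-3, beat_amp = 3e-4,
                               s1_amp = 5e-6, s2_amp = 3.5e-6,
                               s1_freq = 35, s2_freq = 45,
                               s1_delay = 0.03, s2_delay = 0.33,
                               burst_decay = 35, damping = 1,
                               cycle_jitter_sd = 0.010,
                               noise_accel = 0.045, noise_stetho = 0.4,
                               seed = 1L) {
  p <- list(heart_rate = heart_rate, resp_rate = resp_rate,
            resp_amp = resp_amp, beat_amp = beat_amp,
            s1_amp = s1_amp, s2_amp = s2_amp,
            s1_freq = s1_freq, s2_freq = s2_freq,
            s1_delay = s1_delay, s2_delay = s2_delay,
            burst_decay = burst_decay, damping = damping,
            cycle_jitter_sd = cycle_jitter_sd,
            noise_accel = noise_accel, noise_stetho = noise_stetho,
            seed = seed)
  check_finite_scalar(heart_rate, "heart_rate", min = 1)
  check_finite_scalar(resp_rate, "resp_rate", min = 0)
  for (nm in c("resp_amp", "beat_amp", "s1_amp", "s2_amp"))
    check_finite_scalar(p[[nm]], nm, min = 0)
  check_finite_scalar(s1_freq, "s1_freq", min = 1)
  check_finite_scalar(s2_freq, "s2_freq", min = 1)
  check_finite_scalar(s1_delay, "s1_delay", min = 0)
  check_finite_scalar(s2_delay, "s2_delay", min = 0)
  check_finite_scalar(burst_decay, "burst_decay", min = .Machine$double.eps)
  check_finite_scalar(damping, "damping", min = 0, max = 1)
  check_finite_scalar(cycle_jitter_sd, "cycle_jitter_sd", min = 0)
  check_finite_scalar(noise_accel, "noise_accel", min = 0)
  check_finite_scalar(noise_stetho, "noise_stetho", min = 0)
  if (!(s1_delay < s2_delay && s2_delay < 60 / heart_rate))
    stop("require s1_delay < s2_delay < 60/heart_rate", call. = FALSE)
  structure(p, class = "cardiac_sim_params")
}

#' @export
print.cardiac_sim_params <- function(x, ...) {
  cat("Cardiac simulation parameters\n")
  cat(sprintf("  heart rate %g bpm, respiration %g bpm\n",
              x$heart_rate, x$resp_rate))
  cat(sprintf("  S1: %.1f um at %g Hz (+%.0f ms); S2: %.1f um at %g Hz (+%.0f ms)\n",
              x$s1_amp * 1e6, x$s1_freq, x$s1_delay * 1e3,
              x$s2_amp * 1e6, x$s2_freq, x$s2_delay * 1e3))
  cat(sprintf("  damping %g, burst decay %g /s, cycle jitter sd %.0f ms\n",
              x$damping, x$burst_decay, x$cycle_jitter_sd * 1e3))
  invisible(x)
}

# Peak value of exp(-d t) * sin(2 pi f t); used to normalize burst amplitude
# so the waveform peak equals the requested displacement.
burst_peak_factor <- function(freq, decay) {
  w <- 2 * pi * freq
  tstar <- atan(w / decay) / w
  exp(-decay * tstar) * sin(w * tstar)
}

# Labeled burst duration: fraction 1 - exp(-2*decay*T) of burst energy lies
# inside [onset, onset + T]; T = 2/decay keeps ~98% inside the label while
# ending where the envelope has fallen to e^-2 of its peak, the same
# convention the automatic segmenter uses for its trailing edge.
burst_label_duration <- function(decay) 2 / decay

# Add damped-sinusoid bursts at the given onsets to a zero vector.
burst_train <- function(t, onsets, amp, freq, decay) {
  out <- numeric(length(t))
  if (amp <= 0 || length(onsets) == 0L) return(out)
  scale <- amp / burst_peak_factor(freq, decay)
  rate <- 1 / (t[2] - t[1])
  tail_n <- ceiling(8 / decay * rate) # envelope < 3e-4 of peak beyond this
  for (o in onsets) {
    i0 <- max(1L, floor(o * rate) + 1L)
    i1 <- min(length(t), i0 + tail_n)
    if (i0 > length(t)) next
    tt <- t[i0:i1] - o
    keep <- tt >= 0
    out[i0:i1][keep] <- out[i0:i1][keep] +
      scale * exp(-decay * tt[keep]) * sin(2 * pi * freq * tt[keep])
  }
  out
}

#' Segmentation labels for S1/S2 bursts and per-cycle noise windows
#'
#' @param cycles Data frame with columns `s1_start`, `s1_end`, `s2_start`,
#'   `s2_end`, `noise_start`, `noise_end` (seconds, half-open intervals).
#' @param duration Record duration in seconds (used for validation).
#' @return Object of class `segmentation_labels`.
#' @export
segmentation_labels <- function(cycles, duration = Inf) {
  need <- c("s1_start", "s1_end", "s2_start", "s2_end",
            "noise_start", "noise_end")
  if (!all(need %in% names(cycles)))
    stop("labels need columns: ", paste(need, collapse = ", "), call. = FALSE)
  cycles <- as.data.frame(cycles)[need]
  if (nrow(cycles) > 0) {
    ok <- with(cycles, s1_start < s1_end & s1_end <= s2_start &
                 s2_start < s2_end & s2_end <= noise_start &
                 noise_start < noise_end & noise_end <= duration + 1e-9 &
                 s1_start >= 0)
    if (!all(ok))
      stop("segment intervals must be ordered, disjoint and within the record",
           call. = FALSE)
  }
  structure(list(cycles = cycles), class = "segmentation_labels")
}

#' @export
print.segmentation_labels <- function(x, ...) {
  cat(sprintf("Segmentation labels: %d cardiac cycles\n", nrow(x$cycles)))
  invisible(x)
}

#' Number of labeled cardiac cycles
#' @param labels A `segmentation_labels` object.
#' @export
n_cycles <- function(labels) nrow(labels$cycles)

#' Simulate chest-wall displacement with S1/S2 micro-vibration bursts
#'
#' Generates the additive displacement model (respiration + heart-beat pulse
#' train + damped-sinusoid S1/S2 bursts) at the radar slow-time rate, together
#' with ground-truth segmentation labels derived from the burst envelopes.
#'
#' @param params A [cardiac_sim_params()] object.
#' @param duration Record duration in seconds.
#' @param rate Sampling rate in Hz (>= 500; use `1/frame_interval` of the
#'   paired radar configuration, 1000 Hz at defaults).
#' @param d0 Static standoff distance to the radar in metres (default 0.5).
#' @return A `displacement_trace`: list with `samples` (metres), `rate`,
#'   `d0`, `labels` (truth segmentation), `onsets` (cycle onset times),
#'   `components` (the three additive parts), and `params`.
#' @export
simulate_displacement <- function(params, duration, rate = 1000, d0 = 0.5) {
  stopifnot(inherits(params, "cardiac_sim_params"))
  check_finite_scalar(duration, "duration", min = .Machine$double.eps)
  check_finite_scalar(rate, "rate", min = 500)
  check_finite_scalar(d0, "d0")

  n <- round(duration * rate)
  t <- (seq_len(n) - 1L) / rate
  period <- 60 / params$heart_rate

  # cycle onsets with optional (seeded) Gaussian jitter, clamped so cycles
  # cannot reorder
  k <- 0:(ceiling(duration / period))
  onsets <- k * period
  if (params$cycle_jitter_sd > 0) {
    jit <- with_seed(params$seed,
                     stats::rnorm(length(onsets), sd = params$cycle_jitter_sd))
    clamp <- min(3 * params$cycle_jitter_sd, 0.2 * period)
    onsets <- onsets + pmax(pmin(jit, clamp), -clamp)
    onsets[1] <- max(onsets[1], 0)
  }
  onsets <- onsets[onsets < duration]

  respiration <- params$resp_amp * sin(2 * pi * params$resp_rate / 60 * t)

  # heart-beat pulse train: Gaussian bump (sigma 35 ms, peak 140 ms after
  # cycle onset). The Gaussian's super-exponential spectral decay keeps its
  # >20 Hz residue far below the micrometer bursts, so the high-pass filter
  # separates beat from heart sounds cleanly; a finite-support pulse with C1
  # edges would leak burst-scale energy into the S1/S2 band.
  heartbeat <- numeric(n)
  hb_sigma <- 0.035
  hb_delay <- 0.14
  if (params$beat_amp > 0) {
    half <- 6 * hb_sigma # truncation point, < 2e-8 of the peak
    for (o in onsets) {
      ctr <- o + hb_delay
      i0 <- max(1L, floor((ctr - half) * rate) + 1L)
      i1 <- min(n, floor((ctr + half) * rate) + 1L)
      if (i0 > n) next
      tt <- t[i0:i1] - ctr
      heartbeat[i0:i1] <- heartbeat[i0:i1] +
        params$beat_amp * exp(-tt^2 / (2 * hb_sigma^2))
    }
  }

  s1_eff <- params$s1_amp * params$damping
  s2_eff <- params$s2_amp * params$damping
  s1 <- burst_train(t, onsets + params$s1_delay, s1_eff,
                    params$s1_freq, params$burst_decay)
  s2 <- burst_train(t, onsets + params$s2_delay, s2_eff,
                    params$s2_freq, params$burst_decay)

  labels <- truth_labels(onsets, params, duration,
                         any_burst = (s1_eff > 0 || s2_eff > 0))

  structure(list(
    samples = respiration + heartbeat + s1 + s2,
    rate = rate, d0 = d0, duration = duration,
    labels = labels, onsets = onsets,
    components = list(respiration = respiration, heartbeat = heartbeat,
                      s1 = s1, s2 = s2),
    burst_amps = c(s1 = s1_eff, s2 = s2_eff),
    params = params), class = "displacement_trace")
}

# Ground-truth labels from the burst envelope model. The noise window is the
# longest quiet interval of the cycle (after S2, before the next S1), shrunk
# by 20 ms margins.
truth_labels <- function(onsets, params, duration, any_burst) {
  empty <- data.frame(s1_start = numeric(0), s1_end = numeric(0),
                      s2_start = numeric(0), s2_end = numeric(0),
                      noise_start = numeric(0), noise_end = numeric(0))
  if (!any_burst || length(onsets) == 0L)
    return(segmentation_labels(empty, duration))
  tb <- burst_label_duration(params$burst_decay)
  rows <- lapply(seq_along(onsets), function(i) {
    o <- onsets[i]
    s1s <- o + params$s1_delay; s1e <- s1s + tb
    s2s <- o + params$s2_delay; s2e <- s2s + tb
    if (s2e > duration) return(NULL)
    nxt <- if (i < length(onsets)) onsets[i + 1] + params$s1_delay
           else duration
    ns <- s2e + 0.02
    ne <- min(nxt - 0.02, duration)
    if (ne - ns < 0.05) return(NULL)
    data.frame(s1_start = s1s, s1_end = s1e, s2_start = s2s, s2_end = s2e,
               noise_start = ns, noise_end = ne)
  })
  segmentation_labels(do.call(rbind, c(rows, list(empty))), duration)
}

#' @export
print.displacement_trace <- function(x, ...) {
  cat(sprintf("Chest-wall displacement trace: %.1f s at %g Hz (%d samples)\n",
              x$duration, x$rate, length(x$samples)))
  cat(sprintf("  standoff D0 = %.3g m, peak |Dp| = %.3g um, %d labeled cycles\n",
              x$d0, max(abs(x$samples)) * 1e6, n_cycles(x$labels)))
  invisible(x)
}

#' Attenuate only the S1/S2 burst component of a trace
#'
#' Models channel-specific damping (e.g. chest-band pressure on a contact
#' sensor) while keeping respiration, heart beat, cycle timing and labels
#' identical, so challenge-case channels share one underlying motion.
#'
#' @param trace A `displacement_trace`.
#' @param damping Multiplier in \[0,1\] applied to the burst component.
#' @return A new `displacement_trace`.
#' @export
damp_bursts <- function(trace, damping) {
  stopifnot(inherits(trace, "displacement_trace"))
  check_finite_scalar(damping, "damping", min = 0, max = 1)
  out <- trace
  out$components$s1 <- trace$components$s1 * damping
  out$components$s2 <- trace$components$s2 * damping
  out$burst_amps <- trace$burst_amps * damping
  out$samples <- with(out$components, respiration + heartbeat + s1 + s2)
  out
}

#' Simulate the chest-mounted accelerometer (seismocardiogram) channel
#'
#' The accelerometer senses skin acceleration: the discrete second derivative
#' of the displacement (central second difference scaled by rate^2), plus
#' white Gaussian sensor noise.
#'
#' @param trace A `displacement_trace`.
#' @param noise_accel Sensor-noise RMS in m/s^2 (default from the trace's
#'   simulation parameters).
#' @param seed Integer seed for the noise realization.
#' @return A `sensor_record` of kind `"accelerometer"` (m/s^2) at the trace
#'   rate.
#' @export
simulate_accelerometer <- function(trace,
                                   noise_accel = trace$params$noise_accel,
                                   seed = NULL) {
  stopifnot(inherits(trace, "displacement_trace"))
  check_finite_scalar(noise_accel, "noise_accel", min = 0)
  d <- trace$samples
  n <- length(d)
  if (n < 3L) stop("trace shorter than 3 samples", call. = FALSE)
  a <- numeric(n)
  a[2:(n - 1)] <- (d[3:n] - 2 * d[2:(n - 1)] + d[1:(n - 2)]) * trace$rate^2
  a[1] <- a[2]; a[n] <- a[n - 1]
  if (noise_accel > 0)
    a <- a + with_seed(seed, stats::rnorm(n, sd = noise_accel))
  sensor_record(a, trace$rate, kind = "accelerometer", units = "m/s^2")
}

#' Simulate the acoustic stethoscope (phonocardiogram) channel
#'
#' Output is the 20 Hz high-passed micro-vibration (in arbitrary units,
#' 1e6 a.u./m), plus a harmonic-overtone term at twice the burst centre
#' frequencies scaled by `hf_gain` (emulating the stethoscope's
#' high-frequency heart-sound content that the radar does not capture), plus
#' white sensor noise, plus optional band-limited background-sound
#' interference.
#'
#' @param trace A `displacement_trace`.
#' @param hf_gain Overtone gain (unitless, >= 0; 0 disables the overtone).
#' @param noise_stetho Sensor-noise RMS in arbitrary units.
#' @param background_level Background-sound interference RMS, arbitrary units.
#' @param seed Integer seed for the noise realizations.
#' @return A `sensor_record` of kind `"stethoscope"` at the trace rate.
#' @export
simulate_stethoscope <- function(trace, hf_gain = 0.3,
                                 noise_stetho = trace$params$noise_stetho,
                                 background_level = 0, seed = NULL) {
  stopifnot(inherits(trace, "displacement_trace"))
  check_finite_scalar(hf_gain, "hf_gain", min = 0)
  check_finite_scalar(noise_stetho, "noise_stetho", min = 0)
  check_finite_scalar(background_level, "background_level", min = 0)
  p <- trace$params
  n <- length(trace$samples)
  t <- (seq_len(n) - 1L) / trace$rate
  micro <- highpass_zero_phase(trace$samples, trace$rate, 20)
  overtone <- 0
  if (hf_gain > 0) {
    overtone <- burst_train(t, trace$onsets + p$s1_delay,
                            trace$burst_amps[["s1"]], 2 * p$s1_freq,
                            p$burst_decay) +
                burst_train(t, trace$onsets + p$s2_delay,
                            trace$burst_amps[["s2"]], 2 * p$s2_freq,
                            p$burst_decay)
  }
  x <- STETH_GAIN * (micro + hf_gain * overtone)
  if (noise_stetho > 0 || background_level > 0) {
    noise <- with_seed(seed, {
      ns <- if (noise_stetho > 0) stats::rnorm(n, sd = noise_stetho) else 0
      bg <- if (background_level > 0)
        background_level * highpass_zero_phase(stats::rnorm(n), trace$rate, 20)
      else 0
      ns + bg
    })
    x <- x + noise
  }
  sensor_record(x, trace$rate, kind = "stethoscope", units = "a.u.")
}
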
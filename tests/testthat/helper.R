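# Shared fixtures and small utilities for the suite. Scenario runs are
# cached per (preset, seed, duration) because several tests interrogate the
# same end-to-end result.

rms <- function(x) sqrt(mean(x^2))

quiet_params <- function(...) {
  # all motion components off unless specified; no cycle jitter
  cardiac_sim_params(resp_amp = 0, beat_amp = 0, s1_amp = 0, s2_amp = 0,
                     cycle_jitter_sd = 0, ...)
}

# displacement trace carrying an arbitrary waveform (for analytic-input
# tests of downstream operations)
waveform_trace <- function(samples, rate = 1000, d0 = 0.5) {
  tr <- simulate_displacement(quiet_params(), length(samples) / rate,
                              rate = rate, d0 = d0)
  tr$samples <- samples
  tr
}

.scenario_cache <- new.env(parent = emptyenv())
cached_scenario <- function(preset, seed = 1L, duration = 60) {
  key <- paste(preset, seed, duration, sep = "|")
  if (is.null(.scenario_cache[[key]]))
    .scenario_cache[[key]] <- run_scenario(preset, seed = seed,
                                           duration = duration)
  .scenario_cache[[key]]
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
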
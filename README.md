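# radarsteth

Contactless heart-sound recovery from millimetre-wave FMCW MIMO radar, with
the matching contact-sensor reference chains and evaluation metrics — as a
fully synthetic, testable R pipeline.

## The problem

The first and second heart sounds (S1, S2 — atrioventricular and semilunar
valve closures) shake the chest wall by only a few micrometres in the
20–75 Hz band. A 77 GHz frequency-modulated continuous-wave (FMCW) radar can
measure that motion without contact: the dechirped baseband of channel *n*
for a chest target at standoff D₀ + Dₚ(t) is

    sₙ(τ,t) = A·exp(j2π[α·τ_d(t)·τ + f_c·τ_d(t)])·exp(j2π(d₀/λ)(n−1)sinθ),
    τ_d(t) = 2(D₀ + Dₚ(t))/c

Beam steering with the vector wₙ = exp(j2π(d₀/λ)(n−1)sinθ) adds the N = 12
virtual TDM-MIMO channels coherently (a 10·log₁₀N ≈ 10.8 dB SNR gain); a
fast-time FFT forms the range profile with its peak at the beat frequency
f_b = α·τ_d; the unwrapped slow-time phase of the strongest bin is linear in
the skin vibration, φ(t) = 4π·Dₚ(t)/λ; and a zero-phase 20 Hz high-pass
removes respiration and the fundamental heart beat, leaving the heart-sound
waveform. The package implements this chain end to end, together with:

* a seeded chest-motion simulator (respiration + heart-beat pulse train +
  damped-sinusoid S1/S2 bursts, with ground-truth segment labels),
* raw-radar-cube synthesis (and a binary + JSON-sidecar container format),
* the accelerometer (seismocardiogram) chain: 20 Hz high-pass + 20-sample
  moving average,
* the stethoscope (phonocardiogram) chain: 20 Hz high-pass + polyphase
  resampling to the 1000 Hz radar time base,
* evaluation: Hamming STFT spectrograms (70-point window, 64 overlap),
  segmented SNR averaged over up to 40 cardiac cycles, automatic S1/S2
  segmentation, and the ICNIRP exposure worked example,
* an end-to-end scenario runner for six challenge cases (reference,
  loose fit, tight fit, thick clothing, opposite side, background sound).

See `vignettes/radar-heart-sounds.Rmd` for the model, the numerical choices
and their rationale.

## Worked example

```r
library(radarsteth)
r <- run_scenario("reference", seed = 1)   # 60 s at 60 bpm, all 3 channels
print(r)
```

```
Scenario 'reference' (seed 1, 40 cycles)
  radar          S1   13.7 dB   S2   11.0 dB
  stethoscope    S1   13.8 dB   S2   11.3 dB
  accelerometer  S1   15.2 dB   S2   10.4 dB
```

One shared chest motion is simulated; the radar cube is synthesized,
beamformed, range-processed and phase-demodulated; the two contact channels
are generated and filtered; and each channel's segmented SNR is computed
against the ground-truth labels — the ratio of mean S1 (or S2) window power
to mean noise-window power in dB, averaged over 40 cycles. Radar values near
11–14 dB are the regime a reference measurement of this kind reports.
Challenge presets act directionally:

```r
report_table(list(r, run_scenario("tight-fit", seed = 1)))
```

```
       case       channel s1_snr_db s2_snr_db
1 reference         radar 13.737028 10.981815
2 reference   stethoscope 13.839885 11.336217
3 reference accelerometer 15.172349 10.379346
4 tight-fit         radar 13.737028 10.981815
5 tight-fit   stethoscope  6.767359  4.830911
6 tight-fit accelerometer  7.935493  3.985843
```

Tight chest-band pressure damps the skin vibration under both contact
sensors (≈ 7 dB drop) while the contactless radar channel — whose input is
untouched by the band — is bit-identical at the same seed.

The lower-level API mirrors the processing chain:
`simulate_displacement()` → `synthesize_cube()` → `steering_vector()` /
`beamform()` → `range_profile()` → `select_strongest_bin()` →
`extract_phase()` → `highpass_heart_sound()`, plus `process_stethoscope()`,
`process_accelerometer()`, `stft_spectrogram()`, `segment_snr()`,
`auto_segment()`, `power_density()`.

A thin command-line front end with subcommands (`simulate`,
`process-radar`, `process-accel`, `process-stetho`, `analyze`,
`run-scenario`, `report`) ships as `inst/scripts/radarsteth.R`.

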
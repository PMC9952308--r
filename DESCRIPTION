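Package: radarsteth
Title: Contactless Heart-Sound Recovery from FMCW MIMO Radar
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates micrometer-scale chest-wall vibrations produced by the
    first and second heart sounds together with co-registered accelerometer
    (seismocardiogram) and stethoscope (phonocardiogram) channels, synthesizes
    the corresponding raw complex-baseband frequency-modulated continuous-wave
    (FMCW) multi-input multi-output (MIMO) radar data cube, and recovers the
    heart-sound waveform by beam steering, range processing, strongest-bin
    selection, phase demodulation and high-pass filtering. Includes the
    matching contact-sensor processing chains, short-time Fourier transform
    spectrograms, segmented signal-to-noise-ratio evaluation averaged over
    cardiac cycles, and an end-to-end scenario runner for challenge cases
    (loose/tight sensor fit, thick clothing, opposite-side placement,
    background sound).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
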
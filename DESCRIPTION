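Package: mwppg
Title: Synthetic Multi-Wavelength Photoplethysmography and Lightweight Anomaly Detection
Version: 0.1.0
Authors@R: person("mwppg", "developers", role = c("aut", "cre"), email = "mwppg@example.org")
Description: Tools for simulating multi-wavelength photoplethysmography (MW-PPG)
    recordings (green, red, near-infrared channels at 125 Hz) with labeled
    artifacts (motion, contact force, sensor dropout and clipping, ambient light,
    low temperature), channel-level time-series augmentation (shift, scale, warp,
    baseline drift, noise, dropout), zero-phase Butterworth low-pass filtering,
    overlapped windowing with weighted-vote labels, a compact data-aware feature
    set (peak statistics, spectral band power and slope, turning points, binned
    and wavelet entropy, median difference), information-gain feature ranking
    with random-forest recursive feature elimination and best-first wrapper
    search, and four lightweight anomaly detectors (decision tree, random
    forest, Gaussian-kernel support vector machine, reconstruction
    autoencoder) evaluated at channel level and sensor level across window
    sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
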
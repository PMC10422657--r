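# mwppg

Synthetic multi-wavelength photoplethysmography (MW-PPG) and lightweight
anomaly detection in R.

## The problem

Wearable PPG sensors increasingly acquire several wavelengths at once
(green 525 nm, red 631 nm, near-infrared 940 nm), one channel per
source–detector pair. Downstream estimates (heart rate, SpO₂, pulse-shape
analysis) are only as good as the signal windows they consume, so a cheap,
window-level artifact detector — runnable on the wearable itself — is a key
pre-processing stage. Artifacts come from gross motion, contact-force
changes (which depress the pulsatile AC/DC ratio), sensor faults (dropout,
ADC saturation) and the environment (ambient light, cold tissue).

`mwppg` is a self-contained, tested re-implementation of that pipeline for
people who want to study window-level MW-PPG artifact detection without
access to proprietary recordings:

1. **`signal_synth`** — a generator of clean 3-channel records at 125 Hz
   (systolic peak, dicrotic notch, diastolic bump per beat; respiration
   baseline; heart rate 91.6 ± 8.9 BPM, respiration 0.172 ± 0.08 Hz) plus
   six artifact injectors with exact per-sample ground-truth labels.
2. **`augmentation`** — the six channel-level operators
   (shift/scale/warp/drift/noise/dropout) used for dataset expansion and
   synthetic channel-wise anomalies.
3. **`windowing`** — zero-phase 5th-order Butterworth low-pass at 10 Hz,
   overlapped fixed-length windows, weighted-vote window labels
   (`Σ wᵢ·lᵢ ≥ m`, with `m = ⌈α·n⌉`, α = 0.2 by default) and 80/10/10
   train/val/test splitting.
4. **`features`** — a 10-feature "custom" set: number of peaks, peak
   (amplitude) variance, peak-width variance, mean PSD in an above-cardiac
   band, cardiac-to-high-frequency PSD slope, ± turning points, binned
   entropy, Ricker-wavelet entropy, median successive difference; assembled
   channel-level (10 attributes) or sensor-level (16 channel-wise
   attributes).
5. **`selection`** — information-gain ranking in bits
   (`IG = H(class) − H(class | attribute)`), channel aggregation,
   random-forest recursive feature elimination with a 2.5% F1 stop rule and
   best-first forward wrapper search.
6. **`detect_eval`** — four lightweight detectors implemented natively
   (CART decision tree with Gini, depth 15; random forest of 10 such trees,
   depth 10; Gaussian-kernel SVM, γ = 10⁻⁴, C = 1, trained by dual
   coordinate descent; a 4-layer reconstruction autoencoder with 5-neuron
   ReLU hidden layers thresholded on validation F1), swept across window
   sizes 2–10 s at channel level and sensor level.

## Worked example

```r
library(mwppg)

# 10 minutes of labeled synthetic MW-PPG in the default category mix
# (clean / motion / contact force / sensor / environment)
records <- synth_dataset(total_s = 600, seed = 42)
records <- lapply(records, lowpass_filter)

report <- run_experiment(records,
                         window_sizes = c(2, 6),
                         modes = c("channel", "sensor"),
                         detectors = c("random_forest", "autoencoder"),
                         paper_mode = TRUE, filter = FALSE, seed = 42)
print(report)
```

```
<mwppg_eval_report> feature set 'custom'
 window_s    mode      detector  accuracy        f1 n_test
        2 channel random_forest 0.9827586 0.8800000    174
        2 channel   autoencoder 0.9252874 0.6060606    174
        2  sensor random_forest 0.9827586 0.8888889     58
        2  sensor   autoencoder 0.8103448 0.4210526     58
        6 channel random_forest 1.0000000 1.0000000     57
        6 channel   autoencoder 1.0000000 1.0000000     57
        6  sensor random_forest 1.0000000 1.0000000     19
        6  sensor   autoencoder 1.0000000 1.0000000     19
```

Each row is one cell of the sweep: the test-split accuracy and F1 (anomaly
positive) of one detector at one window size in one detection mode. At this
small scale the 6 s cells saturate; the 2 s cells show the harder
short-window regime, and `report$gains` tabulates the sensor-minus-channel
differences per detector. A 30-minute run (see
`tests/testthat/test-acceptance.R`) gives 6 s channel-level F1 ≈ 0.92 (RF)
and ≈ 0.89 (autoencoder).

A command-line interface covering the same pipeline is installed at
`inst/cli/mwppg` (`synth`, `augment`, `windows`, `extract`, `experiment`
subcommands).

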
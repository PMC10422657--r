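---
title: "Methods: synthetic MW-PPG and lightweight anomaly detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic MW-PPG and lightweight anomaly detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwppg)
```

This vignette documents the models, numerical choices and open design
decisions behind `mwppg`, and states precisely what the synthetic-data
generator does and does not emulate — hence what a green test does and does
not establish.

## 1. The signal model

A reflective PPG channel measures light intensity modulated by pulsatile
blood volume. We model the measured intensity of channel $c$ as

$$x_c(t) = \mathrm{DC}_c + \mathrm{AC}_c \, p(t)
          + r\,\mathrm{AC}_c \sin(2\pi f_{\mathrm{resp}} t + \varphi)
          + \varepsilon_c(t),$$

where $p(t)$ is a unit-amplitude cardiac pulse train, $f_{\mathrm{resp}}$
the respiration frequency, $r$ the relative respiratory baseline amplitude
(default 0.2) and $\varepsilon_c$ white sensor noise (sd 1% of
$\mathrm{AC}_c$). Per beat, $p(t)$ is a sum of two Gaussian lobes — a
systolic pulse (unit peak) and a diastolic bump (relative amplitude 0.35)
— separated by a dicrotic notch. The beat morphology is specified only
qualitatively in the PPG literature; any template producing the three
landmarks is acceptable, and all template parameters are exposed in
`synth_config()`.

Numerical choices that matter:

* **Lobe widths and notch delay scale with the beat period.** The
  configured systolic-to-diastolic delay (0.25 s) is referenced to a 75 BPM
  (0.8 s) beat and scaled proportionally with the actual period. With a
  *fixed* delay in seconds, a fast heart (≳ 110 BPM) puts the diastolic
  bump at half the cycle and the second harmonic overtakes the fundamental
  in the spectrum; proportional scaling keeps the harmonic structure
  heart-rate invariant, so the Welch spectral peak of a clean record sits
  at the cardiac frequency for every draw (a tested invariant, ±0.2 Hz).
* **Rates.** Per-record heart rate is drawn from
  $\mathcal N(91.6, 8.9^2)$ BPM (truncated to 30–220), respiration from
  $\mathcal N(0.172, 0.08^2)$ Hz (truncated below at 0.05) — the
  population statistics of the finger-clip recording sessions the package
  emulates. Beat-to-beat intervals carry 3% coefficient-of-variation
  jitter (configurable); this value is a conventional resting-HRV
  magnitude, not a measured one.
* **Channel contrasts.** Green has the largest relative AC modulation
  (5% of DC), red the smallest (1%), infrared intermediate (2%) —
  the qualitative wavelength ordering of reflective PPG; the exact ratios
  are free parameters with no measured counterpart.
* **Quantization** to the 18-bit ADC grid is available but off by default
  so float pipelines remain exact; the implied full scale
  ($2^{18}-1$) is used by the clipping injector.

## 2. Artifact injectors and the label contract

Six injectors modify a record inside an episode window on a channel mask,
and set per-sample labels **for exactly the samples whose values changed**
(`labeled set == modified set` is asserted by diffing input and output in
the tests — the strongest invariant in the package). Motion and ambient
light affect all masked channels simultaneously with independent
per-channel gains; sensor faults are single-channel (green by default).

* *motion*: multiplicative $\exp(0.1\,m\,g_c\,z(t))$ with $z$ low-pass
  filtered (8 Hz) unit-variance white noise — the multiplicative structure
  follows the attenuation decomposition of reflective PPG; the stochastic
  process is our choice.
* *contact force* / *low temperature*: the pulsatile component is shrunk
  toward a 1 s moving-average baseline by $1-m$ (AC/DC reduction); low
  temperature additionally droops DC by 2%. The attenuation curve is a
  free parameter (the source describing it is not available).
* *dropout*: Bernoulli($p$) samples replaced by a constant (0 or
  hold-last-value).
* *clipping*: pure saturation $\min(x, \text{level})$ — deliberately
  offset-free so that re-applying the same level is exactly idempotent (a
  tested invariant); visible clipping in generated datasets comes from
  setting the level below the systolic excursion.
* *ambient light*: additive offset plus a slow (0.05–0.2 Hz) sinusoidal
  drift.

`synth_dataset()` reads a category as a *recording condition*, not a duty
cycle: an artifact-category record is a clean background with 1–3 episodes
covering roughly 30–60% of the record, with magnitudes drawn once from
fixed moderate ranges (motion 0.8–1.5, contact 0.6–0.9, dropout
probability 0.4–0.8). The default composition is proportional to the
measured category durations of the emulated dataset
(clean 150 / motion 50 / contact 30 / sensor 10 / environment 20 minutes).

## 3. Augmentation

The six channel-level operators return series of the input length always
(shift wraps circularly; warp resamples a monotone piecewise-linear time
map back to the original grid) together with a modified-sample mask. Which
operators *label* their effect as anomalous is not specified by the
emulated methodology, which uses augmentation both for natural variation
and for synthetic channel anomalies; our boundary: dropout always labels,
shift/scale/warp/noise/drift default to clean and are switchable per spec
(`label_as_anomaly`). For `shift` the mask is the wrapped-around region —
the one place where "modified" is defined structurally rather than by
value comparison, since a circular shift changes almost every sample.

## 4. Filtering: why not a bilinear IIR

Pre-processing uses a 5th-order Butterworth low-pass at 10 Hz, zero-phase.
We realize it in the frequency domain with the exact analog magnitude
$|H(f)| = (1 + (f/f_c)^{2n})^{-1/2}$ applied to the reflection-padded DFT
(twice, matching forward–backward filtering). A time-domain digital
Butterworth obtained by the bilinear transform warps frequencies near
Nyquist: at $f_s = 125$ Hz it attenuates 30 Hz by ≈ 56 dB instead of the
analytic 47.7 dB. Offline windowed pre-processing needs no causal
recursion, so the frequency-sampled realization — which matches the
analytic response exactly and is what the tests check against — is the
faithful choice.

## 5. Windowing and the vote label

Windows of $W$ samples advance by $\mathrm{round}(W(1-\text{overlap}))$;
trailing partials are dropped, giving
$\lfloor (N-W)/\text{step}\rfloor + 1$ windows. A window is anomalous iff
$\sum_i w_i l_i \ge m$ over its per-sample labels; we read the weights as
*per-sample* (the printed description of the vote is ambiguous between
per-sample and per-window weights; per-sample is the only reading under
which the sum is well-typed). Defaults $w_i = 1$, $m = \lceil 0.2\,n
\rceil$: the anomalous-fraction threshold $\alpha = 0.2$ is our choice —
the emulated methodology never prints $m$ — and makes the required count
grow with window size, as intended. The sensor-level label is the OR of
the channel labels.

Splitting defaults to whole-record grouping (50%-overlapped windows never
straddle the train/test boundary); `paper_mode = TRUE` splits individual
windows, reproducing the emulated protocol, and is what the acceptance
pipeline uses.

## 6. Features

The computable "custom" set has 10 features (16 sensor-level attributes
after the published per-channel assignments). Numerical choices:

* Peak detection: strict local maxima, topographic prominence
  ≥ 0.1 × window range, minimum distance = one beat at 180 BPM, widths at
  half prominence — all defaults the emulated text omits.
* Variances are unbiased ($n-1$).
* Welch: 2 s Hann segments, 50% overlap, density scaling; windows shorter
  than a segment fall back to one full-window periodogram.
* `PSD_mean`: the literal "50–200 Hz" band is unattainable at
  $f_s = 125$ Hz (Nyquist 62.5); we interpret it as DFT **bin indices**
  50–200 of a 512-point spectrum, i.e. ≈ 12.2–48.8 Hz — an above-cardiac
  noise band; configurable.
* `frequency_bands_slope`: (mean dB in 1–2 Hz − mean dB in 3–10 Hz) per Hz
  of band-center gap, oriented so clean pulsatile windows score higher
  (a tested separation property).
* `wavelet_entropy` demeans the window first: the sampled Ricker kernel is
  only approximately zero-sum, so a DC offset would otherwise leak
  scale-dependent edge energy and break the offset-invariance property
  that all ten features satisfy.
* Degenerate constant windows yield 0 for both entropies and
  `median_diff`.

The TSFEL-style and tsfresh-style retained sets are encoded as
machine-readable specifications (names and channel assignments, used by the
conformance tests) but their feature functions are intentionally not
implemented.

Attributes are z-scored with train-split statistics; near-constant columns
(sd at float-noise level) are centered only. Non-finite values are imputed
to the train median before scaling.

## 7. Selection

Information gain uses equal-frequency discretization (10 bins; attributes
with ≤ `bins` distinct values are used as-is so discrete inputs are scored
exactly against the contingency-table oracle) and base-2 logarithms — the
entropy base is unspecified in the emulated text, and the equal-frequency
choice is a deliberate, documented divergence from WEKA's MDL
discretization (simpler and deterministic). RFE removes the
lowest-information-gain attribute (lexical tie-break), re-evaluating a
10-tree random-forest wrapper by stratified 5-fold CV with pooled
predictions, and stops before the first removal that would drop F1 more
than 2.5% below the full set — so the retained subset's F1 is within
tolerance *by construction*, and the test asserts the construction.
Best-first is a forward greedy wrapper with patience 5, returning the best
subset seen (so a perfectly correlated duplicate attribute can be
*visited* but never *retained*).

## 8. Detectors

No tree, SVM or neural-network package is assumed: all four detectors are
native implementations.

* **CART / random forest**: exact greedy Gini splits over sorted value
  midpoints, `minsplit` 20 / `minbucket` 7; the forest bootstraps rows and
  samples $\lfloor\sqrt p\rfloor$ features per split, 10 trees, depth 10;
  the single tree uses depth 15 and all features.
* **SVM**: RBF kernel ($\gamma = 10^{-4}$, $C = 1$), bias absorbed into
  $K + 1$, trained by dual coordinate descent over a random permutation
  per epoch with a projected-gradient stop (tolerance $10^{-3}$, cap 400
  epochs). A fixed small cyclic budget converges too slowly in the bias
  direction when the kernel is near-constant (tiny $\gamma$), which
  motivated the permuted sweeps and the explicit stop. Prediction is by
  decision-function sign; the reported probability-estimate switch of the
  emulated setup has no effect on binary window labels and no Platt
  scaling is fitted. Training sets beyond 6000 rows are subsampled
  (seeded) to bound the kernel matrix.
* **Autoencoder**: $p \to 5 \to 5 \to 5 \to p$, ReLU hidden layers,
  linear output, full-batch Adam (lr 0.01) on the MSE of the
  normal-labeled training rows only; the anomaly threshold on per-row
  reconstruction MSE maximizes F1 on the validation split (falling back to
  the 95th percentile of normal training errors). The epoch budget
  defaults to **1000**, not the few hundred one might guess: measured on
  the 30-minute acceptance dataset, the reconstruction loss at 200 epochs
  (0.018) is still far from its plateau (0.010, reached at ~500–1000), and
  stopping early miscalibrates the threshold. This protocol (normal-only
  training, validation-tuned threshold) is itself a design decision — the
  emulated description is architectural only.

Channel-level evaluation pools all channels' rows into one model; F1
always treats the anomaly class as positive and is 0 when positives exist
but none are predicted.

## 9. What the generator does not emulate — and a known red test

The synthetic world reproduces the *statistical structure* of the emulated
dataset (rates, category proportions, channel layout, artifact taxonomy)
with exact ground-truth labels. It does **not** reproduce:

* manual labels of borderline windows — synthetic labels flag exactly the
  modified samples, so there is no label noise and no "visually ambiguous"
  class boundary;
* subthreshold artifacts affecting channels to varying extents — our
  motion/contact/environment episodes are strong and simultaneous across
  channels by construction;
* inter-subject variability, sensor-geometry effects, and the augmented
  11-hour expansion of the original study.

Consequently channel-level detection on synthetic data is close to its
ceiling already at 2 s windows (F1 ≈ 0.93 vs ≈ 0.82 reported on real
data), and the documented *sensor-level fusion gain at small windows* does
not materialize: across dataset seeds, sensor-level F1 ≥ channel-level F1
holds for between 0 and 3 of the 4 detectors, not reliably ≥ 3. The
acceptance test for that directional property is therefore a **known
failure** on synthetic ground truth and is deliberately left failing
rather than weakened; the mechanism (saturated channel-level performance
plus a 3× larger channel-level training set) is an honest property of the
stated synthetic world, not an implementation defect. A green run of the
remaining suite establishes pipeline correctness (oracle equivalences,
closed forms, label bookkeeping, split hygiene, determinism) and
end-to-end recoverability (RF and autoencoder F1 ≥ 0.85 at 6 s
channel-level windows) — it does not establish that the fusion advantage
of real MW-PPG recordings transfers to this synthetic world.

## 10. Reproducibility

Every stochastic operation (generation, injection, augmentation, splits,
bootstraps, weight initialization, permuted SVM sweeps) runs under
`with_seed()`, which derives child seeds below $2^{31}$ and restores the
caller's RNG state; identical (input, seed) pairs are bit-identical, and
the full experiment sweep is asserted deterministic in the tests.
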
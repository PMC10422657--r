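#' Generate a clean (artifact-free) MW-PPG record
#'
#' Simulates the pulsatile attenuation of a multi-wavelength reflective PPG
#' sensor: per beat, a primary (systolic) Gaussian lobe followed by a smaller
#' diastolic bump separated by a dicrotic notch; beat-to-beat intervals are
#' drawn around `60 / heart rate` with a small jitter; a slow additive
#' baseline at the respiration frequency modulates each channel; a small
#' amount of white sensor noise is added. All per-sample labels are 0 and the
#' output is bit-reproducible for a fixed seed.
#'
#' @param config an [synth_config()] object.
#' @param keep_components also store the noise-free normalized cardiac and
#'   respiratory components in `meta$components` (useful for oracles).
#' @return an `mwppg_record` with `round(duration * sample_rate)` samples per
#'   channel.
#' @export
generate_clean_record <- function(config = synth_config(),
                                  keep_components = FALSE) {
  abort_if(!inherits(config, "mwppg_synth_config"),
           "config must be an mwppg_synth_config")
  fs <- config$sample_rate
  n <- round(config$duration * fs)
  chs <- names(config$ac)
  if (n == 0L) {
    samples <- stats::setNames(lapply(chs, function(ch) numeric(0)), chs)
    return(multichannel_record(samples, sample_rate = fs,
                               meta = list(seed = config$seed,
                                           category = "clean")))
  }
  t <- (seq_len(n) - 1) / fs

  with_seed(config$seed, {
    hr <- config$heart_rate_mean
    if (config$heart_rate_sd > 0) {
      hr <- stats::rnorm(1, config$heart_rate_mean, config$heart_rate_sd)
      hr <- min(max(hr, 30), 220)
    }
    resp_f <- config$respiration_mean
    if (config$respiration_sd > 0) {
      resp_f <- max(stats::rnorm(1, config$respiration_mean,
                                 config$respiration_sd), 0.05)
    }
    period <- 60 / hr

    # Beat onset times: intervals jittered with coefficient of variation
    # hrv_cv, truncated at +/- 3 sd so intervals stay positive.
    n_beats <- ceiling(config$duration / period) + 3L
    jitter <- pmin(pmax(stats::rnorm(n_beats), -3), 3)
    intervals <- period * (1 + config$hrv_cv * jitter)
    onsets <- cumsum(c(stats::runif(1, -period, 0), intervals[-1]))
    onsets <- onsets[onsets < config$duration + period]

    cardiac <- cardiac_pulse_train(t, onsets, period,
                                   config$dicrotic_rel_amp,
                                   config$dicrotic_delay_s)
    resp_phase <- stats::runif(1, 0, 2 * pi)
    resp <- sin(2 * pi * resp_f * t + resp_phase)

    samples <- stats::setNames(vector("list", length(chs)), chs)
    for (ch in chs) {
      x <- config$dc[[ch]] +
        config$ac[[ch]] * cardiac +
        config$resp_rel * config$ac[[ch]] * resp +
        stats::rnorm(n, 0, config$noise_rel * config$ac[[ch]])
      if (config$quantize) {
        x <- pmin(pmax(round(x), 0), adc_full_scale(config))
      }
      samples[[ch]] <- x
    }

    meta <- list(seed = config$seed, category = "clean",
                 heart_rate_bpm = hr, respiration_hz = resp_f,
                 config = config, artifacts = list())
    if (keep_components) {
      meta$components <- list(cardiac = cardiac, respiration = resp,
                              beat_onsets = onsets)
    }
    multichannel_record(samples, sample_rate = fs, meta = meta)
  })
}

# Sum of per-beat templates on the time grid `t`. Each beat is a systolic
# Gaussian (peak normalized to 1) plus a delayed diastolic Gaussian of
# relative amplitude `dia_amp`. Widths and the systolic-to-diastolic delay
# scale with the beat period (the configured delay is referenced to a
# 75 BPM, 0.8 s beat), so the morphology - and hence the harmonic structure
# - is heart-rate invariant and the dicrotic notch survives at any rate.
cardiac_pulse_train <- function(t, onsets, period, dia_amp, dia_delay) {
  x <- numeric(length(t))
  w_sys <- 0.095 * period
  w_dia <- 0.14 * period
  t_sys <- 0.20 * period
  dia_delay <- dia_delay * period / 0.8
  dt <- if (length(t) > 1) t[2] - t[1] else 1
  for (on in onsets) {
    lo <- max(1L, floor((on - 0.25 * period) / dt) + 1L)
    hi <- min(length(t), ceiling((on + 1.3 * period) / dt) + 1L)
    if (lo > hi) next
    tt <- t[lo:hi] - on
    x[lo:hi] <- x[lo:hi] +
      exp(-((tt - t_sys)^2) / (2 * w_sys^2)) +
      dia_amp * exp(-((tt - t_sys - dia_delay)^2) / (2 * w_dia^2))
  }
  x
}

#' Welch power spectral density estimate
#'
#' Hann-windowed, mean-detrended, overlapped-segment periodogram average
#' (density scaling, one-sided). Used by the spectral features and by the
#' generator-fidelity checks.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples (default `min(length(x), 2*fs)`);
#'   shorter inputs fall back to a single full-length periodogram.
#' @param overlap fractional segment overlap (default 0.5).
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, nperseg = NULL, overlap = 0.5) {
  n <- length(x)
  abort_if(n < 2, "welch_psd needs at least 2 samples")
  nperseg <- min(n, round(nperseg %||% (2 * fs)))
  step <- max(1L, round(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  scale <- fs * sum(win^2)
  nf <- nperseg %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    p <- Mod(stats::fft(seg))^2 / scale
    p <- p[seq_len(nf)]
    # one-sided: double everything except DC (and Nyquist when present)
    dbl <- rep(2, nf)
    dbl[1L] <- 1
    if (nperseg %% 2 == 0) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (seq_len(nf) - 1) * fs / nperseg, psd = acc / length(starts))
}
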
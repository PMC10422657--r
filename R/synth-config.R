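#' Configuration for the synthetic MW-PPG generator
#'
#' Defaults emulate the statistical structure of a finger-clip reflective
#' MW-PPG recording session: three channels (green/red/infrared) sampled at
#' 125 Hz with an 18-bit converter, mean heart rate 91.6 +/- 8.9 BPM and
#' respiration 0.172 +/- 0.08 Hz. The cardiac waveform per beat is a sum of
#' two Gaussian lobes (systolic pulse plus a smaller, delayed diastolic bump)
#' separated by a dicrotic notch; a slow additive baseline at the respiration
#' frequency modulates each channel.
#'
#' @param sample_rate sampling rate in Hz (default 125).
#' @param duration record duration in seconds.
#' @param heart_rate_mean,heart_rate_sd population mean/sd of the per-record
#'   heart rate in BPM (defaults 91.6 / 8.9). `sd = 0` fixes the rate.
#' @param respiration_mean,respiration_sd per-record respiration frequency in
#'   Hz (defaults 0.172 / 0.08; draws truncated below at 0.05 Hz).
#' @param hrv_cv coefficient of variation of the per-beat interval jitter
#'   (default 0.03, i.e. 3%).
#' @param ac named per-channel AC amplitude (pulsatile swing) in intensity
#'   units. The green channel carries the largest relative modulation and red
#'   the smallest, matching the wavelength-dependent pulsatile contrast of
#'   reflective PPG.
#' @param dc named per-channel DC offset (static tissue level).
#' @param resp_rel amplitude of the respiratory baseline relative to the
#'   channel AC amplitude (default 0.2).
#' @param dicrotic_rel_amp diastolic-bump amplitude relative to the systolic
#'   peak (default 0.35, dimensionless).
#' @param dicrotic_delay_s systolic-to-diastolic delay in seconds for a
#'   reference 75 BPM (0.8 s) beat, scaled proportionally with the actual
#'   beat period (default 0.25, i.e. ~31% of the cycle).
#' @param noise_rel standard deviation of additive sensor noise relative to
#'   the channel AC amplitude (default 0.01).
#' @param adc_bits converter resolution; the implied full-scale clip level is
#'   `2^adc_bits - 1` (default 18).
#' @param quantize quantize outputs to integer ADC codes (default `FALSE`, so
#'   float pipelines remain exact).
#' @param seed integer seed for reproducible generation.
#' @return an object of class `mwppg_synth_config`.
#' @export
synth_config <- function(sample_rate = 125,
                         duration = 60,
                         heart_rate_mean = 91.6,
                         heart_rate_sd = 8.9,
                         respiration_mean = 0.172,
                         respiration_sd = 0.08,
                         hrv_cv = 0.03,
                         ac = c(green = 6000, red = 1800, ir = 3000),
                         dc = c(green = 120000, red = 180000, ir = 150000),
                         resp_rel = 0.2,
                         dicrotic_rel_amp = 0.35,
                         dicrotic_delay_s = 0.25,
                         noise_rel = 0.01,
                         adc_bits = 18,
                         quantize = FALSE,
                         seed = NULL) {
  abort_if(!is.numeric(sample_rate) || sample_rate <= 0,
           "invalid config: sample_rate must be > 0")
  abort_if(!is.numeric(duration) || duration < 0,
           "invalid config: duration must be >= 0")
  abort_if(heart_rate_mean <= 0 || respiration_mean <= 0,
           "invalid config: rate means must be positive")
  abort_if(!identical(names(ac), names(dc)) || is.null(names(ac)),
           "invalid config: ac and dc must be named alike")
  abort_if(any(ac >= dc), "invalid config: AC amplitude must be < DC offset")
  structure(list(sample_rate = sample_rate, duration = duration,
                 heart_rate_mean = heart_rate_mean,
                 heart_rate_sd = heart_rate_sd,
                 respiration_mean = respiration_mean,
                 respiration_sd = respiration_sd,
                 hrv_cv = hrv_cv, ac = ac, dc = dc, resp_rel = resp_rel,
                 dicrotic_rel_amp = dicrotic_rel_amp,
                 dicrotic_delay_s = dicrotic_delay_s,
                 noise_rel = noise_rel, adc_bits = adc_bits,
                 quantize = quantize, seed = seed),
            class = "mwppg_synth_config")
}

#' ADC full-scale level implied by a generator configuration
#' @param config an `mwppg_synth_config`.
#' @return numeric full-scale code (`2^adc_bits - 1`).
#' @export
adc_full_scale <- function(config) 2^config$adc_bits - 1
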
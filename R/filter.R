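#' Analytic Butterworth low-pass magnitude response
#'
#' `|H(f)| = 1 / sqrt(1 + (f / cutoff)^(2 * order))` — unit DC gain, -3 dB at
#' the cutoff, monotone roll-off of `20 * order` dB/decade.
#'
#' @param f frequency (Hz), vectorized.
#' @param cutoff cutoff frequency in Hz.
#' @param order filter order.
#' @return magnitude gain(s) in `[0, 1]`.
#' @export
butter_gain <- function(f, cutoff, order) {
  1 / sqrt(1 + (f / cutoff)^(2 * order))
}

#' Zero-phase Butterworth low-pass filtering of a vector
#'
#' Filters in the frequency domain with the exact analog Butterworth
#' magnitude (see [butter_gain()]), applied `passes` times; `passes = 2`
#' matches the magnitude of forward-backward (filtfilt-style) filtering.
#' Because the applied gain is real, the phase response is exactly zero for
#' any number of passes. The input is reflection-padded (up to 3 s per side)
#' to suppress circular edge effects. Offline pre-processing does not need a
#' causal recursion, and this realization is free of the bilinear-transform
#' frequency warping that a time-domain digital Butterworth exhibits near
#' Nyquist.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz (must be below Nyquist).
#' @param order filter order (default 5).
#' @param passes number of magnitude applications (default 2, zero-phase
#'   two-pass equivalent).
#' @return filtered numeric vector, same length as `x`.
#' @export
butter_filter <- function(x, fs, cutoff, order = 5, passes = 2) {
  abort_if(cutoff >= fs / 2, "cutoff must be below the Nyquist frequency")
  n <- length(x)
  if (n < 3) return(x)
  pad <- min(n - 1L, round(3 * fs))
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  m <- length(xp)
  f <- (seq_len(m) - 1) * fs / m
  f <- pmin(f, fs - f)  # fold to physical frequency of each DFT bin
  g <- butter_gain(f, cutoff, order)^passes
  y <- Re(stats::fft(stats::fft(xp) * g, inverse = TRUE)) / m
  y[pad + seq_len(n)]
}

#' Low-pass filter every channel of a record
#'
#' Applies zero-phase Butterworth low-pass filtering ([butter_filter()],
#' two-pass magnitude) to each channel; labels are untouched. Defaults match
#' the pre-processing used for PPG artifact labeling: order 5, cutoff 10 Hz.
#'
#' @param record an `mwppg_record`.
#' @param order filter order (default 5).
#' @param cutoff cutoff frequency in Hz (default 10; must be below Nyquist).
#' @return the filtered `mwppg_record`.
#' @export
lowpass_filter <- function(record, order = 5, cutoff = 10) {
  abort_if(cutoff >= record$sample_rate / 2,
           "cutoff must be below the Nyquist frequency")
  out <- record
  for (ch in channel_names(record)) {
    out$samples[[ch]] <- butter_filter(record$samples[[ch]],
                                       record$sample_rate, cutoff, order,
                                       passes = 2)
  }
  out$meta$filtered <- list(order = order, cutoff = cutoff)
  out
}
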
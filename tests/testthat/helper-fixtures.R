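# Shared fixture builders; everything is generated in code at test time.

# Small fast generator config: fixed heart rate, no sensor noise unless asked.
quiet_config <- function(duration = 10, hr = 90, seed = 1, ...) {
  synth_config(duration = duration, heart_rate_mean = hr, heart_rate_sd = 0,
               respiration_sd = 0, noise_rel = 0, seed = seed, ...)
}

# A record with a known blocky label pattern, for windowing tests.
labeled_record <- function(n = 1250, fs = 125, anomalous = integer(0)) {
  lab <- integer(n)
  lab[anomalous] <- 1L
  multichannel_record(
    samples = list(green = sin(2 * pi * 1.5 * (0:(n - 1)) / fs),
                   red = cos(2 * pi * 1.5 * (0:(n - 1)) / fs),
                   ir = rep(1, n)),
    labels = list(green = lab, red = integer(n), ir = integer(n)),
    sample_rate = fs)
}

# Two well-separated Gaussian clusters in feature space, as an
# mwppg_features object (for detector tests).
cluster_features <- function(n = 200, p = 4, sep = 4, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * p), n, p) + sep * y
  colnames(x) <- paste0("f", seq_len(p))
  structure(list(x = x, labels = y, split = NULL, mode = "channel",
                 spec = feature_set("custom"),
                 row_info = data.frame(record_id = "fix",
                                       start_sample = seq_len(n),
                                       channel = "green"),
                 standardized = TRUE),
            class = "mwppg_features")
}

# Amplitude of a (nearly) sinusoidal vector measured over its interior,
# robust to edge transients: peak absolute value over the central span.
interior_amplitude <- function(x, trim = 0.2) {
  n <- length(x)
  i <- seq(floor(n * trim), ceiling(n * (1 - trim)))
  max(abs(x[i]))
}
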
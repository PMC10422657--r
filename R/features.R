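CUSTOM_FEATURES <- c("num_of_peaks", "peak_var", "peak_width_var",
                     "PSD_mean", "frequency_bands_slope",
                     "neg_turning_points", "pos_turning_points",
                     "binned_entropy", "wavelet_entropy", "median_diff")

#' Data-aware (proposed) window features
#'
#' Five features tuned to pulsatile PPG windows:
#' * `num_of_peaks` — pulse-peak count from [detect_peaks()].
#' * `peak_var` — unbiased sample variance of the peak amplitudes (0 when
#'   fewer than 2 peaks); noise perturbs peak amplitudes and inflates it.
#' * `peak_width_var` — unbiased variance of the half-prominence peak widths
#'   in seconds (0 when fewer than 2 peaks).
#' * `PSD_mean` — mean Welch power density over an above-cardiac noise band.
#'   The band defaults to DFT bin indices 50-200 of a 512-point spectrum,
#'   i.e. `c(50, 200) * fs / 512` (about 12.2-48.8 Hz at 125 Hz);
#'   configurable via `psd_band` (Hz).
#' * `frequency_bands_slope` — (mean dB power in the cardiac band 1-2 Hz
#'   minus mean dB power in the high band 3-10 Hz) divided by the band-center
#'   gap in Hz, oriented so clean pulsatile windows score higher.
#'
#' Welch settings: 2 s Hann segments with 50% overlap (a window shorter than
#' one segment falls back to a single full-window periodogram).
#'
#' @param window numeric vector (one channel, one window; at least 2 s for
#'   meaningful spectral terms).
#' @param fs sampling rate in Hz.
#' @param psd_band high band for `PSD_mean` in Hz (default
#'   `c(50, 200) * fs / 512`).
#' @param low_band,high_band slope bands in Hz (defaults `c(1, 2)` and
#'   `c(3, 10)`).
#' @param hr_max,prominence_frac peak-detector settings, see
#'   [detect_peaks()].
#' @return named numeric vector of the five features.
#' @export
proposed_features <- function(window, fs, psd_band = c(50, 200) * fs / 512,
                              low_band = c(1, 2), high_band = c(3, 10),
                              hr_max = 180, prominence_frac = 0.1) {
  pk <- detect_peaks(window, fs, hr_max, prominence_frac)
  peak_var <- if (length(pk$amplitude) >= 2) stats::var(pk$amplitude) else 0
  peak_width_var <- if (length(pk$width_s) >= 2) stats::var(pk$width_s) else 0
  sp <- welch_psd(window, fs)
  p_db <- 10 * log10(pmax(sp$psd, .Machine$double.xmin))
  in_band <- function(band) sp$freq >= band[1] & sp$freq <= band[2]
  psd_mean <- mean(sp$psd[in_band(psd_band)])
  lo <- in_band(low_band)
  hi <- in_band(high_band)
  slope <- if (any(lo) && any(hi)) {
    (mean(p_db[lo]) - mean(p_db[hi])) /
      (mean(high_band) - mean(low_band))
  } else 0
  c(num_of_peaks = length(pk$index), peak_var = peak_var,
    peak_width_var = peak_width_var, PSD_mean = psd_mean,
    frequency_bands_slope = slope)
}

#' Library-style window features of the custom set
#'
#' The five retained off-the-shelf features:
#' * `pos_turning_points` / `neg_turning_points` — counts of first-difference
#'   sign changes from + to - (local maxima) and - to + (local minima); runs
#'   of equal samples are compressed first.
#' * `binned_entropy` — Shannon entropy (natural log) of the normalized
#'   histogram over `bins` equal-width bins spanning `[min, max]`
#'   (default 10).
#' * `wavelet_entropy` — Shannon entropy (natural log) of the normalized
#'   energy distribution across continuous-wavelet (Ricker/Mexican-hat)
#'   scales 1..9.
#' * `median_diff` — median of successive differences.
#'
#' Degenerate constant windows yield 0 for the entropies and `median_diff`.
#'
#' @param window numeric vector of length >= 3.
#' @param bins histogram bin count for `binned_entropy` (default 10).
#' @param scales Ricker wavelet scales (default `1:9`).
#' @return named numeric vector of the five features.
#' @export
library_features <- function(window, bins = 10, scales = 1:9) {
  abort_if(length(window) < 3, "window must have length >= 3")
  s <- sign(diff(window))
  s <- s[s != 0]
  flips <- if (length(s) >= 2) diff(s) else numeric(0)
  pos_tp <- sum(flips == -2)  # + to - : local maximum
  neg_tp <- sum(flips == 2)   # - to + : local minimum
  c(neg_turning_points = neg_tp, pos_turning_points = pos_tp,
    binned_entropy = binned_entropy(window, bins),
    wavelet_entropy = wavelet_entropy(window, scales),
    median_diff = if (length(window) >= 2) stats::median(diff(window)) else 0)
}

#' @rdname library_features
#' @export
binned_entropy <- function(window, bins = 10) {
  rng <- range(window)
  if (rng[1] == rng[2]) return(0)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  idx <- findInterval(window, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  p <- tabulate(idx, nbins = bins) / length(window)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' @rdname library_features
#' @export
wavelet_entropy <- function(window, scales = 1:9) {
  # demean first: the sampled Ricker kernel is only approximately zero-sum,
  # so a DC offset would otherwise leak scale-dependent edge energy
  window <- window - mean(window)
  energies <- vapply(scales, function(a) {
    sum(cwt_ricker_row(window, a)^2)
  }, numeric(1))
  tot <- sum(energies)
  if (!is.finite(tot) || tot <= 0) return(0)
  p <- energies / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

# One row of a Ricker (Mexican-hat) continuous wavelet transform:
# same-length convolution of the window with the scale-`a` wavelet.
cwt_ricker_row <- function(x, a) {
  m <- min(10L * a, length(x))
  t <- seq_len(m) - (m + 1) / 2
  A <- 2 / (sqrt(3 * a) * pi^0.25)
  psi <- A * (1 - (t / a)^2) * exp(-t^2 / (2 * a^2))
  full <- stats::convolve(x, rev(psi), type = "open")
  off <- (m - 1L) %/% 2
  full[(1L + off):(off + length(x))]
}

#' Built-in feature-set specifications
#'
#' Returns a feature-set specification: the ordered feature names with their
#' per-channel assignments for sensor-level mode (ch1 = green, ch2 = red,
#' ch3 = ir). Three sets are built in:
#' * `"custom"` — the 10-feature data-aware set (16 channel-wise attributes);
#'   fully computable by this package.
#' * `"tsfel"` — the 15-feature retained TSFEL-style set (21 attributes);
#'   specification only (feature functions not implemented).
#' * `"tsfresh"` — the 13-feature retained tsfresh-style set
#'   (21 attributes); specification only.
#'
#' @param name one of `"custom"`, `"tsfel"`, `"tsfresh"`.
#' @return an object of class `mwppg_feature_set` with elements `name`,
#'   `features` (character), `channels` (named list of channel assignments)
#'   and `computable`.
#' @export
feature_set <- function(name = c("custom", "tsfel", "tsfresh")) {
  name <- match.arg(name)
  ch <- function(...) c(...)
  def <- switch(name,
    custom = list(
      peak_var = ch("red", "ir"),
      frequency_bands_slope = ch("green", "red"),
      neg_turning_points = ch("ir"),
      pos_turning_points = ch("ir"),
      binned_entropy = ch("red", "ir"),
      wavelet_entropy = ch("green", "red", "ir"),
      PSD_mean = ch("red"),
      num_of_peaks = ch("green"),
      peak_width_var = ch("red"),
      median_diff = ch("red", "ir")),
    tsfel = list(
      neg_turning_points = ch("ir"),
      pos_turning_points = ch("ir"),
      wavelet_entropy = ch("green", "red", "ir"),
      median_diff = ch("red", "ir"),
      median_absolute_diff = ch("ir"),
      entropy = ch("green", "red", "ir"),
      MFCC_3 = ch("green", "red"),
      MFCC_2 = ch("red"),
      MFCC_7 = ch("green"),
      MFCC_6 = ch("red"),
      MFCC_1 = ch("red"),
      median_frequency = ch("ir"),
      FFT_mean_coefficient_130 = ch("red"),
      spectral_kurtosis = ch("ir"),
      spectral_skewness = ch("red")),
    tsfresh = list(
      binned_entropy = ch("red", "ir"),
      change_quantiles_14 = ch("ir"),
      change_quantiles_16 = ch("ir"),
      change_quantiles_18 = ch("ir"),
      change_quantiles_17 = ch("green"),
      cid_ce_normalize = ch("green", "red", "ir"),
      lempel_ziv_complexity = ch("red", "ir"),
      change_quantiles_15 = ch("ir"),
      agg_linear_trend_5 = ch("green", "red", "ir"),
      change_quantiles_19 = ch("red"),
      change_quantiles_20 = ch("ir"),
      reoccurring_datapoints = ch("green", "red", "ir"),
      change_quantiles_10 = ch("green")))
  abort_if(any(vapply(def, length, integer(1)) == 0),
           "every channel assignment must be non-empty")
  structure(list(name = name, features = names(def), channels = def,
                 computable = name == "custom"),
            class = "mwppg_feature_set")
}

#' Number of sensor-level attributes of a feature set
#' @param spec an `mwppg_feature_set`.
#' @return integer: the sum of channel-assignment sizes.
#' @export
n_attributes <- function(spec) {
  sum(vapply(spec$channels, length, integer(1)))
}

#' @export
print.mwppg_feature_set <- function(x, ...) {
  cat(sprintf("<mwppg_feature_set> '%s': %d features, %d attributes%s\n",
              x$name, length(x$features), n_attributes(x),
              if (x$computable) "" else " (specification only)"))
  invisible(x)
}

# Compute the requested custom-set features for one window of one channel,
# sharing the peak and spectral intermediates.
window_features <- function(x, fs, wanted, params = list()) {
  out <- stats::setNames(numeric(length(wanted)), wanted)
  proposed <- intersect(wanted, c("num_of_peaks", "peak_var",
                                  "peak_width_var", "PSD_mean",
                                  "frequency_bands_slope"))
  if (length(proposed)) {
    pf <- do.call(proposed_features, c(list(window = x, fs = fs),
                                       params[intersect(names(params),
                                         c("psd_band", "low_band",
                                           "high_band", "hr_max",
                                           "prominence_frac"))]))
    out[proposed] <- pf[proposed]
  }
  lib <- intersect(wanted, c("neg_turning_points", "pos_turning_points",
                             "binned_entropy", "wavelet_entropy",
                             "median_diff"))
  if (length(lib)) {
    lf <- library_features(x, bins = params$bins %||% 10,
                           scales = params$scales %||% 1:9)
    out[lib] <- lf[lib]
  }
  unknown <- setdiff(wanted, c(proposed, lib))
  abort_if(length(unknown) > 0,
           paste0("unknown feature name(s): ",
                  paste(unknown, collapse = ", ")))
  out
}

#' Extract a feature matrix from a window set
#'
#' Channel-level mode produces one row per (window, channel) with one column
#' per feature of the set and that channel's window label. Sensor-level mode
#' produces one row per window with one `feature__channel` column per
#' assigned channel of the set (16 columns for the custom set) and the
#' sensor-level OR label. When the manifest carries a `split` column and
#' `standardize = TRUE`, attributes are z-scored with train-split statistics
#' and non-finite values are imputed to the train median (a split-less
#' matrix standardizes over all rows).
#'
#' @param ws an `mwppg_windows` (optionally split, see [split_windows()]).
#' @param records the list of source records (or a single record) the
#'   windows reference.
#' @param spec an [feature_set()] specification (must be computable).
#' @param mode `"channel"` or `"sensor"`.
#' @param standardize z-score the attributes (default `TRUE`).
#' @param params optional feature parameters passed through (see
#'   [proposed_features()], [library_features()]).
#' @return an object of class `mwppg_features`: list with matrix `x`,
#'   integer `labels`, optional `split`, `mode`, `spec` and a `row_info`
#'   data frame.
#' @export
extract_features <- function(ws, records, spec = feature_set("custom"),
                             mode = c("channel", "sensor"),
                             standardize = TRUE, params = list()) {
  mode <- match.arg(mode)
  abort_if(!inherits(spec, "mwppg_feature_set"), "spec must be a feature set")
  abort_if(!spec$computable,
           paste0("feature set '", spec$name, "' is a specification only"))
  if (inherits(records, "mwppg_record")) records <- list(records)
  rec_ids <- vapply(seq_along(records), function(i) {
    records[[i]]$meta$id %||% sprintf("record_%03d", i)
  }, character(1))
  names(records) <- rec_ids
  man <- ws$manifest
  W <- ws$window_samples
  fs <- ws$sample_rate
  chs <- ws$channels

  if (mode == "channel") {
    cols <- spec$features
    n_rows <- nrow(man) * length(chs)
  } else {
    cols <- unlist(lapply(spec$features, function(f) {
      paste0(f, "__", spec$channels[[f]])
    }))
    n_rows <- nrow(man)
  }
  x <- matrix(NA_real_, n_rows, length(cols),
              dimnames = list(NULL, cols))
  labels <- integer(n_rows)
  row_info <- data.frame(record_id = character(n_rows),
                         start_sample = integer(n_rows),
                         channel = character(n_rows))
  split <- if ("split" %in% names(man)) character(n_rows) else NULL

  r <- 0L
  for (i in seq_len(nrow(man))) {
    rec <- records[[man$record_id[i]]]
    abort_if(is.null(rec), paste0("window references unknown record: ",
                                  man$record_id[i]))
    idx <- (man$start_sample[i] + 1L):(man$start_sample[i] + W)
    if (mode == "channel") {
      for (ch in chs) {
        r <- r + 1L
        x[r, ] <- window_features(rec$samples[[ch]][idx], fs,
                                  spec$features, params)
        labels[r] <- man[[paste0("label_", ch)]][i]
        row_info$record_id[r] <- man$record_id[i]
        row_info$start_sample[r] <- man$start_sample[i]
        row_info$channel[r] <- ch
        if (!is.null(split)) split[r] <- man$split[i]
      }
    } else {
      r <- r + 1L
      per_ch <- lapply(chs, function(ch) {
        window_features(rec$samples[[ch]][idx], fs, spec$features, params)
      })
      names(per_ch) <- chs
      vals <- vapply(seq_along(cols), function(j) {
        parts <- strsplit(cols[j], "__", fixed = TRUE)[[1L]]
        per_ch[[parts[2L]]][[parts[1L]]]
      }, numeric(1))
      x[r, ] <- vals
      labels[r] <- man$label_sensor[i]
      row_info$record_id[r] <- man$record_id[i]
      row_info$start_sample[r] <- man$start_sample[i]
      row_info$channel[r] <- "sensor"
      if (!is.null(split)) split[r] <- man$split[i]
    }
  }

  fm <- structure(list(x = x, labels = labels, split = split, mode = mode,
                       spec = spec, row_info = row_info,
                       standardized = FALSE),
                  class = "mwppg_features")
  if (standardize && n_rows > 0) fm <- standardize_features(fm)
  fm
}

#' Standardize a feature matrix with train-split statistics
#'
#' Imputes non-finite entries to the train-split column median and z-scores
#' every column with the train mean and standard deviation (constant columns
#' are centered only). Without a split, all rows serve as the reference.
#'
#' @param fm an `mwppg_features`.
#' @return the standardized `mwppg_features` (with `$center`, `$scale` and
#'   `$median` recorded).
#' @export
standardize_features <- function(fm) {
  ref <- if (!is.null(fm$split)) which(fm$split == "train") else
    seq_len(nrow(fm$x))
  if (!length(ref)) ref <- seq_len(nrow(fm$x))
  med <- apply(fm$x[ref, , drop = FALSE], 2,
               function(v) stats::median(v[is.finite(v)]))
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(fm$x))) {
    bad <- !is.finite(fm$x[, j])
    if (any(bad)) fm$x[bad, j] <- med[j]
  }
  ctr <- colMeans(fm$x[ref, , drop = FALSE])
  scl <- apply(fm$x[ref, , drop = FALSE], 2, stats::sd)
  # near-constant columns (sd at float-noise level relative to the center)
  # are centered only, not rescaled
  scl[!is.finite(scl) | scl <= 1e-8 * pmax(abs(ctr), 1)] <- 1
  fm$x <- sweep(sweep(fm$x, 2, ctr), 2, scl, "/")
  fm$center <- ctr
  fm$scale <- scl
  fm$median <- med
  fm$standardized <- TRUE
  fm
}

#' @export
print.mwppg_features <- function(x, ...) {
  cat(sprintf(
    "<mwppg_features> %d x %d (%s-level, set '%s'), anomalous %.1f%%\n",
    nrow(x$x), ncol(x$x), x$mode, x$spec$name,
    if (nrow(x$x)) 100 * mean(x$labels) else NA_real_))
  invisible(x)
}

#' Subset rows of a feature matrix (keeps labels and bookkeeping aligned)
#' @param fm an `mwppg_features`.
#' @param idx row indices or a logical mask.
#' @return the subset `mwppg_features`.
#' @export
fm_rows <- function(fm, idx) {
  fm$x <- fm$x[idx, , drop = FALSE]
  fm$labels <- fm$labels[idx]
  if (!is.null(fm$split)) fm$split <- fm$split[idx]
  fm$row_info <- fm$row_info[idx, , drop = FALSE]
  fm
}

#' Split a feature matrix by its split column
#' @param fm an `mwppg_features` carrying a `split`.
#' @return named list of `mwppg_features` (`train`, `val`, `test`).
#' @export
fm_split <- function(fm) {
  abort_if(is.null(fm$split), "feature matrix carries no split")
  lapply(stats::setNames(c("train", "val", "test"),
                         c("train", "val", "test")),
         function(s) fm_rows(fm, which(fm$split == s)))
}

#' Write a feature matrix as CSV
#'
#' Header row of attribute names plus `label` and (when present) `split`
#' columns.
#' @param fm an `mwppg_features`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(fm, path) {
  df <- as.data.frame(fm$x)
  df$label <- fm$labels
  if (!is.null(fm$split)) df$split <- fm$split
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
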
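# Sparse spike train with prescribed peak amplitudes, spaced far apart.
spike_train <- function(amps, gap = 100, n = NULL) {
  n <- n %||% (gap * (length(amps) + 1))
  x <- numeric(n)
  x[gap * seq_along(amps)] <- amps
  x
}

test_that("detect_peaks: counts, suppression and degenerate input", {
  fs <- 125
  expect_length(detect_peaks(rep(1, 100), fs)$index, 0)
  # unit sinusoid at 1.5 Hz over 6 s has 9 peaks
  t <- (0:(6 * fs - 1)) / fs
  expect_length(detect_peaks(sin(2 * pi * 1.5 * t), fs)$index, 9)
  # two peaks 0.2 s apart violate the 180-BPM distance: larger retained
  x <- numeric(400)
  x[100] <- 1
  x[125] <- 0.8
  pk <- detect_peaks(x, fs, hr_max = 180)
  expect_identical(pk$index, 100L)
  # same two peaks at relaxed distance are both kept
  pk2 <- detect_peaks(x, fs, hr_max = 400)
  expect_identical(pk2$index, c(100L, 125L))
  expect_error(detect_peaks(numeric(0), fs), "non-empty")
})

test_that("proposed features match their closed-form examples", {
  fs <- 125
  pf <- proposed_features(spike_train(c(1, 2, 3)), fs)
  expect_equal(unname(pf["num_of_peaks"]), 3)
  expect_equal(unname(pf["peak_var"]), 1.0)  # var(1,2,3) unbiased
  # constant-amplitude periodic trains: near-zero peak variances (the
  # sinusoid's boundary peaks carry small sampling/edge effects; the spike
  # train of identical pulses is exact)
  t <- (0:(6 * fs - 1)) / fs
  pf2 <- proposed_features(sin(2 * pi * 1.5 * t), fs)
  expect_lt(unname(pf2["peak_var"]), 1e-6)
  expect_lt(unname(pf2["peak_width_var"]), 5e-3)
  pf3 <- proposed_features(spike_train(rep(2, 5)), fs)
  expect_equal(unname(pf3["peak_var"]), 0)
  expect_equal(unname(pf3["peak_width_var"]), 0)
  # clean pulsatile window outscores equal-power white noise on the slope
  set.seed(4)
  clean <- sin(2 * pi * 1.5 * t)
  noise <- rnorm(length(t), 0, sd(clean))
  expect_gt(unname(proposed_features(clean, fs)["frequency_bands_slope"]),
            unname(proposed_features(noise, fs)["frequency_bands_slope"]))
})

test_that("library features match their closed-form examples", {
  # strictly monotone ramp: no turning points, constant step
  lf <- library_features(seq(0, 10, by = 0.5))
  expect_equal(unname(lf["pos_turning_points"]), 0)
  expect_equal(unname(lf["neg_turning_points"]), 0)
  expect_equal(unname(lf["median_diff"]), 0.5)
  # alternating sequence of length n: pos + neg turning points = n - 2
  for (n in c(10, 25, 64)) {
    alt <- rep(c(0, 1), length.out = n)
    lf <- library_features(alt)
    expect_equal(unname(lf["pos_turning_points"] +
                          lf["neg_turning_points"]), n - 2)
  }
  # samples uniformly filling all 10 bins: entropy ln 10
  u <- rep((0:9 + 0.5) / 10, each = 5)
  expect_equal(binned_entropy(u, bins = 10), log(10), tolerance = 1e-6)
  # degenerate constant window
  lf0 <- library_features(rep(2, 50))
  expect_equal(unname(lf0["binned_entropy"]), 0)
  expect_equal(unname(lf0["wavelet_entropy"]), 0)
  expect_equal(unname(lf0["median_diff"]), 0)
  expect_error(library_features(c(1, 2)), "length")
})

test_that("offset and scale invariances hold for all ten features", {
  fs <- 125
  set.seed(8)
  t <- (0:(4 * fs - 1)) / fs
  x <- sin(2 * pi * 1.4 * t) + 0.2 * rnorm(length(t))
  f <- function(v) c(proposed_features(v, fs), library_features(v))
  base <- f(x)
  shifted <- f(x + 57.3)
  expect_equal(shifted, base, tolerance = 1e-6)
  # positive scaling: peak_var scales c^2; counts and binned entropy exact
  c0 <- 3.7
  scaled <- f(x * c0)
  expect_equal(unname(scaled["peak_var"]),
               unname(base["peak_var"]) * c0^2, tolerance = 1e-10)
  for (nm in c("num_of_peaks", "pos_turning_points", "neg_turning_points")) {
    expect_identical(unname(scaled[nm]), unname(base[nm]))
  }
  expect_equal(unname(scaled["binned_entropy"]),
               unname(base["binned_entropy"]), tolerance = 1e-12)
})

test_that("built-in feature sets have the published shapes", {
  custom <- feature_set("custom")
  expect_length(custom$features, 10)
  expect_equal(n_attributes(custom), 16)
  expect_true(custom$computable)
  tsfel <- feature_set("tsfel")
  expect_length(tsfel$features, 15)
  expect_equal(n_attributes(tsfel), 21)
  tsfresh <- feature_set("tsfresh")
  expect_length(tsfresh$features, 13)
  expect_equal(n_attributes(tsfresh), 21)
  expect_error(extract_features(
    segment_windows(labeled_record(), 2), labeled_record(), spec = tsfel),
    "specification only")
})

test_that("extract_features obeys the matrix arithmetic in both modes", {
  rec <- labeled_record(n = 1250, anomalous = 1:300)
  rec$meta$id <- "record"
  ws <- segment_windows(rec, 2, overlap = 0.5)
  n_win <- nrow(ws$manifest)

  fmc <- extract_features(ws, rec, mode = "channel", standardize = FALSE)
  expect_equal(dim(fmc$x), c(n_win * 3, 10))
  expect_identical(colnames(fmc$x), feature_set("custom")$features)
  # channel rows carry that channel's window label
  g_rows <- fmc$row_info$channel == "green"
  expect_equal(fmc$labels[g_rows], ws$manifest$label_green)

  fms <- extract_features(ws, rec, mode = "sensor", standardize = FALSE)
  expect_equal(dim(fms$x), c(n_win, 16))
  expect_true(all(grepl("__", colnames(fms$x))))
  expect_identical(fms$labels, ws$manifest$label_sensor)
  # sensor columns agree with channel-mode values for the same window
  expect_equal(unname(fms$x[1, "num_of_peaks__green"]),
               unname(fmc$x[which(g_rows)[1], "num_of_peaks"]))

  # empty window set: empty matrix with the correct schema
  empty <- segment_windows(labeled_record(n = 10), 2)
  fme <- extract_features(empty, labeled_record(n = 10), mode = "sensor")
  expect_equal(nrow(fme$x), 0)
  expect_equal(ncol(fme$x), 16)
})

test_that("standardization uses train-split statistics", {
  rec <- labeled_record(n = 2500)
  rec$meta$id <- "record"
  ws <- segment_windows(rec, 2, overlap = 0)
  ws <- split_windows(ws, fractions = c(0.6, 0.2, 0.2), seed = 1,
                      paper_mode = TRUE)
  fm <- extract_features(ws, rec, mode = "sensor")
  tr <- fm$x[fm$split == "train", , drop = FALSE]
  expect_equal(unname(colMeans(tr)), rep(0, ncol(tr)), tolerance = 1e-10)
  expect_true(all(is.finite(fm$x)))
})
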
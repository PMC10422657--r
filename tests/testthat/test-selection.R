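# Independent contingency-table oracle for information gain on discrete
# inputs (no binning).
ig_oracle <- function(x, y) {
  h <- function(counts) {
    p <- counts / sum(counts)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  hy <- h(table(y))
  tab <- table(x, y)
  hc <- sum(rowSums(tab) / length(x) * apply(tab, 1, h))
  max(hy - hc, 0)
}

test_that("info_gain worked examples", {
  # perfect predictor of a balanced class: 1 bit
  y <- rep(c(0, 1), 20)
  expect_equal(info_gain(y, y), 1.0)
  # constant attribute: 0
  expect_equal(info_gain(rep(1, 40), y), 0)
  # single-class labels: 0 by definition
  expect_equal(info_gain(rnorm(10), rep(1, 10)), 0)
  # hand-computed 2x2 contingency example:
  # class 6 pos / 4 neg; bin a: 4 pos 0 neg, bin b: 2 pos 4 neg
  x <- c(rep(0, 4), rep(1, 6))
  yy <- c(rep(1, 4), rep(1, 2), rep(0, 4))
  expect_equal(info_gain(x, yy), 0.4200, tolerance = 1e-3)
  expect_error(info_gain(1:3, 1:2), "mismatch")
})

test_that("info_gain equals the exhaustive oracle on discrete inputs", {
  set.seed(13)
  for (rep_i in 1:50) {
    n <- sample(4:20, 1)
    k <- sample(2:4, 1)
    x <- sample(seq_len(k), n, replace = TRUE)
    y <- sample(0:1, n, replace = TRUE)
    expect_equal(info_gain(x, y, bins = 4), ig_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("info_gain is bounded by the class entropy", {
  set.seed(14)
  for (rep_i in 1:30) {
    n <- sample(10:200, 1)
    x <- rnorm(n)
    y <- sample(0:1, n, replace = TRUE, prob = c(0.7, 0.3))
    ig <- info_gain(x, y)
    expect_gte(ig, 0)
    hy <- ig_oracle(y, y)
    expect_lte(ig, hy + 1e-12)
  }
})

test_that("aggregate_channels averages per-feature channel attributes", {
  x <- cbind(a__green = c(1, 4), a__red = c(2, 5), a__ir = c(3, 6),
             b__green = c(10, 20), b__red = c(10, 20))
  fm <- structure(list(x = x, labels = c(0L, 1L), split = NULL,
                       mode = "sensor", spec = feature_set("custom"),
                       row_info = data.frame(record_id = c("r", "r"),
                                             start_sample = c(0L, 1L),
                                             channel = "sensor")),
                  class = "mwppg_features")
  agg <- aggregate_channels(fm)
  expect_equal(dim(agg$x), c(2, 2))
  expect_equal(unname(agg$x[, "a"]), c(2, 5))      # mean of 1,2,3 / 4,5,6
  expect_equal(unname(agg$x[, "b"]), c(10, 20))    # identical columns
  expect_equal(agg$labels, c(0L, 1L))
  fm$mode <- "channel"
  expect_error(aggregate_channels(fm), "sensor-level")
})

test_that("combined-channel aggregation denoises complementary channels", {
  # one latent signal observed with independent noise per channel: the mean
  # across channels has higher information gain than any single channel
  set.seed(15)
  n <- 400
  latent <- rep(c(0, 3), each = n / 2)
  y <- rep(c(0L, 1L), each = n / 2)
  chs <- sapply(1:3, function(i) latent + rnorm(n, 0, 2.5))
  colnames(chs) <- paste0("f__", c("green", "red", "ir"))
  fm <- structure(list(x = chs, labels = y, split = NULL, mode = "sensor",
                       spec = feature_set("custom"),
                       row_info = data.frame(record_id = "r",
                                             start_sample = seq_len(n),
                                             channel = "sensor")),
                  class = "mwppg_features")
  ig_per <- vapply(1:3, function(j) info_gain(chs[, j], y), numeric(1))
  agg <- aggregate_channels(fm)
  expect_gt(info_gain(agg$x[, 1], y), max(ig_per))
})

test_that("rank_attributes sorts descending with lexical tie-break", {
  set.seed(16)
  n <- 300
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(strong = y + rnorm(n, 0, 0.3),
             weak = y + rnorm(n, 0, 3),
             zz_noise = rnorm(n),
             aa_noise = rnorm(n))
  fm <- structure(list(x = x, labels = y, split = NULL, mode = "channel",
                       spec = feature_set("custom"),
                       row_info = data.frame(record_id = "r",
                                             start_sample = seq_len(n),
                                             channel = "green")),
                  class = "mwppg_features")
  rk <- rank_attributes(fm)
  expect_equal(rk$attribute[1], "strong")
  expect_true(all(diff(rk$info_gain_bits) <= 0))
  # ranking report CSV
  path <- tempfile(fileext = ".csv")
  write_ranking_csv(rk, path = path)
  back <- utils::read.csv(path)
  expect_identical(names(back), c("attribute", "info_gain_bits",
                                  "retained"))
  expect_equal(nrow(back), 4)
  unlink(path)
})

test_that("rfe drops a pure-noise attribute and keeps its F1 guarantee", {
  set.seed(17)
  n <- 240
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(inf1 = y * 2 + rnorm(n, 0, 0.5),
             inf2 = -y + rnorm(n, 0, 0.5),
             noise = rnorm(n))
  fm <- structure(list(x = x, labels = y, split = NULL, mode = "channel",
                       spec = feature_set("custom"),
                       row_info = data.frame(record_id = "r",
                                             start_sample = seq_len(n),
                                             channel = "green")),
                  class = "mwppg_features")
  sel <- rfe_select(fm, cv_folds = 3, seed = 2)
  expect_false("noise" %in% sel$retained)
  expect_true(all(c("inf1", "inf2") %in% sel$retained) ||
                length(sel$retained) >= 1)
  # the stop criterion guarantee, asserted on the returned report
  expect_gte(sel$cv_f1, sel$full_f1 - 0.025)
  # cutoff equals the weakest retained attribute's gain
  rk <- rank_attributes(fm)
  expect_equal(sel$cutoff,
               min(rk$info_gain_bits[rk$attribute %in% sel$retained]))
  # degenerate single-attribute input returned unchanged
  fm1 <- fm
  fm1$x <- fm$x[, "inf1", drop = FALSE]
  expect_identical(rfe_select(fm1)$retained, "inf1")
})

test_that("best-first forward search finds signal, skips duplicates", {
  set.seed(18)
  n <- 160
  y <- rep(c(0L, 1L), each = n / 2)
  sig <- y * 3 + rnorm(n, 0.4)
  x <- cbind(sig = sig, dup = sig, noise = rnorm(n))
  fm <- structure(list(x = x, labels = y, split = NULL, mode = "channel",
                       spec = feature_set("custom"),
                       row_info = data.frame(record_id = "r",
                                             start_sample = seq_len(n),
                                             channel = "green")),
                  class = "mwppg_features")
  cfg <- detector_config("decision_tree", seed = 1)  # deterministic wrapper
  sel <- best_first_select(fm, cfg = cfg, cv_folds = 3, seed = 3)
  expect_true("sig" %in% sel$retained || "dup" %in% sel$retained)
  # a perfectly correlated duplicate cannot improve the wrapper, so the
  # best subset never contains both copies
  expect_lt(sum(c("sig", "dup") %in% sel$retained), 2)
  # empty pool selects nothing
  fm0 <- fm
  fm0$x <- fm$x[, integer(0), drop = FALSE]
  expect_length(best_first_select(fm0, cfg = cfg)$retained, 0)
})
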
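#' Weighted-vote window label
#'
#' A window is anomalous (1) iff the weighted sum of its per-sample labels
#' reaches the threshold: `sum(w_i * l_i) >= m`. With the default unit
#' weights and `m = ceiling(alpha * n)` the required number of anomalous
#' samples grows with the window size.
#'
#' @param sample_labels per-sample binary labels within one window.
#' @param weights per-sample weights (default all 1).
#' @param m threshold value (default `ceiling(alpha * n)`).
#' @param alpha anomalous-fraction threshold used when `m` is not given
#'   (default 0.2).
#' @return integer 0 or 1.
#' @export
vote_label <- function(sample_labels, weights = NULL, m = NULL,
                       alpha = 0.2) {
  n <- length(sample_labels)
  if (is.null(weights)) weights <- rep(1, n)
  abort_if(length(weights) != n, "weights and labels must share one length")
  if (is.null(m)) m <- ceiling(alpha * n)
  as.integer(sum(weights * sample_labels) >= m)
}

#' Segment a record into overlapped fixed-length windows
#'
#' Start offsets form the arithmetic progression `0, step, 2*step, ...` with
#' `step = round(window_samples * (1 - overlap))`; a trailing partial window
#' is discarded, so the window count is `floor((N - W) / step) + 1` for
#' `N >= W` and 0 otherwise. Each window receives a per-channel binary label
#' by the weighted vote ([vote_label()]) over its sample labels, and a
#' sensor-level label equal to the OR across channels.
#'
#' @param record an `mwppg_record`.
#' @param window_s window length in seconds (> 0).
#' @param overlap fractional overlap between adjacent windows in `[0, 1)`
#'   (default 0.5).
#' @param alpha anomalous-fraction vote threshold (default 0.2).
#' @param record_id identifier stored in the manifest (default from
#'   `meta$id`).
#' @return an object of class `mwppg_windows`: a list with the segmentation
#'   parameters and a `manifest` data frame
#'   (`record_id, start_sample, window_samples, label_<ch>..., label_sensor`).
#'   `start_sample` is zero-based.
#' @export
segment_windows <- function(record, window_s, overlap = 0.5, alpha = 0.2,
                            record_id = NULL) {
  abort_if(window_s <= 0, "window_s must be > 0")
  abort_if(overlap < 0 || overlap >= 1, "overlap must be in [0,1)")
  fs <- record$sample_rate
  W <- round(window_s * fs)
  step <- max(1L, round(W * (1 - overlap)))
  N <- record_length(record)
  record_id <- record_id %||% (record$meta$id %||% "record")
  chs <- channel_names(record)
  if (N < W || W < 1L) {
    manifest <- empty_manifest(chs)
  } else {
    n_win <- floor((N - W) / step) + 1L
    starts <- (seq_len(n_win) - 1L) * step
    labs <- matrix(0L, n_win, length(chs), dimnames = list(NULL, chs))
    for (ch in chs) {
      l <- record$labels[[ch]]
      for (i in seq_len(n_win)) {
        labs[i, ch] <- vote_label(l[(starts[i] + 1L):(starts[i] + W)],
                                  alpha = alpha)
      }
    }
    manifest <- data.frame(record_id = record_id, start_sample = starts,
                           window_samples = W)
    for (ch in chs) manifest[[paste0("label_", ch)]] <- labs[, ch]
    manifest$label_sensor <- as.integer(rowSums(labs) > 0)
  }
  structure(list(window_s = window_s, window_samples = W, overlap = overlap,
                 alpha = alpha, sample_rate = fs, channels = chs,
                 manifest = manifest),
            class = "mwppg_windows")
}

empty_manifest <- function(chs) {
  manifest <- data.frame(record_id = character(0),
                         start_sample = integer(0),
                         window_samples = integer(0))
  for (ch in chs) manifest[[paste0("label_", ch)]] <- integer(0)
  manifest$label_sensor <- integer(0)
  manifest
}

#' Segment a list of records into one combined window set
#'
#' @param records list of `mwppg_record` objects sharing channel layout and
#'   sampling rate.
#' @inheritParams segment_windows
#' @return an `mwppg_windows` whose manifest concatenates all records'
#'   windows (record ids kept for leakage-free splitting).
#' @export
window_dataset <- function(records, window_s, overlap = 0.5, alpha = 0.2) {
  abort_if(!length(records), "records must be a non-empty list")
  parts <- lapply(seq_along(records), function(i) {
    rid <- records[[i]]$meta$id %||% sprintf("record_%03d", i)
    segment_windows(records[[i]], window_s, overlap, alpha, record_id = rid)
  })
  ws <- parts[[1L]]
  ws$manifest <- do.call(rbind, lapply(parts, `[[`, "manifest"))
  rownames(ws$manifest) <- NULL
  ws
}

#' @export
print.mwppg_windows <- function(x, ...) {
  cat(sprintf(
    "<mwppg_windows> %d windows of %g s (%d samples, overlap %.0f%%)\n",
    nrow(x$manifest), x$window_s, x$window_samples, 100 * x$overlap))
  if (nrow(x$manifest)) {
    cat(sprintf("  sensor-level anomalous: %.1f%%\n",
                100 * mean(x$manifest$label_sensor)))
  }
  invisible(x)
}

#' Split windows into train / validation / test
#'
#' Default fractions 0.8 / 0.1 / 0.1. By default whole source records are
#' assigned to one split (`grouped = TRUE`) so that 50%-overlapped windows
#' never straddle the train/test boundary; `paper_mode = TRUE` instead splits
#' individual windows at random, as window-level splitting of an overlapped
#' segmentation would.
#'
#' @param ws an `mwppg_windows`.
#' @param fractions numeric length-3 vector `(train, val, test)` summing
#'   to 1.
#' @param seed integer seed for the shuffle.
#' @param paper_mode split individual windows instead of whole records
#'   (default `FALSE`).
#' @param grouped group by source record (default `TRUE`; ignored when
#'   `paper_mode = TRUE`).
#' @return the window set with a `split` column
#'   (`"train"`/`"val"`/`"test"`) added to the manifest.
#' @export
split_windows <- function(ws, fractions = c(0.8, 0.1, 0.1), seed = NULL,
                          paper_mode = FALSE, grouped = TRUE) {
  abort_if(length(fractions) != 3 || any(fractions < 0) ||
             abs(sum(fractions) - 1) > 1e-8,
           "fractions must be three non-negative numbers summing to 1")
  n <- nrow(ws$manifest)
  split <- character(n)
  if (n > 0) {
    if (paper_mode || !grouped) {
      idx <- with_seed(seed, sample.int(n))
      n_test <- round(fractions[3] * n)
      n_val <- round(fractions[2] * n)
      split[idx] <- rep(c("test", "val", "train"),
                        c(n_test, n_val, n - n_test - n_val))
    } else {
      rids <- unique(ws$manifest$record_id)
      rids <- with_seed(seed, sample(rids))
      sizes <- table(ws$manifest$record_id)[rids]
      assigned <- character(length(rids))
      names(assigned) <- rids
      filled <- c(train = 0, val = 0, test = 0)
      target <- stats::setNames(fractions * n, c("train", "val", "test"))
      for (r in rids) {
        # greedy: put the record where the deficit (relative to target)
        # is largest
        deficit <- target - filled
        pick <- names(which.max(deficit))
        assigned[r] <- pick
        filled[pick] <- filled[pick] + sizes[[r]]
      }
      split <- assigned[ws$manifest$record_id]
    }
  }
  ws$manifest$split <- unname(split)
  ws
}
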
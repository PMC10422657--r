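#' Multi-channel PPG record
#'
#' The basic container of the package: synchronized per-channel sample arrays
#' at a fixed sampling rate together with per-sample, per-channel binary
#' anomaly labels (1 = anomalous sample) and free-form provenance metadata.
#' Channels are ordered `green`, `red`, `ir` by convention (525 nm, 631 nm,
#' 940 nm source-detector pairs of a reflective MW-PPG sensor unit).
#'
#' @param samples named list of equal-length numeric vectors (light-intensity
#'   units), one per channel.
#' @param labels named list of equal-length integer vectors in `{0,1}`, or
#'   `NULL` for all-clean labels.
#' @param sample_rate sampling rate in Hz.
#' @param meta free-form list of provenance metadata (seed, artifact manifest,
#'   category, generator components, ...).
#' @return an object of class `mwppg_record`.
#' @export
multichannel_record <- function(samples, labels = NULL, sample_rate = 125,
                                meta = list()) {
  abort_if(!is.list(samples) || is.null(names(samples)) ||
             any(names(samples) == ""), "samples must be a named list")
  n <- unique(vapply(samples, length, integer(1)))
  abort_if(length(n) > 1, "all channel arrays must share one length")
  if (is.null(labels)) {
    labels <- lapply(samples, function(x) integer(length(x)))
  }
  abort_if(!identical(names(labels), names(samples)),
           "labels must be named like samples")
  for (ch in names(labels)) {
    abort_if(length(labels[[ch]]) != length(samples[[ch]]),
             "labels must align 1:1 with samples")
    abort_if(!all(labels[[ch]] %in% c(0L, 1L)), "labels must be 0/1")
    labels[[ch]] <- as.integer(labels[[ch]])
  }
  abort_if(!is.numeric(sample_rate) || sample_rate <= 0,
           "sample_rate must be positive")
  structure(list(samples = samples, labels = labels,
                 sample_rate = sample_rate, meta = meta),
            class = "mwppg_record")
}

#' @export
print.mwppg_record <- function(x, ...) {
  n <- record_length(x)
  cat(sprintf("<mwppg_record> %d channels x %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), n, x$sample_rate, n / x$sample_rate))
  for (ch in names(x$samples)) {
    cat(sprintf("  %-6s anomalous: %5.1f%%\n", ch,
                100 * mean(x$labels[[ch]])))
  }
  invisible(x)
}

#' @export
length.mwppg_record <- function(x) record_length(x)

#' Number of samples per channel of a record
#' @param record an `mwppg_record`.
#' @return integer sample count.
#' @export
record_length <- function(record) {
  if (!length(record$samples)) return(0L)
  length(record$samples[[1L]])
}

#' Duration of a record in seconds
#' @param record an `mwppg_record`.
#' @return numeric seconds.
#' @export
record_duration <- function(record) record_length(record) / record$sample_rate

channel_names <- function(record) names(record$samples)

#' Write / read a record as CSV plus JSON sidecar
#'
#' The on-disk format is a plain CSV with header
#' `time,green,red,ir,label_green,label_red,label_ir` (one row per sample,
#' time in seconds) and a `<path>.json` sidecar holding the sampling rate and
#' the provenance metadata (seed, artifact manifest).
#'
#' @param record an `mwppg_record`.
#' @param path CSV file path.
#' @return `write_record_csv` returns `path` invisibly; `read_record_csv`
#'   returns an `mwppg_record`.
#' @export
write_record_csv <- function(record, path) {
  n <- record_length(record)
  df <- data.frame(time = (seq_len(n) - 1) / record$sample_rate)
  for (ch in channel_names(record)) df[[ch]] <- record$samples[[ch]]
  for (ch in channel_names(record)) df[[paste0("label_", ch)]] <-
      record$labels[[ch]]
  utils::write.csv(df, path, row.names = FALSE)
  meta <- record$meta
  meta$components <- NULL  # bulky generator internals stay in memory only
  jsonlite::write_json(list(sample_rate = record$sample_rate, meta = meta),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}

#' @rdname write_record_csv
#' @export
read_record_csv <- function(path) {
  df <- utils::read.csv(path)
  side <- paste0(path, ".json")
  fs <- 125
  meta <- list()
  if (file.exists(side)) {
    j <- jsonlite::read_json(side, simplifyVector = TRUE)
    fs <- j$sample_rate %||% 125
    meta <- as.list(j$meta %||% list())
  }
  chs <- setdiff(names(df), c("time", grep("^label_", names(df), value = TRUE)))
  samples <- lapply(df[chs], as.numeric)
  labels <- lapply(chs, function(ch) {
    col <- paste0("label_", ch)
    if (col %in% names(df)) as.integer(df[[col]]) else integer(nrow(df))
  })
  names(labels) <- chs
  multichannel_record(samples, labels, sample_rate = fs, meta = meta)
}
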
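#' Detect pulse peaks in a single-channel window
#'
#' Strict local maxima filtered by topographic prominence and a minimum
#' inter-peak distance. The distance floor is the shortest physiologic beat
#' interval, `fs * 60 / hr_max` samples (default `hr_max` 180 BPM); the
#' prominence floor is a fraction of the window's total amplitude range
#' (default 0.1). When two candidates violate the distance floor the larger
#' one is retained. Widths are measured at half prominence by linear
#' interpolation. Deterministic; a flat window yields no peaks.
#'
#' @param window numeric vector (one channel, one window).
#' @param fs sampling rate in Hz.
#' @param hr_max maximum heart rate in BPM defining the minimum peak
#'   distance (default 180).
#' @param prominence_frac minimum prominence as a fraction of
#'   `max(window) - min(window)` (default 0.1).
#' @return list with `index` (1-based sample indices), `amplitude`,
#'   `prominence`, and `width_s` (half-prominence widths in seconds).
#' @export
detect_peaks <- function(window, fs, hr_max = 180, prominence_frac = 0.1) {
  abort_if(!length(window), "window must be non-empty")
  n <- length(window)
  empty <- list(index = integer(0), amplitude = numeric(0),
                prominence = numeric(0), width_s = numeric(0))
  if (n < 3) return(empty)
  rng <- max(window) - min(window)
  if (rng == 0) return(empty)
  cand <- which(window[2:(n - 1)] > window[1:(n - 2)] &
                  window[2:(n - 1)] > window[3:n]) + 1L
  if (!length(cand)) return(empty)

  prom <- vapply(cand, peak_prominence, numeric(1), x = window)
  keep <- prom >= prominence_frac * rng
  cand <- cand[keep]
  prom <- prom[keep]
  if (!length(cand)) return(empty)

  # Greedy minimum-distance suppression, larger peaks first.
  min_dist <- fs * 60 / hr_max
  ord <- order(window[cand], decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(cand[i] - cand[kept]) >= min_dist)) {
      kept <- c(kept, i)
    }
  }
  kept <- sort(kept)
  cand <- cand[kept]
  prom <- prom[kept]

  widths <- vapply(seq_along(cand), function(i) {
    half_prominence_width(window, cand[i], prom[i])
  }, numeric(1)) / fs
  list(index = cand, amplitude = window[cand], prominence = prom,
       width_s = widths)
}

# Topographic prominence of the local maximum at position `i`: walk out on
# each side until a strictly higher sample (or the boundary) is met; the
# prominence is the peak height above the higher of the two interval minima.
peak_prominence <- function(x, i) {
  left <- i
  while (left > 1 && x[left - 1] <= x[i]) left <- left - 1
  right <- i
  n <- length(x)
  while (right < n && x[right + 1] <= x[i]) right <- right + 1
  left_min <- min(x[left:i])
  right_min <- min(x[i:right])
  x[i] - max(left_min, right_min)
}

# Width (in samples) of the peak at `i` at height `x[i] - 0.5 * prom`,
# linearly interpolated at the crossings.
half_prominence_width <- function(x, i, prom) {
  h <- x[i] - 0.5 * prom
  n <- length(x)
  l <- i
  while (l > 1 && x[l - 1] >= h && x[l - 1] <= x[i]) l <- l - 1
  xl <- if (l > 1 && x[l - 1] < h) {
    (l - 1) + (h - x[l - 1]) / (x[l] - x[l - 1])
  } else l
  r <- i
  while (r < n && x[r + 1] >= h && x[r + 1] <= x[i]) r <- r + 1
  xr <- if (r < n && x[r + 1] < h) {
    r + (x[r] - h) / (x[r] - x[r + 1])
  } else r
  xr - xl
}
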
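AUGMENTER_KINDS <- c("shift", "scale", "warp", "drift", "noise", "dropout")

#' Channel-level augmentation specification
#'
#' One of the six single-channel transforms used both to expand a dataset
#' with natural-looking variation and to create synthetic channel-wise
#' anomalies:
#' * `shift` — circular shift by `w` samples; the wrapped-around region is
#'   flagged modified.
#' * `scale` — elementwise multiplication by a scalar or per-sample vector
#'   `s`.
#' * `warp` — monotone piecewise-linear time warping through `knots` random
#'   interior anchors (or explicit `anchors`), resampled back to the original
#'   grid by linear interpolation.
#' * `drift` — adds a polynomial baseline of degree <= 4 with coefficients
#'   `coef` (constant first), evaluated on the window's time grid in seconds.
#' * `noise` — adds i.i.d. Gaussian noise with standard deviation `sigma`.
#' * `dropout` — replaces samples by `fill` (default 0) where an i.i.d.
#'   Bernoulli(`p`) mask fires.
#'
#' @param kind one of `r paste(AUGMENTER_KINDS, collapse = ", ")`.
#' @param w shift amount in samples (integer; `shift`).
#' @param s scalar or per-sample multiplicative factor(s) (`scale`).
#' @param knots number of random interior warp anchors (default 3; `warp`).
#' @param anchors optional explicit warp mapping as a two-column matrix of
#'   (source index, target index) anchor pairs, strictly monotone (`warp`).
#' @param max_warp maximum relative anchor displacement (default 0.1;
#'   `warp`).
#' @param coef polynomial drift coefficients, constant term first, length
#'   <= 5 (degree <= 4; `drift`).
#' @param sigma Gaussian noise standard deviation in signal units (`noise`).
#' @param p dropout probability in `[0, 1]` (`dropout`).
#' @param fill dropout fill value (default 0) or `"hold"` for
#'   last-value-carried-forward (`dropout`).
#' @param fs sampling rate used by `drift`'s time grid (default 125).
#' @param label_as_anomaly should the modified mask be OR-ed into the channel
#'   labels by [augment_record()]? Default: `TRUE` for `dropout` (it emulates
#'   a sensor fault), `FALSE` otherwise (shift/scale/warp and mild
#'   noise/drift emulate natural variation).
#' @param seed integer seed (noise, dropout, random warp anchors).
#' @return an object of class `mwppg_augmenter_spec`.
#' @export
augmenter_spec <- function(kind, w = 0L, s = 1, knots = 3, anchors = NULL,
                           max_warp = 0.1, coef = numeric(5), sigma = 0,
                           p = 0, fill = 0, fs = 125,
                           label_as_anomaly = NULL, seed = NULL) {
  abort_if(!kind %in% AUGMENTER_KINDS,
           paste0("unsupported augmenter kind: ", kind))
  abort_if(p < 0 || p > 1, "dropout probability must be in [0,1]")
  abort_if(length(coef) > 5, "drift polynomial must have degree <= 4")
  if (!is.null(anchors)) {
    abort_if(!is.matrix(anchors) || ncol(anchors) != 2 ||
               any(diff(anchors[, 1]) <= 0) || any(diff(anchors[, 2]) <= 0),
             "invalid spec: warp anchors must be strictly monotone pairs")
  }
  if (is.null(label_as_anomaly)) label_as_anomaly <- kind == "dropout"
  structure(list(kind = kind, w = as.integer(w), s = s, knots = knots,
                 anchors = anchors, max_warp = max_warp, coef = coef,
                 sigma = sigma, p = p, fill = fill, fs = fs,
                 label_as_anomaly = isTRUE(label_as_anomaly), seed = seed),
            class = "mwppg_augmenter_spec")
}

#' Apply one augmenter to a single-channel series
#'
#' Output length always equals input length (shift wraps; warp resamples
#' back to the original grid). The returned mask marks the samples the
#' transform touched: the wrapped region for `shift`, and the samples whose
#' value changed for every other kind. Stochastic kinds are reproducible per
#' seed.
#'
#' @param series numeric vector (one channel).
#' @param spec an [augmenter_spec()].
#' @return list with `series` (augmented vector) and `mask` (logical,
#'   per-sample modified flags).
#' @export
apply_augmenter <- function(series, spec) {
  abort_if(!inherits(spec, "mwppg_augmenter_spec"),
           "spec must be an mwppg_augmenter_spec")
  n <- length(series)
  if (n == 0L) return(list(series = series, mask = logical(0)))
  with_seed(spec$seed, {
    out <- switch(spec$kind,
      shift = {
        w <- ((spec$w %% n) + n) %% n
        if (w == 0L) {
          list(series = series, mask = logical(n))
        } else {
          y <- c(series[(w + 1L):n], series[seq_len(w)])
          mask <- logical(n)
          mask[(n - w + 1L):n] <- TRUE  # wrapped-around region
          list(series = y, mask = mask)
        }
      },
      scale = {
        y <- series * spec$s
        list(series = y, mask = y != series)
      },
      warp = {
        phi <- spec$anchors
        if (is.null(phi)) {
          k <- spec$knots
          src <- seq(1, n, length.out = k + 2L)
          jit <- stats::runif(k, -spec$max_warp, spec$max_warp) * n
          tgt <- src
          tgt[2:(k + 1L)] <- tgt[2:(k + 1L)] + jit
          tgt <- cummax(pmin(pmax(tgt, 1), n))  # enforce monotonicity
          phi <- cbind(src, tgt)
        }
        abort_if(any(diff(phi[, 1]) <= 0) || any(diff(phi[, 2]) < 0),
                 "invalid spec: non-monotone warp anchors")
        src_idx <- stats::approx(phi[, 1], phi[, 2], xout = seq_len(n),
                                 rule = 2)$y
        y <- stats::approx(seq_len(n), series, xout = src_idx, rule = 2)$y
        list(series = y, mask = y != series)
      },
      drift = {
        t <- (seq_len(n) - 1) / spec$fs
        d <- numeric(n)
        for (j in seq_along(spec$coef)) d <- d + spec$coef[j] * t^(j - 1)
        list(series = series + d, mask = d != 0)
      },
      noise = {
        if (spec$sigma <= 0) {
          list(series = series, mask = logical(n))
        } else {
          eps <- stats::rnorm(n, 0, spec$sigma)
          list(series = series + eps, mask = eps != 0)
        }
      },
      dropout = {
        fire <- stats::runif(n) < spec$p
        y <- series
        if (identical(spec$fill, "hold")) {
          last <- series[1L]
          for (i in seq_len(n)) {
            if (fire[i]) y[i] <- last else last <- y[i]
          }
        } else {
          y[fire] <- spec$fill
        }
        list(series = y, mask = y != series)
      })
    out
  })
}

#' Apply per-channel augmenters to a record
#'
#' Each spec is applied to its own channel only; when the spec's
#' `label_as_anomaly` is `TRUE` the channel labels are OR-ed with the
#' modified mask. Other channels (samples and labels) are untouched.
#'
#' @param record an `mwppg_record`.
#' @param specs named list mapping channel name to an [augmenter_spec()] (or
#'   a list of specs applied in order).
#' @return a new `mwppg_record`.
#' @export
augment_record <- function(record, specs) {
  if (!length(specs)) return(record)
  bad <- setdiff(names(specs), channel_names(record))
  abort_if(length(bad) > 0,
           paste0("unknown channels: ", paste(bad, collapse = ", ")))
  out <- record
  for (ch in names(specs)) {
    sp_list <- specs[[ch]]
    if (inherits(sp_list, "mwppg_augmenter_spec")) sp_list <- list(sp_list)
    for (sp in sp_list) {
      res <- apply_augmenter(out$samples[[ch]], sp)
      out$samples[[ch]] <- res$series
      if (sp$label_as_anomaly) {
        out$labels[[ch]] <- as.integer(out$labels[[ch]] | res$mask)
      }
    }
  }
  out
}
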
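ARTIFACT_KINDS <- c("motion", "contact_force", "sensor_dropout",
                    "sensor_clipping", "ambient_light", "low_temperature")

#' Artifact injection specification
#'
#' Describes one artifact episode to be injected into a record: the artifact
#' kind, the affected channels, the time window, a dimensionless magnitude
#' and kind-specific parameters.
#'
#' Kinds and their realizations (inside `[onset, onset + duration)` on masked
#' channels only):
#' * `motion` — multiplicative band-limited fluctuation (low-pass-filtered
#'   white noise, cutoff `params$cutoff_hz`, default 8 Hz, exponentiated),
#'   applied to all masked channels simultaneously with independent
#'   per-channel random gains; log-sd is `0.1 * magnitude * gain`.
#' * `contact_force` — the pulsatile (AC) component is scaled down towards
#'   the local baseline by factor `1 - magnitude` (AC/DC ratio reduction).
#' * `sensor_dropout` — samples are replaced by a constant (`params$fill`,
#'   default 0, or `"hold"` for last clean value) where an i.i.d.
#'   Bernoulli(`params$prob`, default 0.5) mask fires.
#' * `sensor_clipping` — pure saturation `pmin(x, params$clip_level)`
#'   (default: 70% quantile of the windowed samples); idempotent.
#' * `ambient_light` — additive offset plus a slow sinusoidal drift, with
#'   independent per-channel random gains; scale `0.1 * magnitude * mean`.
#' * `low_temperature` — global attenuation of the AC amplitude by factor
#'   `1 - magnitude` plus a 2% DC droop (severe-attenuation cold-tissue
#'   response).
#'
#' @param kind one of `r paste(ARTIFACT_KINDS, collapse = ", ")`.
#' @param channels channel names affected (the channel mask).
#' @param onset episode onset in seconds (>= 0).
#' @param duration episode duration in seconds.
#' @param magnitude dimensionless severity scale (>= 0).
#' @param params named list of kind-specific parameters (see above).
#' @param seed integer seed for the episode's randomness.
#' @return an object of class `mwppg_artifact_spec`.
#' @export
artifact_spec <- function(kind, channels = c("green", "red", "ir"),
                          onset = 0, duration = 1, magnitude = 1,
                          params = list(), seed = NULL) {
  abort_if(!kind %in% ARTIFACT_KINDS,
           paste0("unsupported artifact kind: ", kind))
  abort_if(onset < 0 || duration < 0, "onset and duration must be >= 0")
  abort_if(magnitude < 0, "magnitude must be >= 0")
  if (!is.null(params$prob)) {
    abort_if(params$prob < 0 || params$prob > 1,
             "dropout probability must be in [0,1]")
  }
  structure(list(kind = kind, channels = channels, onset = onset,
                 duration = duration, magnitude = magnitude,
                 params = params, seed = seed),
            class = "mwppg_artifact_spec")
}

#' Inject one artifact episode into a record
#'
#' Returns a new record in which the masked channels are modified inside the
#' episode window according to the artifact kind (see [artifact_spec()]), and
#' labels are set to 1 for exactly the samples whose values changed. Samples
#' outside the window and unmasked channels are bit-identical to the input.
#' The episode manifest is appended to `meta$artifacts`.
#'
#' @param record an `mwppg_record`.
#' @param spec an `mwppg_artifact_spec`.
#' @return a new `mwppg_record`.
#' @export
inject_artifact <- function(record, spec) {
  abort_if(!inherits(spec, "mwppg_artifact_spec"),
           "spec must be an mwppg_artifact_spec")
  fs <- record$sample_rate
  n <- record_length(record)
  i0 <- round(spec$onset * fs) + 1L
  i1 <- round((spec$onset + spec$duration) * fs)
  abort_if(i0 < 1L || i1 > n, "artifact window lies outside the record")
  missing_ch <- setdiff(spec$channels, channel_names(record))
  abort_if(length(missing_ch) > 0,
           paste0("unknown channels: ", paste(missing_ch, collapse = ", ")))
  if (i1 < i0) return(record)
  idx <- i0:i1

  out <- record
  with_seed(spec$seed, {
    nw <- length(idx)
    # shared stochastic structure so simultaneous channels co-vary
    shared <- switch(spec$kind,
      motion = {
        z <- stats::rnorm(nw)
        z <- butter_filter(z, fs, cutoff = spec$params$cutoff_hz %||% 8,
                           order = 4, passes = 1)
        s <- stats::sd(z)
        if (s > 0) z / s else z
      },
      ambient_light = {
        f <- spec$params$drift_hz %||% stats::runif(1, 0.05, 0.2)
        sin(2 * pi * f * (idx - i0) / fs + stats::runif(1, 0, 2 * pi))
      },
      NULL)
    for (ch in spec$channels) {
      x <- record$samples[[ch]]
      seg <- x[idx]
      new_seg <- switch(spec$kind,
        motion = {
          g <- stats::runif(1, 0.5, 1.5)
          seg * exp(0.1 * spec$magnitude * g * shared)
        },
        contact_force = {
          base <- rolling_baseline(seg, fs)
          base + (seg - base) * (1 - min(spec$magnitude, 1))
        },
        sensor_dropout = {
          p <- spec$params$prob %||% 0.5
          fire <- stats::runif(nw) < p
          fill <- spec$params$fill %||% 0
          s2 <- seg
          if (identical(fill, "hold")) {
            hold <- if (i0 > 1L) x[i0 - 1L] else seg[1L]
            s2[fire] <- hold
          } else {
            s2[fire] <- fill
          }
          s2
        },
        sensor_clipping = {
          lvl <- spec$params$clip_level %||% stats::quantile(seg, 0.7,
                                                             names = FALSE)
          pmin(seg, lvl)
        },
        ambient_light = {
          g <- stats::runif(1, 0.5, 1.5)
          amp <- 0.1 * spec$magnitude * g * mean(seg)
          seg + amp * (0.5 + shared)
        },
        low_temperature = {
          base <- rolling_baseline(seg, fs)
          0.98 * base + (seg - base) * (1 - min(spec$magnitude, 1))
        })
      modified <- new_seg != seg
      x[idx] <- new_seg
      out$samples[[ch]] <- x
      lab <- out$labels[[ch]]
      lab[idx][modified] <- 1L
      out$labels[[ch]] <- lab
    }
  })
  out$meta$artifacts <- c(out$meta$artifacts %||% list(),
                          list(unclass(spec)))
  out
}

# Centered moving-average baseline (~1 s), used to split a windowed segment
# into its local DC and AC parts without touching samples outside the window.
rolling_baseline <- function(seg, fs, width_s = 1) {
  k <- max(3L, round(width_s * fs))
  if (k %% 2 == 0) k <- k + 1L
  n <- length(seg)
  if (n <= k) return(rep(mean(seg), n))
  half <- k %/% 2
  padded <- c(rep(seg[1L], half), seg, rep(seg[n], half))
  cs <- cumsum(c(0, padded))
  (cs[(k + 1):(n + k)] - cs[1:n]) / k
}

#' Generate a labeled synthetic MW-PPG dataset
#'
#' Emits a list of fixed-length records whose total per-category durations
#' match a requested composition. The default composition is proportional to
#' the measured category durations of the emulated study dataset
#' (clean 150, motion 50, contact force 30, sensor 10, environment 20
#' minutes), scaled to `total_s`. Artifact-category records consist of a
#' clean background with 1-3 injected episodes of that category covering
#' roughly 30-60% of the record; sensor artifacts (dropout / clipping) are
#' injected on the green channel by default; environment records draw ambient
#' light or low temperature. Deterministic under a fixed seed.
#'
#' @param total_s total dataset duration in seconds (used with the default
#'   proportional composition).
#' @param composition named vector of per-category durations in seconds
#'   (categories among `clean`, `motion`, `contact_force`, `sensor`,
#'   `environment`); overrides `total_s`.
#' @param config generator configuration shared by all records.
#' @param record_s length of each emitted record in seconds (default 60).
#' @param seed integer master seed.
#' @return list of `mwppg_record` objects (empty for an empty composition).
#' @export
synth_dataset <- function(total_s = 600, composition = NULL,
                          config = synth_config(), record_s = 60,
                          seed = NULL) {
  if (is.null(composition)) {
    ref <- c(clean = 150, motion = 50, contact_force = 30,
             sensor = 10, environment = 20)
    composition <- ref / sum(ref) * total_s
  }
  abort_if(any(composition < 0), "composition durations must be >= 0")
  composition <- composition[composition > 0]
  if (!length(composition)) return(list())

  counts <- round(composition / record_s)
  counts[counts < 1] <- 1
  total_records <- sum(counts)
  seeds <- derive_seeds(seed, 4L * total_records)
  records <- vector("list", total_records)
  k <- 0L
  for (cat in names(composition)) {
    per_len <- composition[[cat]] / counts[[cat]]
    for (r in seq_len(counts[[cat]])) {
      k <- k + 1L
      cfg <- config
      cfg$duration <- per_len
      cfg$seed <- seeds[[4L * k - 3L]]
      rec <- generate_clean_record(cfg)
      rec$meta$category <- cat
      rec$meta$id <- sprintf("%s_%02d", cat, r)
      if (cat != "clean") {
        rec <- with_seed(seeds[[4L * k - 2L]], {
          inject_category_episodes(rec, cat, cfg,
                                   seeds[[4L * k - 1L]])
        })
      }
      records[[k]] <- rec
    }
  }
  records
}

# Draw and inject 1-3 artifact episodes of one category into a clean record.
# Called inside a with_seed() scope; per-episode seeds derive from ep_seed.
inject_category_episodes <- function(rec, category, config, ep_seed) {
  dur <- record_duration(rec)
  n_ep <- sample(1:3, 1)
  ep_seeds <- derive_seeds(ep_seed, n_ep)
  # target ~30-60% artifact coverage split across episodes
  cover <- stats::runif(1, 0.3, 0.6) * dur / n_ep
  slots <- seq(0, dur, length.out = n_ep + 1L)
  for (e in seq_len(n_ep)) {
    ep_dur <- min(cover, slots[e + 1L] - slots[e] - 0.2)
    if (ep_dur <= 0.5) next
    onset <- stats::runif(1, slots[e], slots[e + 1L] - ep_dur)
    spec <- switch(category,
      motion = artifact_spec("motion", channels = channel_names(rec),
                             onset = onset, duration = ep_dur,
                             magnitude = stats::runif(1, 0.8, 1.5),
                             seed = ep_seeds[[e]]),
      contact_force = artifact_spec("contact_force",
                                    channels = channel_names(rec),
                                    onset = onset, duration = ep_dur,
                                    magnitude = stats::runif(1, 0.6, 0.9),
                                    seed = ep_seeds[[e]]),
      sensor = {
        kind <- sample(c("sensor_dropout", "sensor_clipping"), 1)
        params <- if (kind == "sensor_dropout") {
          list(prob = stats::runif(1, 0.4, 0.8), fill = 0)
        } else {
          # clip just below the systolic excursion of the green channel
          list(clip_level = config$dc[["green"]] + 0.3 * config$ac[["green"]])
        }
        artifact_spec(kind, channels = "green", onset = onset,
                      duration = ep_dur, magnitude = 1, params = params,
                      seed = ep_seeds[[e]])
      },
      environment = {
        kind <- sample(c("ambient_light", "low_temperature"), 1)
        artifact_spec(kind, channels = channel_names(rec), onset = onset,
                      duration = ep_dur,
                      magnitude = stats::runif(1, 0.7, 1.3),
                      seed = ep_seeds[[e]])
      },
      stop("unknown dataset category: ", category))
    rec <- inject_artifact(rec, spec)
  }
  rec
}
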
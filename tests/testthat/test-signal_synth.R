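test_that("clean record has the configured size, beats and labels", {
  cfg <- quiet_config(duration = 60, hr = 90, seed = 7)
  rec <- generate_clean_record(cfg, keep_components = TRUE)
  expect_s3_class(rec, "mwppg_record")
  expect_equal(record_length(rec), 7500)
  expect_identical(names(rec$samples), c("green", "red", "ir"))
  expect_true(all(unlist(rec$labels) == 0L))

  # oracle: strict local maxima of the noise-free cardiac component above
  # the diastolic bump amplitude count the systolic peaks
  card <- rec$meta$components$cardiac
  n <- length(card)
  pk <- which(card[2:(n - 1)] > card[1:(n - 2)] &
                card[2:(n - 1)] > card[3:n]) + 1L
  systolic <- sum(card[pk] > 1.5 * cfg$dicrotic_rel_amp)
  expect_gte(systolic, 89)
  expect_lte(systolic, 91)
  # per beat: one systolic maximum and one diastolic bump maximum
  diastolic <- sum(card[pk] <= 1.5 * cfg$dicrotic_rel_amp)
  expect_gte(diastolic, systolic - 2)
  expect_lte(diastolic, systolic + 2)
})

test_that("duration 0 yields an empty record; bad configs error", {
  rec <- generate_clean_record(synth_config(duration = 0))
  expect_equal(record_length(rec), 0)
  expect_length(rec$labels$green, 0)
  expect_error(synth_config(sample_rate = 0), "sample_rate")
  expect_error(synth_config(duration = -1), "duration")
  expect_error(synth_config(ac = c(green = 2, red = 1, ir = 1),
                            dc = c(green = 1, red = 2, ir = 2)), "AC")
})

test_that("default config carries the emulated population parameters", {
  cfg <- synth_config()
  expect_equal(cfg$heart_rate_mean, 91.6)
  expect_equal(cfg$heart_rate_sd, 8.9)
  expect_equal(cfg$respiration_mean, 0.172)
  expect_equal(cfg$respiration_sd, 0.08)
  expect_equal(cfg$sample_rate, 125)
  expect_equal(cfg$adc_bits, 18)
})

test_that("generation is bit-reproducible for a fixed seed", {
  a <- generate_clean_record(synth_config(duration = 5, seed = 42))
  b <- generate_clean_record(synth_config(duration = 5, seed = 42))
  c <- generate_clean_record(synth_config(duration = 5, seed = 43))
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, c$samples))
})

test_that("clean-signal Welch spectrum peaks at the cardiac frequency", {
  for (seed in c(7, 11, 23)) {
    rec <- generate_clean_record(synth_config(duration = 60, seed = seed))
    f_hr <- rec$meta$heart_rate_bpm / 60
    sp <- welch_psd(rec$samples$green - mean(rec$samples$green),
                    rec$sample_rate, nperseg = 8 * rec$sample_rate)
    expect_lt(abs(sp$freq[which.max(sp$psd)] - f_hr), 0.2)
  }
})

test_that("artifact label bookkeeping is exact for every injector", {
  rec <- generate_clean_record(quiet_config(duration = 20, seed = 3))
  specs <- list(
    artifact_spec("motion", onset = 1, duration = 3, seed = 5),
    artifact_spec("contact_force", onset = 5, duration = 3,
                  magnitude = 0.7, seed = 5),
    artifact_spec("sensor_dropout", channels = "green", onset = 9,
                  duration = 2, params = list(prob = 0.5), seed = 5),
    artifact_spec("sensor_clipping", channels = "green", onset = 12,
                  duration = 2, seed = 5),
    artifact_spec("ambient_light", onset = 15, duration = 2, seed = 5),
    artifact_spec("low_temperature", onset = 17.5, duration = 2,
                  magnitude = 0.6, seed = 5))
  for (spec in specs) {
    out <- inject_artifact(rec, spec)
    for (ch in names(rec$samples)) {
      modified <- which(out$samples[[ch]] != rec$samples[[ch]])
      labeled <- which(out$labels[[ch]] == 1L)
      expect_identical(modified, labeled)
      if (!ch %in% spec$channels) {
        expect_identical(out$samples[[ch]], rec$samples[[ch]])
      }
    }
    # samples outside the window are bit-identical
    fs <- rec$sample_rate
    inside <- (round(spec$onset * fs) + 1L):round((spec$onset +
                                                     spec$duration) * fs)
    for (ch in spec$channels) {
      expect_identical(out$samples[[ch]][-inside],
                       rec$samples[[ch]][-inside])
    }
  }
})

test_that("dropout with probability 1 replaces and labels the whole span", {
  rec <- generate_clean_record(quiet_config(duration = 10, seed = 2))
  out <- inject_artifact(rec, artifact_spec("sensor_dropout",
                                            channels = "green", onset = 2,
                                            duration = 2,
                                            params = list(prob = 1),
                                            seed = 1))
  idx <- (2 * 125 + 1):(4 * 125)
  expect_true(all(out$samples$green[idx] == 0))
  expect_true(all(out$labels$green[idx] == 1L))
  expect_identical(out$samples$red, rec$samples$red)
  expect_identical(out$labels$ir, rec$labels$ir)
})

test_that("clipping saturates at the level, is idempotent, and spares other channels", {
  rec <- generate_clean_record(quiet_config(duration = 10, seed = 2))
  lvl <- stats::quantile(rec$samples$green, 0.5, names = FALSE)
  spec <- artifact_spec("sensor_clipping", channels = "green", onset = 1,
                        duration = 3, params = list(clip_level = lvl))
  once <- inject_artifact(rec, spec)
  twice <- inject_artifact(once, spec)
  expect_identical(once$samples, twice$samples)
  expect_identical(once$labels, twice$labels)
  idx <- (125 + 1):(4 * 125)
  expect_equal(max(once$samples$green[idx]), lvl)
  # pulsation survives on the untouched channels
  expect_identical(once$samples$red, rec$samples$red)
  expect_identical(once$samples$ir, rec$samples$ir)
})

test_that("zero-magnitude motion is the identity", {
  rec <- generate_clean_record(quiet_config(duration = 5, seed = 9))
  out <- inject_artifact(rec, artifact_spec("motion", onset = 1,
                                            duration = 2, magnitude = 0,
                                            seed = 4))
  expect_identical(out$samples, rec$samples)
  expect_identical(out$labels, rec$labels)
})

test_that("artifact windows and kinds are validated", {
  rec <- generate_clean_record(quiet_config(duration = 5))
  expect_error(inject_artifact(rec, artifact_spec("motion", onset = 4,
                                                  duration = 2)),
               "outside")
  expect_error(artifact_spec("sparkle"), "unsupported")
  expect_error(inject_artifact(rec, artifact_spec("motion",
                                                  channels = "uv",
                                                  onset = 0,
                                                  duration = 1)),
               "unknown channels")
  expect_error(artifact_spec("sensor_dropout", params = list(prob = 2)),
               "probability")
})

test_that("synth_dataset honours composition and defaults", {
  # single-category composition: one clean record, all labels 0
  recs <- synth_dataset(composition = c(clean = 60), seed = 1)
  expect_length(recs, 1)
  expect_true(all(unlist(recs[[1]]$labels) == 0L))
  expect_identical(synth_dataset(composition = numeric(0)), list())

  # default composition scales the 150/50/30/10/20 category minutes
  recs <- synth_dataset(total_s = 600, seed = 2)
  cats <- vapply(recs, function(r) r$meta$category, character(1))
  durs <- vapply(recs, record_duration, numeric(1))
  tot <- tapply(durs, cats, sum)
  expect_equal(unname(tot["clean"]), 600 * 150 / 260, tolerance = 0.11)
  expect_equal(unname(tot["motion"]), 600 * 50 / 260, tolerance = 0.11)
  expect_equal(unname(tot["contact_force"]), 600 * 30 / 260,
               tolerance = 0.11)
  expect_equal(unname(tot["sensor"]), 600 * 10 / 260, tolerance = 0.11)
  expect_equal(unname(tot["environment"]), 600 * 20 / 260, tolerance = 0.11)

  # sensor artifacts hit the green channel only
  sens <- recs[cats == "sensor"]
  for (r in sens) {
    expect_true(sum(r$labels$green) > 0)
    expect_true(sum(r$labels$red) + sum(r$labels$ir) == 0)
  }

  # deterministic under a fixed seed
  again <- synth_dataset(total_s = 600, seed = 2)
  expect_identical(lapply(recs, `[[`, "samples"),
                   lapply(again, `[[`, "samples"))
})

test_that("record CSV round-trips with sidecar metadata", {
  rec <- generate_clean_record(quiet_config(duration = 2, seed = 5))
  rec$meta$id <- "roundtrip"
  path <- tempfile(fileext = ".csv")
  write_record_csv(rec, path)
  back <- read_record_csv(path)
  expect_equal(back$samples$green, rec$samples$green, tolerance = 1e-12)
  expect_identical(back$labels, rec$labels)
  expect_equal(back$sample_rate, 125)
  expect_equal(back$meta$id, "roundtrip")
  unlink(c(path, paste0(path, ".json")))
})
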
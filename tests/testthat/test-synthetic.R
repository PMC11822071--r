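# Synthetic recording generator: stream structure, determinism, spectral
# content, dataset layout and CSV round trip.

test_that("a forced 3000 ms trial yields exactly 450 samples at 150 Hz", {
  r <- generate_trial(neutral_participant(),
                      default_condition_profiles()$short_easy,
                      seed = 3, duration_ms = 3000)
  expect_s3_class(r, "cogload_recording")
  expect_length(r$time, 450)
  expect_equal(diff(r$time), rep(1 / 150, 449), tolerance = 1e-12)
  lens <- vapply(list(r$gaze_x, r$gaze_y, r$pupil, r$hrp, r$gsr, r$valid),
                 length, 0L)
  expect_true(all(lens == 450))
})

test_that("the same seed reproduces an identical stream", {
  p <- neutral_participant()
  cond <- default_condition_profiles()$long_hard
  a <- generate_trial(p, cond, seed = 17)
  b <- generate_trial(p, cond, seed = 17)
  expect_identical(a, b)
})

test_that("non-positive forced durations are rejected", {
  expect_error(generate_trial(neutral_participant(),
                              default_condition_profiles()$short_easy,
                              seed = 1, duration_ms = 0),
               "positive")
  expect_error(generate_trial(neutral_participant(),
                              default_condition_profiles()$short_easy,
                              seed = 1, duration_ms = -100),
               "positive")
})

test_that("zero hf amplitude leaves pupil power above 1 Hz at the noise floor", {
  cond0 <- default_condition_profiles()$short_easy
  cond0$pupil_hf_amp_mm <- 0
  condh <- default_condition_profiles()$short_easy
  condh$pupil_hf_amp_mm <- 0.08
  band_power <- function(r) {
    x <- r$pupil - mean(r$pupil)
    n <- length(x)
    f <- (0:(n - 1)) * 150 / n
    pw <- Mod(stats::fft(x))^2 / n
    # one-sided band 1-4.5 Hz (excludes the slow oscillation)
    sum(pw[f > 1 & f < 4.5])
  }
  p0 <- band_power(generate_trial(neutral_participant(), cond0, seed = 5,
                                  duration_ms = 3000))
  ph <- band_power(generate_trial(neutral_participant(), condh, seed = 5,
                                  duration_ms = 3000))
  # white tracker noise (sd 0.01) puts ~n * sd^2 * bandfraction in the band
  noise_floor <- 450 * 0.01^2 * (3.5 / 75)
  expect_lt(p0, 5 * noise_floor)
  expect_gt(ph, 20 * p0)
})

test_that("the default design gives 44 trials per participant and a full dataset", {
  profs <- default_condition_profiles()
  n_mct <- sum(vapply(profs, function(p)
    if (p$task == "mental_calculation") p$n_trials else 0L, 0L))
  n_vst <- sum(vapply(profs, function(p)
    if (p$task == "visual_search") p$n_trials else 0L, 0L))
  expect_identical(n_mct, 24L)
  expect_identical(n_vst, 20L)

  ds <- generate_dataset(synthetic_config(n_participants = 3, seed = 11))
  expect_length(ds$recordings, 3 * 44)
  expect_identical(nrow(ds$participants), 3L)
  conds <- table(vapply(ds$recordings, `[[`, "", "condition"))
  expect_identical(as.integer(conds[c("short_easy", "serial_hit")]),
                   c(3L * 6L, 3L * 5L))
  keys <- vapply(ds$recordings, function(r)
    paste(r$participant_id, r$trial_id), "")
  expect_false(anyDuplicated(keys) > 0)
})

test_that("dataset generation is reproducible and seeds differ", {
  a <- generate_dataset(synthetic_config(n_participants = 2, seed = 4))
  b <- generate_dataset(synthetic_config(n_participants = 2, seed = 4))
  c <- generate_dataset(synthetic_config(n_participants = 2, seed = 5))
  expect_identical(a$recordings, b$recordings)
  expect_false(identical(a$recordings[[1]]$gaze_x, c$recordings[[1]]$gaze_x))
})

test_that("effect size zero collapses all condition profiles to one", {
  profs <- resolve_profiles(default_condition_profiles(), 0)
  for (f in c("fix_dur_mean_ms", "sacc_amp_px" = "sacc_amp_mean_px",
              "pupil_offset_pct", "ibi_sd_s", "gsr_level_ohm",
              "duration_mean_ms", "pupil_hf_amp_mm")) {
    v <- vapply(profs, `[[`, 0, f)
    expect_equal(max(v) - min(v), 0, tolerance = 1e-9)
  }
  # effect size 1 is the identity
  expect_identical(resolve_profiles(default_condition_profiles(), 1),
                   default_condition_profiles())
})

test_that("profile and config validation rejects out-of-range values", {
  expect_error(condition_profile("short_easy", "mental_calculation", "low",
                                 0, 2700, 150, 366, 126, 240, 98, 1.5,
                                 0.1, 0.02, 0.85, 0.2, 3e5),
               "n_trials")
  expect_error(condition_profile("short_easy", "mental_calculation", "low",
                                 6, 2700, 150, 366, 126, 240, 98, 1.5,
                                 0.1, 0.02, 2.0, 0.2, 3e5),
               "ibi_mean")
  expect_error(synthetic_config(n_participants = 1), "n_participants")
  expect_error(synthetic_config(effect_size = -1), "effect_size")
})

test_that("detected event means recover the configured distributions", {
  # >= 200 trials per condition, neutral participant, raw detected events
  for (lbl in c("short_easy", "serial_hit")) {
    cond <- default_condition_profiles()[[lbl]]
    set.seed(42)
    durs <- c(); amps <- c()
    for (i in 1:200) {
      r <- generate_trial(neutral_participant(), cond)
      fx <- detect_fixations(r)
      durs <- c(durs, fx$duration_ms)
      amps <- c(amps, saccades_between(fx)$amplitude_px)
    }
    se_d <- sd(durs) / sqrt(length(durs))
    se_a <- sd(amps) / sqrt(length(amps))
    expect_lt(abs(mean(durs) - cond$fix_dur_mean_ms), 3 * se_d)
    expect_lt(abs(mean(amps) - cond$sacc_amp_mean_px), 3 * se_a)
  }
})

test_that("recordings survive a CSV round trip losslessly", {
  ds <- generate_dataset(synthetic_config(n_participants = 2, seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recordings(ds, path)
  back <- read_recordings(path)
  expect_length(back$recordings, length(ds$recordings))
  for (i in c(1, 25, 88)) {
    a <- ds$recordings[[i]]; b <- back$recordings[[i]]
    for (f in c("time", "gaze_x", "gaze_y", "pupil", "hrp", "gsr"))
      expect_equal(a[[f]], b[[f]], tolerance = 1e-9)
    expect_identical(a$valid, b$valid)
    expect_identical(a$condition, b$condition)
    expect_equal(a$baseline_pupil, b$baseline_pupil, tolerance = 1e-9)
  }
})

test_that("malformed recordings files are rejected with clear diagnostics", {
  ds <- generate_dataset(synthetic_config(n_participants = 2, seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recordings(ds, path)

  dt <- as.data.frame(data.table::fread(path))
  no_pupil <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(dt[, setdiff(names(dt), "pupil_mm")], no_pupil)
  expect_error(read_recordings(no_pupil), "pupil_mm")

  scrambled <- withr::local_tempfile(fileext = ".csv")
  dt2 <- dt
  dt2$time_s[2] <- dt2$time_s[1] - 1
  data.table::fwrite(dt2, scrambled)
  expect_error(read_recordings(scrambled), "non-monotone")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), empty)
  expect_error(read_recordings(empty), "empty|column")
})
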
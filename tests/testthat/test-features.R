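# Per-trial predictors: K coefficient, pupil dilation, IBI/HRV, GSR, and
# the assembled feature table.

test_that("K is zero at the scope means and matches hand arithmetic", {
  st <- list(mu_d = 400, sd_d = 200, mu_a = 20, sd_a = 10)
  expect_equal(k_coefficient(c(400, 400), c(20, 20), st)$k, 0)
  res <- k_coefficient(c(600, 600), c(10, 20), st)
  expect_equal(res$k_i, c(2, 1))
  expect_equal(res$k, 1.5)
})

test_that("K flips sign when the two z-scored series swap roles", {
  set.seed(3)
  d <- rlnorm(20, 6, 0.3); a <- rlnorm(20, 5, 0.4)
  st <- k_standardization(d, a)
  st_swapped <- list(mu_d = st$mu_a, sd_d = st$sd_a,
                     mu_a = st$mu_d, sd_a = st$sd_d)
  k1 <- k_coefficient(d, a, st)$k_i
  k2 <- k_coefficient(a, d, st_swapped)$k_i
  expect_equal(k2, -k1)
})

test_that("K is invariant under affine rescaling of either series", {
  set.seed(8)
  d <- rlnorm(30, 6, 0.3); a <- rlnorm(30, 5, 0.4)
  k0 <- k_coefficient(d, a, k_standardization(d, a))$k_i
  d2 <- 3.7 * d + 120
  k1 <- k_coefficient(d2, a, k_standardization(d2, a))$k_i
  expect_equal(k1, k0, tolerance = 1e-12)
  a2 <- 0.25 * a + 5
  k2 <- k_coefficient(d, a2, k_standardization(d, a2))$k_i
  expect_equal(k2, k0, tolerance = 1e-12)
})

test_that("scope-wide mean of per-event K values is exactly zero", {
  set.seed(12)
  d <- rlnorm(200, 6, 0.35); a <- rlnorm(200, 5, 0.5)
  st <- k_standardization(d, a)
  expect_equal(mean(k_coefficient(d, a, st)$k_i), 0, tolerance = 1e-12)
})

test_that("K rejects degenerate standardization and flags empty trials", {
  expect_error(k_standardization(c(1, 1), c(2, 3)), "zero variance")
  st <- list(mu_d = 1, sd_d = 1, mu_a = 1, sd_a = 0)
  expect_error(k_coefficient(1, 1, st), "SDs")
  stg <- list(mu_d = 1, sd_d = 1, mu_a = 1, sd_a = 1)
  expect_warning(res <- k_coefficient(numeric(0), numeric(0), stg), "pairs")
  expect_true(is.na(res$k))
})

test_that("pupil dilation is the percent change against baseline", {
  expect_equal(pupil_dilation(rep(4.2, 100), 4.0), 5.0)
  expect_equal(pupil_dilation(rep(3.3, 50), 3.3), 0)
  expect_error(pupil_dilation(rep(4, 10), 0), "baseline")
  expect_warning(v <- pupil_dilation(rep(NA_real_, 10), 4), "valid")
  expect_true(is.na(v))
})

test_that("IBIs recover an exact pulse period within one sample spacing", {
  hrp <- make_pulse_train(rep(0.75, 12))
  ib <- ibi_from_hrp(hrp)
  expect_s3_class(ib, "cogload_ibi")
  expect_length(ib$ibis, 12)
  expect_true(all(abs(ib$ibis - 0.75) <= 1 / 150 + 1e-9))
  expect_length(ib$smoothed_ibis, length(ib$ibis))
})

test_that("constant and flat pulse signals yield no IBIs, with warnings", {
  expect_warning(ib <- ibi_from_hrp(rep(0.5, 600)), "peaks")
  expect_length(ib$ibis, 0)
  w <- capture_warnings(ibi_from_hrp(rnorm(100)))
  expect_true(any(grepl("2 s", w)))
})

test_that("3-beat smoothing shrinks its window at the edges", {
  expect_equal(smooth_ibis(c(0.8, 0.9, 1.0)), c(0.85, 0.9, 0.95))
  expect_equal(smooth_ibis(c(0.8, 1.0)), c(0.8, 1.0))
  expect_equal(smooth_ibis(c(0.6, 0.9, 1.2, 0.9)),
               c(0.75, 0.9, 1.0, 1.05))
})

test_that("HRV is the sample SD of smoothed IBIs with its scaling law", {
  expect_equal(hrv_sdnn(rep(0.8, 20)), 0)
  expect_equal(hrv_sdnn(c(0.85, 0.90, 0.95)), 0.05)
  set.seed(4)
  x <- abs(rnorm(30, 0.8, 0.1))
  expect_equal(hrv_sdnn(3 * x), 3 * hrv_sdnn(x), tolerance = 1e-12)
  expect_warning(v <- hrv_sdnn(numeric(0)), "IBIs")
  expect_true(is.na(v))
})

test_that("GSR level averages the trial and flags implausible resistance", {
  g <- gsr_level(rep(350000, 200))
  expect_equal(as.numeric(g), 350000)
  expect_false(attr(g, "out_of_range"))
  ramp <- gsr_level(seq(3e5, 5e5, length.out = 451))
  expect_equal(as.numeric(ramp), 4e5, tolerance = 1)
  low <- gsr_level(rep(5000, 100))
  expect_true(attr(low, "out_of_range"))
  expect_warning(v <- gsr_level(c(NA, NA)), "valid")
  expect_true(is.na(v))
})

test_that("the feature table has one labelled row per trial with missingness flags", {
  ds <- generate_dataset(synthetic_config(n_participants = 3, seed = 21))
  ft <- build_feature_table(ds)
  expect_identical(nrow(ft), 3L * 44L)
  expect_setequal(unique(ft$group), c("mc_low", "mc_high", "vs_low", "vs_high"))
  # group label is a pure function of condition
  expect_true(all(ft$group[ft$condition %in% c("short_easy", "short_hard")]
                  == "mc_low"))
  expect_true(all(ft$group[ft$condition %in% c("serial_hit", "serial_reject")]
                  == "vs_high"))
  expect_true(all(c("fix_dur_ms_missing", "hrv_s_missing",
                    "lhipa_missing") %in% names(ft)))
  expect_identical(ft$hrv_s_missing, !is.finite(ft$hrv_s))
  expect_true(all(ft$dspan_backward ==
                  ds$participants$dspan_backward[
                    match(ft$participant_id,
                          ds$participants$participant_id)]))
})

test_that("duplicate trial ids abort feature extraction", {
  ds <- generate_dataset(synthetic_config(n_participants = 2, seed = 2))
  ds$recordings[[2]]$trial_id <- ds$recordings[[1]]$trial_id
  expect_error(build_feature_table(ds), "duplicate")
})

test_that("a hand-built trial reproduces independently computed features", {
  fs <- 150
  # gaze: three 400 ms fixations at known centres, instantaneous jumps
  centers <- rbind(c(300, 300), c(600, 300), c(600, 700))
  n_per <- 60
  set.seed(14)
  gx <- c(); gy <- c()
  for (i in 1:3) {
    gx <- c(gx, rnorm(n_per, centers[i, 1], 1))
    gy <- c(gy, rnorm(n_per, centers[i, 2], 1))
  }
  n <- 3 * n_per
  hrp <- make_pulse_train(rep(0.8, 4), start = 0.1)[1:n]
  rec <- structure(
    list(participant_id = "P01", trial_id = "T01",
         condition = "short_easy", task = "mental_calculation",
         load = "low", baseline_pupil = 4.0,
         time = (0:(n - 1)) / fs, gaze_x = gx, gaze_y = gy,
         pupil = rep(4.2, n), hrp = hrp, gsr = rep(3.5e5, n),
         valid = rep(TRUE, n)),
    class = "cogload_recording")
  ds <- structure(list(recordings = list(rec),
                       participants = data.frame(participant_id = "P01",
                                                 dspan_backward = 7L)),
                  class = "cogload_dataset")
  ft <- suppressWarnings(build_feature_table(ds))
  expect_identical(nrow(ft), 1L)
  expect_equal(ft$fix_dur_ms, 400, tolerance = 1)
  expect_equal(ft$sacc_amp_px, mean(c(300, 400)), tolerance = 3)
  expect_equal(ft$pupil_dilation_pct, 100 * (4.2 - 4.0) / 4.0,
               tolerance = 1e-9)
  expect_equal(ft$gsr_ohm, 3.5e5, tolerance = 1e-6)
  # constant pupil -> LHIPA contract value 0
  expect_identical(ft$lhipa, 0)
})

test_that("a trial without pulse peaks keeps its row with the HRV flag set", {
  ds <- generate_dataset(synthetic_config(n_participants = 2, seed = 6))
  ds$recordings[[1]]$hrp <- rep(0, length(ds$recordings[[1]]$hrp))
  ft <- build_feature_table(ds)
  expect_identical(nrow(ft), 2L * 44L)
  r1 <- ft[ft$participant_id == ds$recordings[[1]]$participant_id &
             ft$trial_id == ds$recordings[[1]]$trial_id, ]
  expect_true(r1$hrv_s_missing)
  expect_true(is.na(r1$hrv_s))
  expect_false(r1$fix_dur_ms_missing)
})
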
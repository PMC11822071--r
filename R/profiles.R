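#' Condition profile for the synthetic-recording generator
#'
#' A condition profile holds the generative parameters for one experimental
#' cell. The mental-calculation task (MCT, inducing intrinsic load) has four
#' cells -- short/long operands crossed with easy/hard carrying -- and the
#' visual-search task (VST, inducing extraneous load) has four cells --
#' parallel/serial search crossed with target present (hit) / absent
#' (reject). Short calculations and parallel search are the low-load levels.
#'
#' @param label Condition label, one of `"short_easy"`, `"short_hard"`,
#'   `"long_easy"`, `"long_hard"`, `"parallel_hit"`, `"parallel_reject"`,
#'   `"serial_hit"`, `"serial_reject"`.
#' @param task `"mental_calculation"` or `"visual_search"`.
#' @param load `"low"` or `"high"`.
#' @param n_trials Trials per participant in this cell.
#' @param duration_mean_ms,duration_jitter_ms Target trial duration (the
#'   analysed response window) and its jitter, ms. MCT durations are drawn
#'   normal (the answer screen is capped near 3 s); VST durations are drawn
#'   lognormal because they are response-terminated.
#' @param fix_dur_mean_ms,fix_dur_sd_ms Lognormal mean/SD of single-fixation
#'   durations, ms.
#' @param sacc_amp_mean_px,sacc_amp_sd_px Lognormal mean/SD of saccade
#'   amplitudes, px.
#' @param pupil_offset_pct Mean pupil change during the trial relative to the
#'   participant's pre-task baseline, percent (positive = dilation).
#' @param pupil_lf_amp_mm Amplitude of the slow (<= 0.5 Hz) pupil
#'   oscillation, mm.
#' @param pupil_hf_amp_mm Standard deviation of the band-limited 1.2-4 Hz
#'   pupil component, mm -- effortful pupillary activity. At a 150 Hz
#'   sampling rate this band loads the numerator of the trial-level
#'   low/high wavelet ratio, so larger values raise the LHIPA feature
#'   (matching the direction observed in the study data).
#' @param ibi_mean_s,ibi_sd_s Mean and SD of inter-beat intervals, seconds.
#'   The SD is realised mostly as a slow sinusoidal modulation (respiratory
#'   sinus arrhythmia) so that 3-beat smoothing preserves it.
#' @param gsr_level_ohm Tonic skin-resistance level, Ohms.
#' @return An object of class `cogload_condition` (a validated list).
#' @seealso [default_condition_profiles()]
#' @export
condition_profile <- function(label, task, load, n_trials,
                              duration_mean_ms, duration_jitter_ms,
                              fix_dur_mean_ms, fix_dur_sd_ms,
                              sacc_amp_mean_px, sacc_amp_sd_px,
                              pupil_offset_pct,
                              pupil_lf_amp_mm, pupil_hf_amp_mm,
                              ibi_mean_s, ibi_sd_s, gsr_level_ohm) {
  label <- match.arg(label, c("short_easy", "short_hard", "long_easy",
                              "long_hard", "parallel_hit", "parallel_reject",
                              "serial_hit", "serial_reject"))
  task <- match.arg(task, c("mental_calculation", "visual_search"))
  load <- match.arg(load, c("low", "high"))
  if (!is.numeric(n_trials) || n_trials < 1)
    stop("n_trials must be >= 1")
  scales <- c(duration_mean_ms = duration_mean_ms,
              fix_dur_mean_ms = fix_dur_mean_ms,
              fix_dur_sd_ms = fix_dur_sd_ms,
              sacc_amp_mean_px = sacc_amp_mean_px,
              sacc_amp_sd_px = sacc_amp_sd_px,
              gsr_level_ohm = gsr_level_ohm)
  if (any(scales <= 0))
    stop("distribution scales must be > 0: ",
         paste(names(scales)[scales <= 0], collapse = ", "))
  if (ibi_mean_s < 0.4 || ibi_mean_s > 1.5)
    stop("ibi_mean_s must lie in [0.4, 1.5] s")
  if (ibi_sd_s < 0) stop("ibi_sd_s must be >= 0")
  if (duration_jitter_ms < 0) stop("duration_jitter_ms must be >= 0")
  if (pupil_lf_amp_mm < 0 || pupil_hf_amp_mm < 0)
    stop("pupil oscillation amplitudes must be >= 0")
  structure(
    list(label = label, task = task, load = load,
         n_trials = as.integer(n_trials),
         duration_mean_ms = duration_mean_ms,
         duration_jitter_ms = duration_jitter_ms,
         fix_dur_mean_ms = fix_dur_mean_ms, fix_dur_sd_ms = fix_dur_sd_ms,
         sacc_amp_mean_px = sacc_amp_mean_px,
         sacc_amp_sd_px = sacc_amp_sd_px,
         pupil_offset_pct = pupil_offset_pct,
         pupil_lf_amp_mm = pupil_lf_amp_mm,
         pupil_hf_amp_mm = pupil_hf_amp_mm,
         ibi_mean_s = ibi_mean_s, ibi_sd_s = ibi_sd_s,
         gsr_level_ohm = gsr_level_ohm),
    class = "cogload_condition"
  )
}

#' Default condition profiles
#'
#' The eight experimental cells with generative parameters calibrated to the
#' published per-condition feature means: six MCT trials per cell, five VST
#' trials per cell (24 + 20 trials per participant). The calibration is
#' approximate by construction -- published tables report feature-level
#' statistics after event detection and winsorization, not generative
#' parameters.
#'
#' @return Named list of eight [condition_profile()] objects.
#' @export
default_condition_profiles <- function() {
  p <- list(
    condition_profile("short_easy", "mental_calculation", "low", 6,
                      2700, 150, 366, 126, 240, 98,
                      1.52, 0.10, 0.020, 0.85, 0.24, 354849),
    condition_profile("short_hard", "mental_calculation", "low", 6,
                      2700, 150, 440, 154, 286, 95,
                      2.80, 0.10, 0.030, 0.85, 0.16, 354764),
    condition_profile("long_easy", "mental_calculation", "high", 6,
                      2700, 150, 425, 156, 301, 99,
                      3.30, 0.10, 0.045, 0.85, 0.17, 348591),
    condition_profile("long_hard", "mental_calculation", "high", 6,
                      2700, 150, 429, 142, 325, 97,
                      4.72, 0.10, 0.060, 0.85, 0.12, 346919),
    condition_profile("parallel_hit", "visual_search", "low", 5,
                      2600, 500, 407, 153, 249, 106,
                      -3.59, 0.10, 0.020, 0.85, 0.014, 603614),
    condition_profile("parallel_reject", "visual_search", "low", 5,
                      2600, 500, 452, 176, 326, 74,
                      -3.11, 0.10, 0.030, 0.85, 0.012, 1157920),
    condition_profile("serial_hit", "visual_search", "high", 5,
                      4500, 800, 546, 242, 284, 101,
                      -2.26, 0.10, 0.045, 0.85, 0.010, 892198),
    condition_profile("serial_reject", "visual_search", "high", 5,
                      4500, 800, 529, 196, 305, 93,
                      -3.19, 0.10, 0.060, 0.85, 0.010, 609290)
  )
  names(p) <- vapply(p, `[[`, "", "label")
  p
}

# Numeric profile fields that carry between-condition differences; the
# effect-size multiplier interpolates each toward its across-cell mean.
.scaled_profile_fields <- c(
  "duration_mean_ms", "duration_jitter_ms",
  "fix_dur_mean_ms", "fix_dur_sd_ms",
  "sacc_amp_mean_px", "sacc_amp_sd_px",
  "pupil_offset_pct", "pupil_lf_amp_mm", "pupil_hf_amp_mm",
  "ibi_mean_s", "ibi_sd_s", "gsr_level_ohm"
)

#' Scale between-condition differences of a profile set
#'
#' Every numeric generative field is moved toward its mean across the eight
#' cells: `value' = mean + effect_size * (value - mean)`. `effect_size = 1`
#' returns the profiles unchanged; `effect_size = 0` makes all conditions
#' generatively identical (a null dataset in which no classifier should beat
#' the largest class prior).
#'
#' @param profiles Named list of [condition_profile()] objects.
#' @param effect_size Non-negative multiplier.
#' @return Profiles with scaled fields.
#' @export
resolve_profiles <- function(profiles, effect_size = 1) {
  if (!is.numeric(effect_size) || effect_size < 0)
    stop("effect_size must be >= 0")
  if (effect_size == 1) return(profiles)
  for (f in .scaled_profile_fields) {
    v <- vapply(profiles, `[[`, 0, f)
    v2 <- mean(v) + effect_size * (v - mean(v))
    v2 <- pmax(v2, 1e-8)
    for (i in seq_along(profiles)) profiles[[i]][[f]] <- v2[[i]]
  }
  profiles
}

#' Synthetic dataset configuration
#'
#' @param n_participants Number of simulated participants (>= 2; the study
#'   design has 33).
#' @param profiles Condition profiles, see [default_condition_profiles()].
#' @param screen A [screen_geometry()] object.
#' @param seed Integer seed governing all randomness of the generator.
#' @param effect_size Multiplier on all between-condition differences,
#'   see [resolve_profiles()]. `0` gives a null dataset.
#' @param dspan_mean,dspan_sd Normal parameters for the backward digit-span
#'   score (rounded to integer), defaults matching the study sample
#'   (M = 7.24, SD = 1.02).
#' @param scatter_sd_deg Within-fixation gaze scatter SD in degrees of
#'   visual angle.
#' @param dropout_rate Per-sample probability that the gaze sample is marked
#'   invalid (tracking loss). Default 0.
#' @return An object of class `cogload_synth_config`.
#' @export
synthetic_config <- function(n_participants = 33,
                             profiles = default_condition_profiles(),
                             screen = screen_geometry(),
                             seed = 1L,
                             effect_size = 1,
                             dspan_mean = 7.24, dspan_sd = 1.02,
                             scatter_sd_deg = 0.08,
                             dropout_rate = 0) {
  if (!is.numeric(n_participants) || n_participants < 2)
    stop("n_participants must be >= 2")
  if (!is.numeric(effect_size) || effect_size < 0)
    stop("effect_size must be >= 0")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  stopifnot(inherits(screen, "cogload_screen"))
  lapply(profiles, function(p)
    if (!inherits(p, "cogload_condition")) stop("invalid condition profile"))
  structure(
    list(n_participants = as.integer(n_participants),
         profiles = profiles, screen = screen,
         seed = as.integer(seed), effect_size = effect_size,
         dspan_mean = dspan_mean, dspan_sd = dspan_sd,
         scatter_sd_deg = scatter_sd_deg,
         dropout_rate = dropout_rate),
    class = "cogload_synth_config"
  )
}

#' Draw a table of participant profiles
#'
#' Backward digit-span scores are drawn Normal(`dspan_mean`, `dspan_sd`) and
#' rounded; each participant also receives stable physiological traits
#' (pupil baseline, multiplicative offsets on oculometric and biometric
#' levels) that induce between-participant variance, without which
#' split-half reliability would be degenerate.
#'
#' @param config A [synthetic_config()] object.
#' @return `data.frame` with one row per participant.
#' @export
generate_participants <- function(config) {
  stopifnot(inherits(config, "cogload_synth_config"))
  n <- config$n_participants
  data.frame(
    participant_id = sprintf("P%02d", seq_len(n)),
    dspan_backward = pmax(0L, as.integer(round(
      stats::rnorm(n, config$dspan_mean, config$dspan_sd)))),
    pupil_baseline = pmin(7, pmax(2.5, stats::rnorm(n, 4.5, 0.4))),
    fix_mult = stats::rlnorm(n, 0, 0.12),
    sacc_mult = stats::rlnorm(n, 0, 0.10),
    gsr_mult = stats::rlnorm(n, 0, 0.50),
    hrv_mult = stats::rlnorm(n, 0, 0.25),
    hf_mult = stats::rlnorm(n, 0, 0.15),
    ibi_shift = stats::rnorm(n, 0, 0.06),
    dilation_shift = stats::rnorm(n, 0, 1.5),
    seed_offset = seq_len(n),
    stringsAsFactors = FALSE
  )
}
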
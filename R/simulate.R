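# Synthetic multimodal trial generator. A trial is a scanpath of complete
# fixations separated by short ballistic saccades (the analysed response
# window ends with a response, i.e. at a fixation boundary), plus pupil,
# pulse and skin-resistance channels sharing the 150 Hz clock.

.lnorm_pars <- function(m, s) {
  sdlog <- sqrt(log1p((s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# Draw target response-window duration (ms) for a condition.
.draw_duration <- function(condition) {
  if (condition$duration_jitter_ms == 0) {
    d <- condition$duration_mean_ms
  } else if (condition$task == "visual_search") {
    p <- .lnorm_pars(condition$duration_mean_ms, condition$duration_jitter_ms)
    d <- stats::rlnorm(1, p$meanlog, p$sdlog)
  } else {
    d <- stats::rnorm(1, condition$duration_mean_ms,
                      condition$duration_jitter_ms)
  }
  min(max(d, 2200), 9000)
}

# Saccade transition time from the main sequence: ~21 ms + 2.2 ms/deg.
.saccade_duration_ms <- function(amp_px, px_per_deg) {
  21 + 2.2 * amp_px / px_per_deg
}

# Pick a landing point at exact distance `amp` from `pos` inside the screen
# margins; falls back to heading toward screen centre.
.saccade_target <- function(pos, amp, screen, margin = 60) {
  for (k in 1:20) {
    th <- stats::runif(1, 0, 2 * pi)
    cand <- pos + amp * c(cos(th), sin(th))
    if (cand[1] >= margin && cand[1] <= screen$width_px - margin &&
        cand[2] >= margin && cand[2] <= screen$height_px - margin)
      return(cand)
  }
  ctr <- c(screen$width_px, screen$height_px) / 2
  u <- ctr - pos
  u <- u / sqrt(sum(u^2))
  pos + amp * u
}

# Band-limited 1.2-4 Hz noise with unit SD (zero vector if too short).
.bandlimited_hf <- function(n, fs) {
  if (n < 24) return(numeric(n))
  bf <- signal::butter(2, c(1.2, 4) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 2 * fs))
  x <- x[(fs + 1):(fs + n)]
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s
}

#' Generate one synthetic multimodal trial
#'
#' Produces a 150 Hz recording of gaze position, pupil diameter, a unitless
#' heart-rate pulse channel and skin resistance for one trial of one
#' participant. Gaze alternates stationary fixation clusters (durations
#' lognormal per condition, Gaussian scatter) with ballistic transitions
#' whose amplitudes are lognormal per condition; the pupil is baseline +
#' task-evoked offset + slow sinusoid + band-limited 1.2-4 Hz component +
#' white noise; the pulse channel is a raised-cosine pulse train whose
#' inter-beat intervals carry a slow sinusoidal modulation; skin resistance
#' is the tonic level plus slow drift.
#'
#' Unless `duration_ms` is forced, the trial ends at the boundary of the
#' first fixation whose offset reaches the drawn target duration, so every
#' fixation in the stream is complete (responses terminate a trial at the
#' end of a fixation on the answer).
#'
#' @param participant One row of [generate_participants()] (data.frame or
#'   list).
#' @param condition A [condition_profile()].
#' @param screen A [screen_geometry()].
#' @param seed Optional integer; if supplied, `set.seed(seed)` is called so
#'   the trial is reproducible in isolation.
#' @param duration_ms Optional forced duration; the last fixation is then
#'   truncated at the cut-off. Must be positive.
#' @param fs Sampling rate, Hz.
#' @param scatter_sd_deg Within-fixation gaze scatter SD, degrees.
#' @param dropout_rate Per-sample probability of an invalid gaze sample.
#' @param trial_id Identifier stored in the stream.
#' @return An object of class `cogload_recording`: a list with scalar fields
#'   (`participant_id`, `trial_id`, `condition`, `task`, `load`,
#'   `baseline_pupil`) and equal-length sample vectors `time`, `gaze_x`,
#'   `gaze_y`, `pupil`, `hrp`, `gsr`, `valid`.
#' @export
generate_trial <- function(participant, condition,
                           screen = screen_geometry(),
                           seed = NULL, duration_ms = NULL, fs = 150,
                           scatter_sd_deg = 0.08, dropout_rate = 0,
                           trial_id = "T01") {
  stopifnot(inherits(condition, "cogload_condition"),
            inherits(screen, "cogload_screen"))
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(duration_ms) && duration_ms <= 0)
    stop("trial duration must be positive, got ", duration_ms, " ms")
  p <- as.list(participant)
  defaults <- list(pupil_baseline = 4.5, fix_mult = 1, sacc_mult = 1,
                   gsr_mult = 1, hrv_mult = 1, hf_mult = 1,
                   ibi_shift = 0, dilation_shift = 0,
                   participant_id = "P00")
  for (nm in names(defaults)) if (is.null(p[[nm]])) p[[nm]] <- defaults[[nm]]

  target_ms <- if (is.null(duration_ms)) .draw_duration(condition) else duration_ms

  ## ---- scanpath: complete fixations + transitions -------------------------
  trial_mult <- stats::rlnorm(1, 0, 0.12)
  fpars <- .lnorm_pars(condition$fix_dur_mean_ms * p$fix_mult * trial_mult,
                       condition$fix_dur_sd_ms)
  apars <- .lnorm_pars(condition$sacc_amp_mean_px * p$sacc_mult,
                       condition$sacc_amp_sd_px)
  pos <- c(stats::runif(1, 0.3, 0.7) * screen$width_px,
           stats::runif(1, 0.35, 0.65) * screen$height_px)
  ev_on <- ev_off <- ev_x0 <- ev_y0 <- ev_x1 <- ev_y1 <- numeric(0)
  ev_fix <- logical(0)
  cum <- 0
  repeat {
    d <- stats::rlnorm(1, fpars$meanlog, fpars$sdlog)
    ev_on <- c(ev_on, cum); ev_off <- c(ev_off, cum + d)
    ev_x0 <- c(ev_x0, pos[1]); ev_y0 <- c(ev_y0, pos[2])
    ev_x1 <- c(ev_x1, pos[1]); ev_y1 <- c(ev_y1, pos[2])
    ev_fix <- c(ev_fix, TRUE)
    cum <- cum + d
    if (cum >= target_ms) break
    a <- stats::rlnorm(1, apars$meanlog, apars$sdlog)
    tau <- .saccade_duration_ms(a, screen$px_per_deg)
    nxt <- .saccade_target(pos, a, screen)
    ev_on <- c(ev_on, cum); ev_off <- c(ev_off, cum + tau)
    ev_x0 <- c(ev_x0, pos[1]); ev_y0 <- c(ev_y0, pos[2])
    ev_x1 <- c(ev_x1, nxt[1]); ev_y1 <- c(ev_y1, nxt[2])
    ev_fix <- c(ev_fix, FALSE)
    cum <- cum + tau
    pos <- nxt
  }
  dur_s <- if (is.null(duration_ms)) cum / 1000 else duration_ms / 1000
  n <- round(dur_s * fs)
  if (n < 2) stop("trial too short after discretization (", n, " samples)")
  tms <- (seq_len(n) - 1) / fs * 1000

  idx <- findInterval(tms, ev_on)
  frac <- (tms - ev_on[idx]) / (ev_off[idx] - ev_on[idx])
  frac[ev_fix[idx]] <- 0
  # Saccadic flight samples are kept in the interior of the path, at least
  # ~1.1 deg from either endpoint; sub-2.2 deg saccades complete between
  # samples. Real velocity profiles are not emulated (see vignette).
  margin <- 1.1 * screen$px_per_deg
  amp_ev <- sqrt((ev_x1 - ev_x0)^2 + (ev_y1 - ev_y0)^2)[idx]
  in_flight <- !ev_fix[idx] & amp_ev > 0
  dist <- frac * amp_ev
  dist <- ifelse(amp_ev < 2 * margin, 0,
                 pmin(pmax(dist, margin), amp_ev - margin))
  frac[in_flight] <- dist[in_flight] / amp_ev[in_flight]
  scatter <- scatter_sd_deg * screen$px_per_deg
  gx <- ev_x0[idx] + (ev_x1[idx] - ev_x0[idx]) * frac +
    stats::rnorm(n, 0, scatter)
  gy <- ev_y0[idx] + (ev_y1[idx] - ev_y0[idx]) * frac +
    stats::rnorm(n, 0, scatter)

  valid <- rep(TRUE, n)
  if (dropout_rate > 0) {
    valid <- stats::runif(n) >= dropout_rate
    gx[!valid] <- NA_real_
    gy[!valid] <- NA_real_
  }

  ## ---- pupil --------------------------------------------------------------
  t_s <- (seq_len(n) - 1) / fs
  base <- p$pupil_baseline
  offset <- (condition$pupil_offset_pct + p$dilation_shift) / 100 * base
  f_lf <- stats::runif(1, 0.1, 0.4)
  lf <- condition$pupil_lf_amp_mm * sin(2 * pi * f_lf * t_s +
                                          stats::runif(1, 0, 2 * pi))
  hf_sd <- condition$pupil_hf_amp_mm * p$hf_mult
  hf <- if (hf_sd > 0) hf_sd * .bandlimited_hf(n, fs) else numeric(n)
  pupil <- base + offset + lf + hf + stats::rnorm(n, 0, 0.01)

  ## ---- heart-rate pulse ---------------------------------------------------
  ibi_mean <- min(max(condition$ibi_mean_s + p$ibi_shift, 0.5), 1.3)
  ibi_sd <- condition$ibi_sd_s * p$hrv_mult
  phase <- stats::runif(1, 0, 2 * pi)
  n_beats <- ceiling(dur_s / 0.4) + 3
  k <- seq_len(n_beats)
  ibis <- ibi_mean +
    sqrt(2) * ibi_sd * sin(2 * pi * k / 15 + phase) +
    stats::rnorm(n_beats, 0, 0.15 * ibi_sd)
  ibis <- pmax(ibis, 0.35)
  beats <- stats::runif(1, 0, ibi_mean) + cumsum(c(0, ibis))
  beats <- beats[beats < dur_s + 0.3]
  hrp <- stats::rnorm(n, 0, 0.02)
  w <- 0.25
  for (b in beats) {
    lo <- max(1L, ceiling((b - w / 2) * fs) + 1L)
    hi <- min(n, floor((b + w / 2) * fs) + 1L)
    if (lo > hi) next
    tt <- t_s[lo:hi] - b
    hrp[lo:hi] <- hrp[lo:hi] + 0.5 * (1 + cos(2 * pi * tt / w))
  }

  ## ---- skin resistance ----------------------------------------------------
  level <- condition$gsr_level_ohm * p$gsr_mult
  f_d <- stats::runif(1, 0.01, 0.05)
  gsr <- level * (1 + 0.02 * sin(2 * pi * f_d * t_s +
                                   stats::runif(1, 0, 2 * pi))) +
    stats::rnorm(n, 0, 0.002 * level)

  structure(
    list(participant_id = p$participant_id, trial_id = trial_id,
         condition = condition$label, task = condition$task,
         load = condition$load, baseline_pupil = base,
         time = t_s, gaze_x = gx, gaze_y = gy, pupil = pupil,
         hrp = hrp, gsr = gsr, valid = valid),
    class = "cogload_recording"
  )
}

#' @export
print.cogload_recording <- function(x, ...) {
  cat(sprintf("<cogload_recording> %s/%s  %s (%s, %s load)  %d samples (%.2f s)\n",
              x$participant_id, x$trial_id, x$condition, x$task, x$load,
              length(x$time), length(x$time) / 150))
  invisible(x)
}

#' Generate a full synthetic dataset
#'
#' Simulates `n_participants` participants each completing every condition
#' cell (default design: 24 mental-calculation + 20 visual-search trials, so
#' the default configuration yields `33 * 44 = 1452` recordings). All
#' randomness flows from `config$seed`; each participant's block uses a
#' deterministically derived sub-seed so the dataset is reproducible.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `cogload_dataset` with elements `recordings`
#'   (list of [generate_trial()] streams), `participants` (the trait table)
#'   and `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "cogload_synth_config"))
  profiles <- resolve_profiles(config$profiles, config$effect_size)
  set.seed(config$seed)
  participants <- generate_participants(config)
  recordings <- vector("list",
                       config$n_participants *
                         sum(vapply(profiles, `[[`, 0L, "n_trials")))
  k <- 0L
  for (i in seq_len(config$n_participants)) {
    set.seed((config$seed + 7919L * i) %% .Machine$integer.max)
    prt <- participants[i, ]
    j <- 0L
    for (cond in profiles) {
      for (r in seq_len(cond$n_trials)) {
        j <- j + 1L
        k <- k + 1L
        recordings[[k]] <- generate_trial(
          prt, cond, screen = config$screen,
          scatter_sd_deg = config$scatter_sd_deg,
          dropout_rate = config$dropout_rate,
          trial_id = sprintf("T%02d", j))
      }
    }
  }
  structure(list(recordings = recordings, participants = participants,
                 config = config),
            class = "cogload_dataset")
}

#' @export
print.cogload_dataset <- function(x, ...) {
  cat(sprintf("<cogload_dataset> %d participants, %d recordings\n",
              nrow(x$participants), length(x$recordings)))
  invisible(x)
}
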
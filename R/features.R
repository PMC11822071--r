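# Per-trial oculometric and biometric predictors: the ambient/focal K
# coefficient, task-evoked pupil dilation, inter-beat intervals and SDNN
# heart-rate variability from the pulse channel, tonic skin resistance, and
# the assembled labelled feature table.

#' Standardization statistics for the K coefficient
#'
#' Means and standard deviations of fixation durations and saccade
#' amplitudes over the standardization scope (one participant within one
#' task). Only paired events enter: each fixation that is followed by a
#' saccade contributes its duration, and every saccade its amplitude, so
#' the scope-wide mean of the per-event K values is exactly zero.
#'
#' @param durations_ms Fixation durations (ms) of fixations followed by a
#'   saccade, pooled over the scope.
#' @param amplitudes_px The following saccade amplitudes (px), same length.
#' @return List with `mu_d`, `sd_d`, `mu_a`, `sd_a`.
#' @export
k_standardization <- function(durations_ms, amplitudes_px) {
  stopifnot(length(durations_ms) == length(amplitudes_px))
  if (length(durations_ms) < 2)
    stop("need at least 2 paired events to standardize")
  out <- list(mu_d = mean(durations_ms), sd_d = stats::sd(durations_ms),
              mu_a = mean(amplitudes_px), sd_a = stats::sd(amplitudes_px))
  if (out$sd_d <= 0 || out$sd_a <= 0)
    stop("zero variance in standardization scope")
  out
}

#' Ambient/focal attention K coefficient
#'
#' For each fixation `i` with duration `d_i` followed by a saccade of
#' amplitude `a_{i+1}`, the per-event value is the difference of z-scores
#' `K_i = (d_i - mu_d)/sd_d - (a_{i+1} - mu_a)/sd_a`, with the moments taken
#' over the owning participant-by-task scope; the trial coefficient is the
#' mean of its `K_i`. Positive values indicate focal, negative ambient
#' visual attention.
#'
#' @param durations_ms Durations of the trial's paired fixations, ms.
#' @param amplitudes_px Amplitudes of the saccade following each, px (same
#'   length).
#' @param stats A [k_standardization()] list from the owning scope.
#' @return List with `k` (trial mean) and `k_i` (per-event values). With no
#'   pairs, `k` is `NA` with a warning.
#' @export
k_coefficient <- function(durations_ms, amplitudes_px, stats) {
  stopifnot(length(durations_ms) == length(amplitudes_px))
  if (is.null(stats$sd_d) || is.null(stats$sd_a) ||
      stats$sd_d <= 0 || stats$sd_a <= 0)
    stop("standardization SDs must be > 0")
  if (length(durations_ms) == 0) {
    warning("no fixation-saccade pairs in trial; K is NA")
    return(list(k = NA_real_, k_i = numeric(0)))
  }
  k_i <- (durations_ms - stats$mu_d) / stats$sd_d -
    (amplitudes_px - stats$mu_a) / stats$sd_a
  list(k = mean(k_i), k_i = k_i)
}

#' Task-evoked pupil dilation
#'
#' Percent change of the mean trial pupil diameter relative to the pupil
#' diameter recorded on the pre-task baseline screen.
#'
#' @param pupil Trial pupil series, mm (NAs ignored).
#' @param baseline_pupil Baseline diameter, mm (> 0).
#' @return `100 * (mean(pupil) - baseline) / baseline`; `NA` with a warning
#'   when no valid pupil samples exist.
#' @export
pupil_dilation <- function(pupil, baseline_pupil) {
  if (!is.numeric(baseline_pupil) || baseline_pupil <= 0)
    stop("baseline_pupil must be > 0")
  m <- mean(pupil, na.rm = TRUE)
  if (!is.finite(m)) {
    warning("no valid pupil samples; dilation is NA")
    return(NA_real_)
  }
  100 * (m - baseline_pupil) / baseline_pupil
}

# Prominence of candidate peaks: height minus the higher of the two valley
# minima separating the peak from the nearest higher samples on each side.
.peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1)]
    higher_l <- which(left > h)
    lmin <- if (length(higher_l) > 0) {
      min(x[(max(higher_l)):(p - 1)])
    } else if (p > 1) min(left) else h
    right <- if (p < length(x)) x[(p + 1):length(x)] else numeric(0)
    higher_r <- which(right > h)
    rmin <- if (length(higher_r) > 0) {
      min(x[(p + 1):(p + min(higher_r))])
    } else if (length(right) > 0) min(right) else h
    h - max(lmin, rmin)
  }, 0)
}

#' Locate pulse peaks in the heart-rate pulse channel
#'
#' Local maxima of the unitless pulse signal, kept when their prominence
#' reaches `prominence_frac` of the signal's 5th-95th percentile span, then
#' thinned (highest first) so that retained peaks are at least
#' `min_distance_s` apart -- the refractory floor for human inter-beat
#' intervals.
#'
#' @param hrp Pulse signal samples.
#' @param fs Sampling rate, Hz.
#' @param min_distance_s Minimum inter-peak distance, s.
#' @param prominence_frac Fraction of the 5-95 percentile span required as
#'   prominence.
#' @return Integer vector of peak sample indices (sorted).
#' @export
find_pulse_peaks <- function(hrp, fs = 150, min_distance_s = 0.33,
                             prominence_frac = 0.25) {
  n <- length(hrp)
  if (n < 3) return(integer(0))
  d <- diff(hrp)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (length(cand) == 0) return(integer(0))
  span <- diff(stats::quantile(hrp, c(0.05, 0.95), names = FALSE, type = 7))
  if (span <= 0) return(integer(0))
  prom <- .peak_prominence(hrp, cand)
  cand <- cand[prom >= prominence_frac * span]
  if (length(cand) == 0) return(integer(0))
  ord <- cand[order(hrp[cand], decreasing = TRUE)]
  keep <- integer(0)
  min_gap <- min_distance_s * fs
  for (p in ord) {
    if (all(abs(keep - p) >= min_gap)) keep <- c(keep, p)
  }
  sort(keep)
}

#' Inter-beat intervals from the pulse channel
#'
#' Detects pulse peaks ([find_pulse_peaks()]), takes successive peak-time
#' differences as inter-beat intervals (IBIs), and smooths them with a
#' centred 3-beat moving average (shrinking to the available beats at the
#' edges) to suppress finger-movement noise.
#'
#' @inheritParams find_pulse_peaks
#' @return An object of class `cogload_ibi`: list with `peak_times` (s),
#'   `ibis` (s) and `smoothed_ibis` (s). With fewer than 2 peaks the series
#'   are empty and a warning is raised.
#' @export
ibi_from_hrp <- function(hrp, fs = 150, min_distance_s = 0.33,
                         prominence_frac = 0.25) {
  if (length(hrp) < 2 * fs)
    warning("pulse series shorter than 2 s; IBI estimate unreliable")
  peaks <- find_pulse_peaks(hrp, fs, min_distance_s, prominence_frac)
  if (length(peaks) < 2) {
    warning("fewer than 2 pulse peaks; no IBIs")
    return(structure(list(peak_times = (peaks - 1) / fs, ibis = numeric(0),
                          smoothed_ibis = numeric(0)),
                     class = "cogload_ibi"))
  }
  pt <- (peaks - 1) / fs
  ibis <- diff(pt)
  structure(list(peak_times = pt, ibis = ibis,
                 smoothed_ibis = smooth_ibis(ibis)),
            class = "cogload_ibi")
}

#' Centred 3-beat moving average with shrinking edges
#'
#' @param ibis Numeric IBI series, s.
#' @return Smoothed series of equal length; at the first and last beat the
#'   window shrinks to the two available values.
#' @export
smooth_ibis <- function(ibis) {
  m <- length(ibis)
  if (m <= 2) return(ibis)
  out <- numeric(m)
  out[1] <- mean(ibis[1:2])
  out[m] <- mean(ibis[(m - 1):m])
  i <- 2:(m - 1)
  out[i] <- (ibis[i - 1] + ibis[i] + ibis[i + 1]) / 3
  out
}

#' Heart-rate variability (SDNN of smoothed IBIs)
#'
#' @param ibi A `cogload_ibi` object or a numeric vector of (smoothed)
#'   IBIs, s.
#' @return Sample standard deviation (n - 1 denominator), s; `NA` with a
#'   warning for fewer than 2 intervals.
#' @export
hrv_sdnn <- function(ibi) {
  x <- if (inherits(ibi, "cogload_ibi")) ibi$smoothed_ibis else as.numeric(ibi)
  if (length(x) < 2) {
    warning("fewer than 2 IBIs; HRV is NA")
    return(NA_real_)
  }
  stats::sd(x)
}

#' Tonic skin-resistance level
#'
#' Mean skin resistance over the trial window. Human skin resistance
#' typically lies between 10 kOhm and 2 MOhm; values outside that range are
#' retained but flagged via the `"out_of_range"` attribute.
#'
#' @param gsr Skin-resistance samples, Ohms.
#' @param valid Optional logical vector of usable samples.
#' @return Mean resistance (Ohms) with attribute `out_of_range`; `NA` with a
#'   warning when no valid samples remain.
#' @export
gsr_level <- function(gsr, valid = NULL) {
  x <- as.numeric(gsr)
  if (!is.null(valid)) x <- x[valid]
  x <- x[is.finite(x)]
  if (length(x) == 0) {
    warning("no valid skin-resistance samples; GSR is NA")
    return(NA_real_)
  }
  m <- mean(x)
  attr(m, "out_of_range") <- (m < 1e4 || m > 2e6)
  m
}

.group_label <- function(task, load) {
  paste0(ifelse(task == "mental_calculation", "mc", "vs"), "_", load)
}

#' Build the labelled per-trial feature table
#'
#' Runs event detection on every recording, winsorizes fixation durations
#' and saccade amplitudes per participant-by-task scope
#' ([winsorize_upper()]), computes the standardization moments for the K
#' coefficient on the winsorized paired events of the same scope, and
#' assembles one row per trial with the seven physiological predictors, the
#' backward digit-span covariate, condition labels and the derived 4-group
#' factor (`mc_low`, `mc_high`, `vs_low`, `vs_high`).
#'
#' @param dataset A `cogload_dataset` (from [generate_dataset()] or
#'   [read_recordings()]).
#' @param params [event_params()] for fixation detection.
#' @param fs Sampling rate, Hz.
#' @param lhipa_wavelet,lhipa_sigma LHIPA settings, see [lhipa()].
#' @param peak_min_distance_s,peak_prominence_frac Pulse-peak settings, see
#'   [find_pulse_peaks()].
#' @return `data.frame` with columns `participant_id`, `trial_id`,
#'   `condition`, `task`, `load`, `group`, `fix_dur_ms`, `sacc_amp_px`,
#'   `k_coef`, `hrv_s`, `gsr_ohm`, `lhipa`, `pupil_dilation_pct`,
#'   `dspan_backward` plus `*_missing` logical flags (and
#'   `gsr_out_of_range`).
#' @export
build_feature_table <- function(dataset, params = event_params(), fs = 150,
                                lhipa_wavelet = "sym16",
                                lhipa_sigma = "unit",
                                peak_min_distance_s = 0.33,
                                peak_prominence_frac = 0.25) {
  recs <- if (inherits(dataset, "cogload_dataset")) dataset$recordings
          else dataset
  participants <- if (inherits(dataset, "cogload_dataset"))
    dataset$participants else NULL
  stopifnot(length(recs) > 0)
  ids <- vapply(recs, function(r) paste(r$participant_id, r$trial_id,
                                        sep = "/"), "")
  if (anyDuplicated(ids))
    stop("duplicate trial ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  ## ---- events per trial ---------------------------------------------------
  ev <- lapply(recs, function(r) {
    fx <- suppressWarnings(detect_fixations(r, params))
    sc <- saccades_between(fx)
    list(fix = fx, sacc = sc)
  })

  scope <- vapply(recs, function(r) paste(r$participant_id, r$task,
                                          sep = "/"), "")
  n_fix <- vapply(ev, function(e) nrow(e$fix), 0L)
  n_sac <- vapply(ev, function(e) nrow(e$sacc), 0L)

  ## ---- winsorization per participant x task -------------------------------
  all_dur <- unlist(lapply(ev, function(e) e$fix$duration_ms))
  all_amp <- unlist(lapply(ev, function(e) e$sacc$amplitude_px))
  dur_scope <- rep(scope, n_fix)
  amp_scope <- rep(scope, n_sac)
  for (sc in unique(scope)) {
    i <- dur_scope == sc
    if (sum(i) > 0) all_dur[i] <- winsorize_upper(all_dur[i])
    j <- amp_scope == sc
    if (sum(j) > 0) all_amp[j] <- winsorize_upper(all_amp[j])
  }
  dur_by_trial <- split(all_dur, rep(seq_along(recs), n_fix))
  amp_by_trial <- split(all_amp, rep(seq_along(recs), n_sac))

  ## ---- K standardization per scope (paired events only) -------------------
  paired <- lapply(seq_along(recs), function(t) {
    d <- dur_by_trial[[as.character(t)]]
    a <- amp_by_trial[[as.character(t)]]
    if (is.null(d)) d <- numeric(0)
    if (is.null(a)) a <- numeric(0)
    if (length(a) == 0) return(list(d = numeric(0), a = numeric(0)))
    list(d = d[seq_along(a)], a = a)
  })
  k_stats <- lapply(split(seq_along(recs), scope), function(tix) {
    d <- unlist(lapply(paired[tix], `[[`, "d"))
    a <- unlist(lapply(paired[tix], `[[`, "a"))
    if (length(d) < 2) return(NULL)
    tryCatch(k_standardization(d, a), error = function(e) NULL)
  })

  ## ---- per-trial rows -----------------------------------------------------
  rows <- lapply(seq_along(recs), function(t) {
    r <- recs[[t]]
    d <- dur_by_trial[[as.character(t)]]
    a <- amp_by_trial[[as.character(t)]]
    fix_dur <- if (length(d) > 0) mean(d) else NA_real_
    sacc_amp <- if (length(a) > 0) mean(a) else NA_real_
    st <- k_stats[[scope[t]]]
    kc <- if (!is.null(st) && length(paired[[t]]$a) > 0) {
      k_coefficient(paired[[t]]$d, paired[[t]]$a, st)$k
    } else NA_real_
    ib <- suppressWarnings(ibi_from_hrp(r$hrp, fs, peak_min_distance_s,
                                        peak_prominence_frac))
    hrv <- suppressWarnings(hrv_sdnn(ib))
    g <- suppressWarnings(gsr_level(r$gsr))
    lh <- suppressWarnings(lhipa(r$pupil, fs, wavelet = lhipa_wavelet,
                                 sigma = lhipa_sigma))
    pd <- suppressWarnings(pupil_dilation(r$pupil, r$baseline_pupil))
    data.frame(
      participant_id = r$participant_id, trial_id = r$trial_id,
      condition = r$condition, task = r$task, load = r$load,
      group = .group_label(r$task, r$load),
      fix_dur_ms = fix_dur, sacc_amp_px = sacc_amp, k_coef = kc,
      hrv_s = hrv, gsr_ohm = as.numeric(g), lhipa = lh,
      pupil_dilation_pct = pd,
      gsr_out_of_range = isTRUE(attr(g, "out_of_range")),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)

  if (!is.null(participants) && "dspan_backward" %in% names(participants)) {
    out$dspan_backward <- participants$dspan_backward[
      match(out$participant_id, participants$participant_id)]
  } else {
    out$dspan_backward <- NA_integer_
  }
  for (f in c("fix_dur_ms", "sacc_amp_px", "k_coef", "hrv_s", "gsr_ohm",
              "lhipa", "pupil_dilation_pct")) {
    out[[paste0(f, "_missing")]] <- !is.finite(out[[f]])
  }
  out
}
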
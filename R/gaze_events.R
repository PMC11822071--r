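# Dispersion-threshold (I-DT) fixation detection, saccade derivation and the
# upper-tail winsorization rule used before feature aggregation.

#' Detection parameters for I-DT
#'
#' @param dispersion_px Dispersion threshold in pixels, applied to
#'   `(max x - min x) + (max y - min y)` of the candidate window. Default:
#'   1 degree of visual angle under the default screen geometry.
#' @param min_duration_ms Minimum fixation duration, ms.
#' @param max_gap_bridge Maximum run length of invalid samples bridged by
#'   linear interpolation; longer gaps split the stream and terminate any
#'   open window.
#' @param screen Screen geometry used to convert the default threshold.
#' @return An object of class `cogload_event_params`.
#' @export
event_params <- function(dispersion_px = NULL, min_duration_ms = 100,
                         max_gap_bridge = 3, screen = screen_geometry()) {
  if (is.null(dispersion_px)) dispersion_px <- deg_to_px(1, screen)
  if (dispersion_px <= 0 || min_duration_ms <= 0)
    stop("dispersion_px and min_duration_ms must be > 0")
  structure(list(dispersion_px = dispersion_px,
                 min_duration_ms = min_duration_ms,
                 max_gap_bridge = as.integer(max_gap_bridge)),
            class = "cogload_event_params")
}

.empty_fixations <- function() {
  data.frame(onset_s = numeric(0), offset_s = numeric(0),
             duration_ms = numeric(0), centroid_x_px = numeric(0),
             centroid_y_px = numeric(0), mean_pupil_mm = numeric(0),
             n_samples = integer(0))
}

# Coerce input to a gaze sample frame (time, x, y, pupil, valid).
.as_gaze_samples <- function(samples) {
  if (inherits(samples, "cogload_recording")) {
    return(data.frame(time = samples$time, x = samples$gaze_x,
                      y = samples$gaze_y, pupil = samples$pupil,
                      valid = samples$valid))
  }
  samples <- as.data.frame(samples)
  stopifnot(all(c("time", "x", "y") %in% names(samples)))
  if (is.null(samples$valid))
    samples$valid <- is.finite(samples$x) & is.finite(samples$y)
  if (is.null(samples$pupil)) samples$pupil <- NA_real_
  samples
}

# Bridge invalid runs of length <= max_gap by linear interpolation; return a
# list of contiguous valid segments (longer gaps split).
.bridge_segments <- function(s, max_gap) {
  ok <- s$valid & is.finite(s$x) & is.finite(s$y)
  if (!any(ok)) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  bridged <- ok
  for (i in seq_along(r$values)) {
    if (!r$values[i] && r$lengths[i] <= max_gap &&
        i > 1 && i < length(r$values)) {
      bridged[starts[i]:ends[i]] <- TRUE
    }
  }
  idx_ok <- which(bridged)
  if (length(idx_ok) == 0) return(list())
  segs <- split(idx_ok, cumsum(c(1, diff(idx_ok) > 1)))
  lapply(segs, function(ix) {
    seg <- s[ix, , drop = FALSE]
    bad <- !(seg$valid & is.finite(seg$x) & is.finite(seg$y))
    if (any(bad)) {
      seg$x <- stats::approx(seg$time[!bad], seg$x[!bad], seg$time,
                             rule = 2)$y
      seg$y <- stats::approx(seg$time[!bad], seg$y[!bad], seg$time,
                             rule = 2)$y
      if (any(is.finite(seg$pupil[!bad])))
        seg$pupil <- stats::approx(seg$time[!bad], seg$pupil[!bad], seg$time,
                                   rule = 2)$y
    }
    seg
  })
}

# Core I-DT on one contiguous segment. Window dispersion is monotone
# non-decreasing under extension, so the maximal admissible window from a
# start index is the prefix of cummax/cummin dispersions under threshold.
.idt_segment <- function(seg, dispersion_px, min_dur_s, dt) {
  n <- nrow(seg)
  out <- list()
  i <- 1L
  while (i <= n) {
    xs <- seg$x[i:n]; ys <- seg$y[i:n]
    dv <- (cummax(xs) - cummin(xs)) + (cummax(ys) - cummin(ys))
    m <- sum(dv <= dispersion_px)
    if (m >= 2L) {
      last <- i + m - 1L
      dur <- seg$time[last] - seg$time[i] + dt
      if (dur >= min_dur_s) {
        out[[length(out) + 1L]] <- data.frame(
          onset_s = seg$time[i],
          offset_s = seg$time[last] + dt,
          duration_ms = dur * 1000,
          centroid_x_px = mean(seg$x[i:last]),
          centroid_y_px = mean(seg$y[i:last]),
          mean_pupil_mm = mean(seg$pupil[i:last]),
          n_samples = m)
        i <- last + 1L
        next
      }
    }
    i <- i + 1L
  }
  out
}

#' Detect fixations with the I-DT dispersion algorithm
#'
#' Grows a sample window while its dispersion `(max x - min x) +
#' (max y - min y)` stays at or under the threshold and emits a fixation
#' when the window covers at least the minimum duration. Durations are
#' frame-inclusive: the offset is the last sample's time plus one sampling
#' interval, so a fixation spanning `k` samples at 150 Hz lasts
#' `k/150` seconds.
#'
#' Invalid-sample runs up to `params$max_gap_bridge` are bridged by linear
#' interpolation; longer gaps terminate the current window and detection
#' restarts after the gap.
#'
#' @param samples A `cogload_recording`, or a data.frame with columns
#'   `time` (s), `x`, `y` (px) and optionally `pupil` (mm) and `valid`.
#' @param params An [event_params()] object.
#' @return `data.frame` of time-ordered, non-overlapping fixations with
#'   columns `onset_s`, `offset_s`, `duration_ms`, `centroid_x_px`,
#'   `centroid_y_px`, `mean_pupil_mm`, `n_samples`.
#' @export
detect_fixations <- function(samples, params = event_params()) {
  stopifnot(inherits(params, "cogload_event_params"))
  s <- .as_gaze_samples(samples)
  if (is.unsorted(s$time, strictly = TRUE))
    stop("samples must be strictly time-ordered")
  if (sum(s$valid & is.finite(s$x) & is.finite(s$y)) < 2) {
    warning("fewer than 2 valid gaze samples; no fixations detected")
    return(.empty_fixations())
  }
  dt <- stats::median(diff(s$time))
  segs <- .bridge_segments(s, params$max_gap_bridge)
  out <- list()
  for (seg in segs) {
    if (nrow(seg) < 2) next
    out <- c(out, .idt_segment(seg, params$dispersion_px,
                               params$min_duration_ms / 1000, dt))
  }
  if (length(out) == 0) return(.empty_fixations())
  do.call(rbind, out)
}

#' Derive saccades between consecutive fixations
#'
#' The saccade following fixation `i` spans from that fixation's offset to
#' the next fixation's onset; its amplitude is the Euclidean distance
#' between the two fixation centroids.
#'
#' @param fixations Output of [detect_fixations()] (time-ordered).
#' @return `data.frame` with `n - 1` rows (columns `onset_s`, `offset_s`,
#'   `duration_ms`, `amplitude_px`); empty for fewer than 2 fixations.
#' @export
saccades_between <- function(fixations) {
  n <- nrow(fixations)
  if (is.null(n) || n < 2) {
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      duration_ms = numeric(0), amplitude_px = numeric(0)))
  }
  i <- seq_len(n - 1)
  amp <- sqrt(diff(fixations$centroid_x_px)^2 +
                diff(fixations$centroid_y_px)^2)
  data.frame(onset_s = fixations$offset_s[i],
             offset_s = fixations$onset_s[i + 1],
             duration_ms = (fixations$onset_s[i + 1] -
                              fixations$offset_s[i]) * 1000,
             amplitude_px = amp)
}

#' Upper-tail winsorization at mean + 1 IQR
#'
#' Outlier reduction for positive event magnitudes (fixation durations,
#' saccade amplitudes): values above `mean(x) + IQR(x)` are replaced by the
#' largest value not exceeding that bound ("reduced to the highest
#' non-outlying value"). Only the upper tail is treated; the mean and IQR
#' are computed once on the input (single pass), and quantiles use linear
#' interpolation between order statistics (R type 7).
#'
#' @param values Non-empty numeric vector of positive values.
#' @return Vector of the same length and order; no value is ever increased.
#' @export
winsorize_upper <- function(values) {
  if (length(values) == 0) stop("winsorize_upper: empty input")
  if (any(!is.finite(values))) stop("winsorize_upper: non-finite values")
  bound <- mean(values) + stats::IQR(values, type = 7)
  over <- values > bound
  if (!any(over)) return(values)
  keep <- values[!over]
  if (length(keep) == 0) {
    warning("all values exceed the winsorization bound; using the bound")
    repl <- bound
  } else {
    repl <- max(keep)
  }
  values[over] <- repl
  values
}

#' Flatten detected events into the events table
#'
#' @param fixations,saccades Event frames from [detect_fixations()] and
#'   [saccades_between()].
#' @param participant_id,trial_id Identifiers copied onto each row.
#' @return Long `data.frame` with an `event_type` column (`"fixation"` /
#'   `"saccade"`), suitable for the events CSV.
#' @export
events_table <- function(fixations, saccades,
                         participant_id = NA_character_,
                         trial_id = NA_character_) {
  f <- data.frame(participant_id = participant_id, trial_id = trial_id,
                  event_type = rep("fixation", nrow(fixations)),
                  onset_s = fixations$onset_s, offset_s = fixations$offset_s,
                  duration_ms = fixations$duration_ms,
                  centroid_x_px = fixations$centroid_x_px,
                  centroid_y_px = fixations$centroid_y_px,
                  amplitude_px = NA_real_,
                  mean_pupil_mm = fixations$mean_pupil_mm)
  s <- data.frame(participant_id = participant_id, trial_id = trial_id,
                  event_type = rep("saccade", nrow(saccades)),
                  onset_s = saccades$onset_s, offset_s = saccades$offset_s,
                  duration_ms = saccades$duration_ms,
                  centroid_x_px = NA_real_, centroid_y_px = NA_real_,
                  amplitude_px = saccades$amplitude_px,
                  mean_pupil_mm = NA_real_)
  out <- rbind(f, s)
  out[order(out$onset_s), , drop = FALSE]
}
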
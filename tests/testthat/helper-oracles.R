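# Independent brute-force oracles and stream builders shared across tests.
# Each oracle recomputes its quantity from first principles, without calling
# the package's implementation path.

# Exhaustive window-scan I-DT: from each start index, grow the window by
# explicit recomputation of (max x - min x) + (max y - min y) over the full
# window; emit when the maximal admissible window covers the minimum
# duration (frame-inclusive, offset = last sample + dt).
oracle_idt <- function(time, x, y, dispersion_px, min_dur_s, dt) {
  n <- length(time)
  rows <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j + 1L <= n) {
      w <- i:(j + 1L)
      d <- (max(x[w]) - min(x[w])) + (max(y[w]) - min(y[w]))
      if (d > dispersion_px) break
      j <- j + 1L
    }
    if (j > i && (time[j] - time[i] + dt) >= min_dur_s) {
      rows[[length(rows) + 1L]] <- data.frame(
        onset_s = time[i], offset_s = time[j] + dt,
        duration_ms = (time[j] - time[i] + dt) * 1000,
        centroid_x_px = mean(x[i:j]), centroid_y_px = mean(y[i:j]),
        n_samples = j - i + 1L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(rows) == 0) {
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      duration_ms = numeric(0), centroid_x_px = numeric(0),
                      centroid_y_px = numeric(0), n_samples = integer(0)))
  }
  do.call(rbind, rows)
}

# Random gaze stream mixing stationary clusters and jumps, sometimes with
# drifting segments, for oracle-equivalence checks.
random_gaze_stream <- function(n_max = 500, fs = 150) {
  n <- sample(20:n_max, 1)
  x <- numeric(n); y <- numeric(n)
  pos <- c(runif(1, 200, 800), runif(1, 200, 600))
  i <- 1
  while (i <= n) {
    len <- min(sample(5:60, 1), n - i + 1)
    mode <- sample(c("cluster", "drift", "jump"), 1,
                   prob = c(0.6, 0.25, 0.15))
    if (mode == "jump") {
      pos <- pos + runif(2, -300, 300)
      len <- min(len, 3)
    }
    drift <- if (mode == "drift") runif(2, -6, 6) else c(0, 0)
    for (k in seq_len(len)) {
      pos <- pos + drift
      x[i] <- pos[1] + rnorm(1, 0, 4)
      y[i] <- pos[2] + rnorm(1, 0, 4)
      i <- i + 1
      if (i > n) break
    }
  }
  data.frame(time = (seq_len(n) - 1) / fs, x = x, y = y)
}

# Hand-rolled periodized DWT detail coefficients: explicit double loop with
# modular indexing, own QMF derivation.
oracle_dwt_detail <- function(x, level, lo) {
  L <- length(lo)
  hi <- (-1)^(0:(L - 1)) * lo[L:1]
  a <- x
  det <- NULL
  for (lev in seq_len(level)) {
    n <- length(a)
    if (n %% 2 == 1) { a <- c(a, a[n]); n <- n + 1 }
    appr <- numeric(n / 2); det <- numeric(n / 2)
    for (k in seq_len(n / 2)) {
      sa <- 0; sdt <- 0
      for (m in 0:(L - 1)) {
        xi <- ((2 * k - 1 - m) %% n) + 1
        sa <- sa + lo[m + 1] * a[xi]
        sdt <- sdt + hi[m + 1] * a[xi]
      }
      appr[k] <- sa; det[k] <- sdt
    }
    a <- appr
  }
  det
}

# Pairwise-counting AUC with half-credit for ties (Mann-Whitney).
oracle_auc_count <- function(scores, y_pos) {
  sp <- scores[y_pos]; sn <- scores[!y_pos]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Type-7 quantile by hand (linear interpolation of order statistics).
oracle_quantile7 <- function(x, p) {
  xs <- sort(x); n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Raised-cosine pulse train with prescribed inter-beat intervals.
make_pulse_train <- function(ibis, fs = 150, start = 0.4, width = 0.25,
                             noise_sd = 0) {
  beats <- start + cumsum(c(0, ibis))
  dur <- max(beats) + 0.5
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  hrp <- stats::rnorm(n, 0, noise_sd)
  for (b in beats) {
    lo <- max(1L, ceiling((b - width / 2) * fs) + 1L)
    hi <- min(n, floor((b + width / 2) * fs) + 1L)
    if (lo > hi) next
    hrp[lo:hi] <- hrp[lo:hi] + 0.5 * (1 + cos(2 * pi * (t[lo:hi] - b) / width))
  }
  hrp
}

# Band-limited unit-SD noise via a Butterworth band-pass (frequencies Hz).
bandlimited_noise <- function(n, fs, f_lo, f_hi) {
  bf <- signal::butter(2, c(f_lo, f_hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 2 * fs))
  x <- x[(fs + 1):(fs + n)]
  x / stats::sd(x)
}

# Neutral participant (all trait multipliers 1) for generator tests.
neutral_participant <- function(id = "P00") {
  list(participant_id = id, pupil_baseline = 4.5, fix_mult = 1,
       sacc_mult = 1, gsr_mult = 1, hrv_mult = 1, hf_mult = 1,
       ibi_shift = 0, dilation_shift = 0, dspan_backward = 7L)
}

# Feature-table skeleton with prescribed per-trial values, for reliability
# and model tests that do not need real recordings.
synthetic_feature_table <- function(n_participants = 33,
                                    trial_values = NULL,
                                    participant_effect_sd = 0,
                                    noise_sd = 1) {
  g <- rep(c("mc_low", "mc_high", "vs_low", "vs_high"),
           times = c(12, 12, 10, 10))
  task <- ifelse(grepl("^mc", g), "mental_calculation", "visual_search")
  load <- ifelse(grepl("low$", g), "low", "high")
  do.call(rbind, lapply(seq_len(n_participants), function(p) {
    base <- rnorm(1, 0, participant_effect_sd)
    v <- if (is.null(trial_values)) base + rnorm(44, 0, noise_sd)
         else trial_values
    data.frame(participant_id = sprintf("P%02d", p),
               trial_id = sprintf("T%02d", 1:44),
               group = g, task = task, load = load,
               fix_dur_ms = v, sacc_amp_px = base + rnorm(44, 0, noise_sd),
               k_coef = rnorm(44), hrv_s = abs(rnorm(44, 0.1, 0.03)),
               gsr_ohm = rnorm(44, 4e5, 5e4), lhipa = rnorm(44, 1.5, 0.5),
               pupil_dilation_pct = rnorm(44, 2, 3),
               dspan_backward = 7L,
               stringsAsFactors = FALSE)
  }))
}
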
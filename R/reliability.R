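# Split-half reliability with Spearman-Brown correction over many random
# splits of each participant's trials.

#' Spearman-Brown correction
#'
#' Steps a half-test correlation up to full-test reliability:
#' `2 r / (1 + r)`. The correction is monotone in `r` and fixes 0 and 1.
#'
#' @param r Pearson correlation(s) between half-test scores.
#' @return Corrected coefficient(s).
#' @export
spearman_brown <- function(r) 2 * r / (1 + r)

#' Split-half reliability of trial features
#'
#' For each random split, every participant's trials within the group are
#' partitioned into two halves (an odd trial goes to a random half),
#' per-participant half means are formed, the Pearson correlation between
#' halves is taken across participants, and the Spearman-Brown correction
#' applied. Results aggregate the corrected coefficient over all splits.
#'
#' Participants with fewer than 2 usable (non-missing) trials for a feature
#' are excluded from that feature's splits; the count is recorded in the
#' output. Negative correlations are corrected as-is (2r/(1+r) may be
#' negative); only pathological `r < -0.5` is clamped into [-1, 1] and
#' counted in `n_clamped`.
#'
#' @param features Feature table from [build_feature_table()].
#' @param feature Character vector of feature column names (e.g.
#'   `"fix_dur_ms"`, `"k_coef"`). All named features share the call but get
#'   independent split schedules.
#' @param group Group label to subset (`"mc_low"`, `"mc_high"`, `"vs_low"`,
#'   `"vs_high"`).
#' @param n_splits Number of random splits (the study design uses 5000).
#' @param seed Integer seed for the split schedule.
#' @return `data.frame` with one row per feature: `feature`, `group`,
#'   `n_splits`, `mean_sb`, `min_sb`, `max_sb`, `mean_r`, `n_participants`,
#'   `n_excluded`, `n_clamped`, `seed`.
#' @export
split_half_reliability <- function(features, feature, group,
                                   n_splits = 5000, seed = 1L) {
  stopifnot(n_splits >= 1)
  sub <- features[features$group == group, , drop = FALSE]
  if (nrow(sub) == 0) stop("no trials in group ", group)
  set.seed(seed)
  out <- lapply(feature, function(f) {
    if (!f %in% names(sub)) stop("unknown feature column: ", f)
    flag <- paste0(f, "_missing")
    usable <- if (flag %in% names(sub)) !sub[[flag]] else is.finite(sub[[f]])
    vals <- split(sub[[f]][usable],
                  factor(sub$participant_id[usable],
                         levels = unique(sub$participant_id)))
    sizes <- vapply(vals, length, 0L)
    n_excluded <- sum(sizes < 2)
    vals <- vals[sizes >= 2]
    P <- length(vals)
    if (P < 3)
      stop("fewer than 3 participants with >= 2 usable trials for ", f,
           " in ", group)
    S <- n_splits
    M1 <- matrix(0, P, S)
    M2 <- matrix(0, P, S)
    for (p in seq_len(P)) {
      v <- vals[[p]]
      m <- length(v)
      U <- matrix(stats::runif(m * S), m, S)
      R <- matrix(0L, m, S)
      for (i in seq_len(m))
        R[i, ] <- 1L + colSums(U < matrix(U[i, ], m, S, byrow = TRUE))
      base <- m %/% 2L
      size1 <- base + if (m %% 2L == 1L) stats::rbinom(S, 1L, 0.5) else 0L
      I <- R <= matrix(size1, m, S, byrow = TRUE)
      s1 <- colSums(v * I)
      n1 <- colSums(I)
      M1[p, ] <- s1 / n1
      M2[p, ] <- (sum(v) - s1) / (m - n1)
    }
    a <- sweep(M1, 2, colMeans(M1))
    b <- sweep(M2, 2, colMeans(M2))
    denom <- sqrt(colSums(a^2) * colSums(b^2))
    r <- ifelse(denom > 0, colSums(a * b) / denom, NA_real_)
    r <- r[is.finite(r)]
    if (length(r) == 0) stop("no valid splits for ", f, " in ", group)
    sb <- spearman_brown(r)
    clamp <- r < -0.5
    sb[clamp] <- pmin(pmax(sb[clamp], -1), 1)
    data.frame(feature = f, group = group, n_splits = S,
               mean_sb = mean(sb), min_sb = min(sb), max_sb = max(sb),
               mean_r = mean(r), n_participants = P,
               n_excluded = n_excluded, n_clamped = sum(clamp),
               seed = seed, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Reliability report over all features and groups
#'
#' Convenience wrapper running [split_half_reliability()] for every
#' feature-by-group cell.
#'
#' @inheritParams split_half_reliability
#' @param features Feature table.
#' @param feature_cols Feature columns to assess.
#' @return Row-bound reliability table.
#' @export
reliability_report <- function(features,
                               feature_cols = c("fix_dur_ms", "sacc_amp_px",
                                                "k_coef", "hrv_s", "gsr_ohm",
                                                "lhipa",
                                                "pupil_dilation_pct"),
                               n_splits = 5000, seed = 1L) {
  groups <- intersect(c("mc_low", "mc_high", "vs_low", "vs_high"),
                      unique(features$group))
  do.call(rbind, lapply(seq_along(groups), function(gi) {
    split_half_reliability(features, feature_cols, groups[gi],
                           n_splits = n_splits, seed = seed + gi)
  }))
}
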
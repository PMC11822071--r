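#' Low-High Index of Pupillary Activity
#'
#' Wavelet index of the balance between low- and high-frequency pupil
#' oscillations; it is expected to fall as high-frequency pupillary
#' activity (a correlate of mental effort) grows. The pupil series is
#' decomposed with a periodized DWT; the high-frequency band is the level-1
#' detail and the low-frequency band the level `floor(log2(n)/2)` detail
#' (both normalised by `sqrt(2^level)`). The LF coefficients are divided by
#' the time-aligned HF coefficients, modulus maxima of the ratio sequence
#' are located, a universal threshold `lambda = sigma * sqrt(2 ln m)` is
#' applied, and the index is the count of supra-threshold maxima divided by
#' the signal duration in seconds.
#'
#' @param pupil Pupil diameter series (mm) at `fs` Hz. Internal `NA` runs
#'   are linearly interpolated before the transform.
#' @param fs Sampling rate, Hz.
#' @param wavelet Wavelet family, see [wavelet_filters()].
#' @param sigma Noise-scale estimator for the universal threshold.
#'   `"unit"` (default) takes the dimensionless LF/HF ratio at unit noise
#'   scale, so the threshold `sqrt(2 ln m)` counts epochs in which
#'   low-frequency coefficients dominate the concurrent high-frequency
#'   coefficients by a fixed factor -- this keeps the index monotone in the
#'   band balance. `"modmax_sd"` (SD of the modulus-maxima sequence) and
#'   `"mad_ratio"` (MAD of the ratio sequence) are data-driven scales;
#'   being proportional to the ratio itself they make the index
#'   scale-invariant, which suppresses its sensitivity to the band balance.
#' @return The index (modulus maxima per second). A constant series returns
#'   0 with a warning (no oscillatory content); a series shorter than 16
#'   usable samples returns `NA` with a warning.
#' @export
lhipa <- function(pupil, fs = 150, wavelet = "sym16",
                  sigma = c("unit", "modmax_sd", "mad_ratio")) {
  sigma <- match.arg(sigma)
  x <- as.numeric(pupil)
  ok <- is.finite(x)
  if (sum(ok) < 16) {
    warning("pupil series too short for LHIPA; returning NA")
    return(NA_real_)
  }
  if (!all(ok)) {
    idx <- seq_along(x)
    x <- stats::approx(idx[ok], x[ok], idx, rule = 2)$y
  }
  n <- length(x)
  if (stats::sd(x) == 0) {
    warning("constant pupil series; LHIPA = 0")
    return(0)
  }
  hif <- 1L
  lof <- max(2L, min(floor(log2(n) / 2), floor(log2(n))))
  cH <- dwt_detail(x, hif, wavelet) / sqrt(2^hif)
  cL <- dwt_detail(x, lof, wavelet) / sqrt(2^lof)
  stride <- 2^(lof - hif)
  k <- seq_along(cL)
  hi_idx <- pmin((k - 1) * stride + 1, length(cH))
  denom <- cH[hi_idx]
  eps <- max(abs(denom)) * 1e-12
  if (eps == 0) eps <- .Machine$double.eps
  denom[abs(denom) < eps] <- eps * sign(denom[abs(denom) < eps] + eps)
  ratio <- cL / denom
  mm <- modulus_maxima(ratio)
  s_hat <- switch(sigma,
                  unit = 1,
                  modmax_sd = stats::sd(mm),
                  mad_ratio = stats::mad(ratio))
  lambda <- s_hat * sqrt(2 * log(length(ratio)))
  sum(mm > lambda) / (n / fs)
}
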
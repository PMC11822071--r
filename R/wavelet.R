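# Minimal periodized discrete wavelet transform used by the pupillary
# activity index. Filter tables are the standard orthogonal wavelet
# coefficients (symlet-16 and Haar).

.sym16_dec_lo <- c(
  6.230006701220761e-06, -3.113556407621969e-06, -1.0943147929529757e-04,
  2.8078582128442894e-05, 8.523547108047095e-04, -1.084456223089688e-04,
  -3.8809122526038786e-03, 7.182119788317892e-04, 1.2666731659857348e-02,
  -3.1265171722710075e-03, -3.1051202843553064e-02, 4.869274404904607e-03,
  3.2333091610663785e-02, -6.698304907021778e-02, -3.4574228416972504e-02,
  3.9712293362064416e-01, 7.565249878756971e-01, 4.7534280601152273e-01,
  -5.4040601387606135e-02, -1.5959219218520598e-01, 3.072113906330156e-02,
  7.803785290341991e-02, -3.510275068374009e-03, -2.4952758046290123e-02,
  1.359844742484172e-03, 6.9377611308027096e-03, -2.2211647621176323e-04,
  -1.3387206066921965e-03, 3.656592483348223e-05, 1.6545679579108483e-04,
  -5.396483179315242e-06, -1.0797982104319795e-05)

#' Orthogonal wavelet filter pair
#'
#' Returns the decomposition low-pass filter and its quadrature-mirror
#' high-pass counterpart `hi[k] = (-1)^k lo[L - 1 - k]` (0-based).
#'
#' @param wavelet `"sym16"` (default, a near-symmetric 32-tap symlet) or
#'   `"haar"`.
#' @return List with numeric vectors `lo` and `hi`.
#' @export
wavelet_filters <- function(wavelet = c("sym16", "haar")) {
  wavelet <- match.arg(wavelet)
  lo <- switch(wavelet,
               sym16 = .sym16_dec_lo,
               haar = c(1, 1) / sqrt(2))
  L <- length(lo)
  k <- 0:(L - 1)
  hi <- (-1)^k * lo[L - k]
  list(lo = lo, hi = hi)
}

# One periodized analysis step. Odd-length inputs are extended by repeating
# the final sample. Convolution convention (0-based):
#   y[k] = sum_m f[m] x[(2k + 1 - m) mod n],  k = 0 .. n/2 - 1.
.dwt_step <- function(x, filt) {
  n <- length(x)
  if (n %% 2 == 1) {
    x <- c(x, x[n])
    n <- n + 1
  }
  L <- length(filt$lo)
  k <- seq_len(n / 2)
  idx <- outer(2 * k - 1, 0:(L - 1), function(a, m) ((a - m) %% n) + 1)
  xm <- matrix(x[idx], nrow = n / 2)
  list(approx = as.numeric(xm %*% filt$lo),
       detail = as.numeric(xm %*% filt$hi))
}

#' Detail coefficients of a periodized DWT
#'
#' Iterates the analysis filter bank on the approximation channel and
#' returns the detail coefficients at the requested level. Periodized
#' boundary handling keeps `ceiling(n / 2^level)` coefficients per level, so
#' any level up to `floor(log2(n))` is reachable regardless of filter
#' length.
#'
#' @param x Numeric signal.
#' @param level Decomposition level (>= 1).
#' @param wavelet Filter family, see [wavelet_filters()].
#' @return Numeric vector of level-`level` detail coefficients.
#' @export
dwt_detail <- function(x, level, wavelet = "sym16") {
  stopifnot(level >= 1, length(x) >= 2^level)
  filt <- wavelet_filters(wavelet)
  a <- x
  for (j in seq_len(level - 1)) a <- .dwt_step(a, filt)$approx
  .dwt_step(a, filt)$detail
}

#' Modulus maxima of a coefficient sequence
#'
#' A point is a modulus maximum when its absolute value is at least as large
#' as both neighbours and strictly larger than at least one of them.
#' Boundary points cannot qualify.
#'
#' @param x Numeric vector.
#' @return Vector of the same length holding `abs(x)` at modulus maxima and
#'   0 elsewhere.
#' @export
modulus_maxima <- function(x) {
  n <- length(x)
  m <- abs(x)
  if (n < 3) return(numeric(n))
  out <- numeric(n)
  i <- 2:(n - 1)
  is_max <- (m[i - 1] <= m[i]) & (m[i] >= m[i + 1]) &
    ((m[i - 1] < m[i]) | (m[i] > m[i + 1]))
  out[i][is_max] <- m[i][is_max]
  out
}
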
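# Coiflet-5 orthonormal scaling (low-pass analysis) filter, 30 taps.
# Standard published coefficients; the quadrature mirror high-pass and the
# synthesis filters are derived from it below.
COIF5_DEC_LO <- c(
  -9.60401011276789415e-08, -1.62379951720483376e-07,
   2.06122039857887835e-06,  3.70072771133947962e-06,
  -2.12702216725156143e-05, -4.12198619242655010e-05,
   1.40356328123732431e-04,  3.01857941668244784e-04,
  -6.37558926125881154e-04, -1.66162730392987882e-03,
   2.43157544253828862e-03,  6.76152022062041693e-03,
  -9.15950733867616253e-03, -1.97583916009654650e-02,
   3.26747994670573555e-02,  4.12875304721178338e-02,
  -1.05563151307337233e-01, -6.20377515749819600e-02,
   4.37982306659163378e-01,  7.74293622860327435e-01,
   4.21571266730754346e-01, -5.20466702535547637e-02,
  -9.19215880600860874e-02,  2.81697442705323535e-02,
   2.34083221189277831e-02, -1.01315848469002764e-02,
  -4.15931262757864018e-03,  2.17829437784569473e-03,
   3.58577741161757678e-04, -2.12081862067494000e-04)

# quadrature mirror: g[m] = (-1)^m h[M-1-m]
qmf_highpass <- function(h) {
  M <- length(h)
  rev(h) * (-1)^(seq_len(M) - 1L)
}

# circular (periodized) analysis step: y_a[k] = sum_m h[m+1] x[(2k+m) mod N]
# for k = 0..N/2-1, and likewise for the high-pass. N must be even.
dwt_step <- function(x, h, g) {
  N <- length(x)
  half <- N %/% 2L
  k2 <- 2L * (seq_len(half) - 1L)  # 0, 2, 4, ...
  a <- numeric(half)
  d <- numeric(half)
  for (m in seq_along(h)) {
    idx <- (k2 + (m - 1L)) %% N + 1L
    a <- a + h[m] * x[idx]
    d <- d + g[m] * x[idx]
  }
  list(approx = a, detail = d)
}

# circular synthesis step (transpose of the orthogonal analysis operator):
# x[n] = sum_k a[k] h[(n-2k) mod N] + d[k] g[(n-2k) mod N]
idwt_step <- function(a, d, h, g) {
  half <- length(a)
  N <- 2L * half
  x <- numeric(N)
  k2 <- 2L * (seq_len(half) - 1L)
  for (m in seq_along(h)) {
    idx <- (k2 + (m - 1L)) %% N + 1L
    contrib <- h[m] * a + g[m] * d
    # scatter-add; idx values are unique for fixed m
    x[idx] <- x[idx] + contrib
  }
  x
}

#' Multi-level discrete wavelet decomposition (periodized, Coiflet-5)
#'
#' Decomposes a series into `levels` octave bands with the orthonormal
#' Coiflet-5 filter pair applied circularly (periodized transform), each
#' level splitting the running approximation into a half-length
#' approximation and detail. The input length must be divisible by
#' `2^levels`; [dwt_denoise()] handles padding.
#'
#' @param x numeric series, length divisible by `2^levels`.
#' @param levels number of decomposition levels.
#' @return list with `approx` (deepest approximation) and `details`
#'   (list of detail vectors, level 1 first).
#' @export
dwt_decompose <- function(x, levels) {
  h <- COIF5_DEC_LO
  g <- qmf_highpass(h)
  if (length(x) %% 2L^levels != 0L)
    stop("parameter error: length must be divisible by 2^levels")
  if (length(x) < 2L * length(h))
    stop("parameter error: series shorter than the filter support")
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a, h, g)
    a <- s$approx
    details[[j]] <- s$detail
  }
  list(approx = a, details = details)
}

#' Multi-level inverse discrete wavelet transform (periodized, Coiflet-5)
#'
#' @param decomp list as returned by [dwt_decompose()]; detail vectors may
#'   be zeroed for approximation-only reconstruction.
#' @return reconstructed numeric series.
#' @export
dwt_reconstruct <- function(decomp) {
  h <- COIF5_DEC_LO
  g <- qmf_highpass(h)
  a <- decomp$approx
  for (j in rev(seq_along(decomp$details)))
    a <- idwt_step(a, decomp$details[[j]], h, g)
  a
}

# approximation-only reconstruction after `levels` decompositions,
# on an already padded (divisible-length) series
dwt_approx_padded <- function(x, levels) {
  dec <- dwt_decompose(x, levels)
  for (j in seq_along(dec$details))
    dec$details[[j]] <- numeric(length(dec$details[[j]]))
  dwt_reconstruct(dec)
}

#' Wavelet band-difference denoising of the tilt signal
#'
#' Computes approximation-only Coiflet-5 reconstructions of `sin_theta`
#' after `j_lo` and `j_hi` decomposition levels (all detail components
#' suppressed to zero), and their difference. At 128 samples/s the
#' level-3 approximation band is roughly 0-8 Hz and the level-10 band
#' roughly 0-0.0625 Hz, so the difference `r3 - r10` keeps the
#' postural-transition band while removing residual integration drift and
#' the static posture baseline. The signal is extended by symmetric
#' (half-sample) reflection to the next multiple of `2^j_hi` before the
#' periodized transform and cropped back afterwards, so the output length
#' equals the input length.
#'
#' @param sin_theta numeric series (sine of the tilt angle, in [-1, 1]).
#' @param j_lo shallow decomposition depth (default 3).
#' @param j_hi deep decomposition depth (default 10).
#' @return list with `r3`, `r10` and `tilt_denoise = r3 - r10`, each of
#'   `length(sin_theta)`.
#' @export
dwt_denoise <- function(sin_theta, j_lo = 3L, j_hi = 10L) {
  n <- length(sin_theta)
  if (n < 2L * length(COIF5_DEC_LO))
    stop("parameter error: series shorter than one filter length")
  block <- 2L^j_hi
  target <- block * ceiling(n / block)
  padded <- symmetric_extend(sin_theta, target)
  r_lo <- dwt_approx_padded(padded, j_lo)[seq_len(n)]
  r_hi <- dwt_approx_padded(padded, j_hi)[seq_len(n)]
  list(r3 = r_lo, r10 = r_hi, tilt_denoise = r_lo - r_hi)
}

# extend x to `target` samples by repeated half-sample symmetric reflection
symmetric_extend <- function(x, target) {
  n <- length(x)
  if (target == n) return(x)
  ext <- x
  flip <- rev(x)
  while (length(ext) < target) {
    ext <- c(ext, flip)
    flip <- rev(flip)
  }
  ext[seq_len(target)]
}
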
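# one forward IIR pass initialized at the steady state for a constant
# input at level x[1] (removes the start-up transient)
filter_ss <- function(b, a, x) {
  g <- sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], length(b) - 1L),
                            init.y = rep(g * x[1], length(a) - 1L)))
}

#' Zero-phase Butterworth low-pass filter for the accelerometer
#'
#' Each accelerometer axis is filtered with a 4th-order Butterworth
#' low-pass design (cut-off 5 Hz by default, the upper edge of the human
#' movement band) applied forward and backward, giving zero phase lag and
#' an effective 8th-order magnitude response with unit DC gain. Edges are
#' handled by odd-reflective padding of 1 s with steady-state filter
#' initialization. Gyroscope streams are deliberately not low-pass
#' filtered; bias removal is the only gyroscope conditioning.
#'
#' @param rec an [imu_recording()], or an n x 3 numeric matrix at
#'   `sample_rate`.
#' @param cutoff_hz cut-off frequency, Hz; must be below the Nyquist rate.
#' @param order filter order of the one-way design.
#' @param sample_rate sampling rate, required when `rec` is a bare matrix.
#' @return n x 3 matrix of filtered accelerations, m/s^2.
#' @export
lowpass_accel <- function(rec, cutoff_hz = 5, order = 4,
                          sample_rate = NULL) {
  if (inherits(rec, "imu_recording")) {
    mat <- rec$accel
    fs <- rec$sample_rate
  } else {
    mat <- as.matrix(rec)
    fs <- sample_rate
    if (is.null(fs)) stop("sample_rate required for matrix input")
  }
  if (cutoff_hz >= fs / 2)
    stop("parameter error: cutoff must be below the Nyquist frequency ",
         fs / 2, " Hz")
  if (nrow(mat) < 2L * fs) stop("recording shorter than 2 s")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  pad <- fs  # 1 s
  out <- apply(mat, 2L, function(x) {
    n <- length(x)
    p <- min(pad, n - 1L)
    xp <- c(2 * x[1] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
    y <- filter_ss(bf$b, bf$a, xp)
    y <- rev(filter_ss(bf$b, bf$a, rev(y)))
    y[(p + 1L):(p + n)]
  })
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}

#' Euclidean magnitude of a tri-axial stream
#'
#' @param mat n x 3 numeric matrix.
#' @return numeric vector, per-sample Euclidean norm.
#' @export
vec_magnitude <- function(mat) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat))) stop("non-finite input")
  sqrt(rowSums(mat^2))
}

# causal rolling mean over a trailing window of N samples; the first N-1
# samples average over the available prefix (warm-up)
roll_mean_causal <- function(x, N) {
  n <- length(x)
  if (N <= 1L) stop("parameter error: window must exceed 1 sample")
  if (n < N) stop("series shorter than the window")
  out <- as.numeric(stats::filter(x, rep(1 / N, N), sides = 1))
  k <- seq_len(N - 1L)
  out[k] <- cumsum(x[k]) / k
  out
}

#' Short-term mean and variance over a trailing window
#'
#' Computes the causal short-term mean of a scalar series over a trailing
#' window of `window` samples, and the short-term variance as the trailing
#' window average of the squared deviation of each lagged sample from the
#' short-term mean *at that lag* (the per-lag-mean form, which differs
#' from a fixed-mean windowed variance). The first `window - 1` samples
#' use the available prefix and are flagged as warm-up; downstream
#' stationarity decisions ignore them.
#'
#' @param x numeric series (typically an acceleration or angular-velocity
#'   magnitude).
#' @param window window length in samples (default 128, i.e. 1 s at
#'   128 samples/s).
#' @return list with numeric `mean`, `var` and logical `warmup` vectors,
#'   all of `length(x)`.
#' @export
short_term_stats <- function(x, window = 128L) {
  mu <- roll_mean_causal(x, window)
  v <- roll_mean_causal((x - mu)^2, window)
  warm <- seq_along(x) < window
  list(mean = mu, var = v, warmup = warm)
}

#' Track and remove the gyroscope bias
#'
#' Latches the per-axis gyroscope bias to the instantaneous gyroscope
#' sample whenever the short-term variance of the gyroscope magnitude
#' falls below `threshold` (the sensor is then at rest apart from its
#' bias), and holds the previous value otherwise. Before the first latch
#' the bias is zero. The unbiased stream is `gyro - bias`.
#'
#' @param gyro n x 3 matrix of angular velocities, rad/s.
#' @param gyro_var short-term variance of the gyroscope magnitude,
#'   rad^2/s^2, computed with the same window as [short_term_stats()].
#' @param threshold latch threshold, rad^2/s^2.
#' @param warmup optional logical vector flagging the rolling-statistics
#'   warm-up prefix; no latching happens there (a one-sample window has
#'   zero variance by construction).
#' @return list with n x 3 matrices `bias` and `unbiased`.
#' @export
track_gyro_bias <- function(gyro, gyro_var, threshold = 1e-5,
                            warmup = NULL) {
  gyro <- as.matrix(gyro)
  n <- nrow(gyro)
  stopifnot(length(gyro_var) == n)
  ok <- gyro_var < threshold
  if (!is.null(warmup)) ok <- ok & !warmup
  latch <- which(ok)
  bias <- matrix(0, n, 3L)
  if (length(latch)) {
    src <- findInterval(seq_len(n), latch)
    has <- src > 0L
    bias[has, ] <- gyro[latch[src[has]], , drop = FALSE]
  }
  dimnames(bias) <- list(NULL, c("x", "y", "z"))
  list(bias = bias, unbiased = gyro - bias)
}

#' Run the full preprocessing stage
#'
#' Low-pass filters the accelerometer, computes magnitudes and short-term
#' statistics of both streams, and tracks/removes the gyroscope bias.
#'
#' @param rec an [imu_recording()].
#' @param control a [pt_control()] list (only the `preprocess` section is
#'   used).
#' @return An object of class `preprocessed_streams`: filtered `accel`,
#'   `gyro_unbiased`, `gyro_bias`, magnitudes `accel_mag`/`gyro_mag`,
#'   short-term `accel_mean`/`accel_var`/`gyro_mean`/`gyro_var`, logical
#'   `warmup`, plus `sample_rate` and `window_len`.
#' @export
preprocess_streams <- function(rec, control = pt_control()) {
  p <- control$preprocess
  accel <- lowpass_accel(rec, cutoff_hz = p$cutoff_hz, order = p$order)
  accel_mag <- vec_magnitude(accel)
  sa <- short_term_stats(accel_mag, p$window)
  gyro_mag <- vec_magnitude(rec$gyro)
  sg <- short_term_stats(gyro_mag, p$window)
  bias <- track_gyro_bias(rec$gyro, sg$var, p$bias_var_threshold,
                          warmup = sg$warmup)
  structure(
    list(accel = accel, gyro_unbiased = bias$unbiased,
         gyro_bias = bias$bias,
         accel_mag = accel_mag, accel_mean = sa$mean, accel_var = sa$var,
         gyro_mag = gyro_mag, gyro_mean = sg$mean, gyro_var = sg$var,
         warmup = sa$warmup,
         sample_rate = rec$sample_rate, window_len = p$window),
    class = "preprocessed_streams"
  )
}
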
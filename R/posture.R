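#' Label stationary and active periods
#'
#' A sample is stationary (sp) when the lower back is almost motionless:
#' the filtered acceleration magnitude deviates from standard gravity by
#' less than `accel_dev_thresh`, and the short-term variances of the
#' acceleration and gyroscope magnitudes are below their thresholds.
#' Everything else (and the warm-up prefix of the rolling statistics) is
#' active (ap). Stationary runs shorter than `min_sp_s` are merged into
#' the surrounding active period to suppress flickers, and each interior
#' active segment is bracketed by the last sample of the preceding
#' stationary period (`n_ls`) and the first sample of the following one
#' (`n_rs`) — the anchors used for drift correction.
#'
#' @param pre a [preprocess_streams()] result.
#' @param accel_dev_thresh allowed deviation of the acceleration magnitude
#'   from g0, m/s^2.
#' @param accel_var_thresh short-term acceleration variance threshold,
#'   m^2/s^4.
#' @param gyro_var_thresh short-term gyroscope variance threshold,
#'   rad^2/s^2.
#' @param g0 standard gravity, m/s^2.
#' @param min_sp_s minimum stationary-run duration, s.
#' @return An object of class `activity_mask`: list with `labels`
#'   (character `"sp"`/`"ap"` per sample), `segments` (data.frame with
#'   `kind`, `first`, `last`, and for ap rows `n_ls`, `n_rs`), and flag
#'   `no_anchor` when the recording contains no stationary period.
#' @export
detect_stationary <- function(pre, accel_dev_thresh = 0.05,
                              accel_var_thresh = 0.01,
                              gyro_var_thresh = 0.01,
                              g0 = 9.81, min_sp_s = 0.25) {
  sp <- abs(pre$accel_mag - g0) < accel_dev_thresh &
    pre$accel_var < accel_var_thresh &
    pre$gyro_var < gyro_var_thresh &
    !pre$warmup
  min_run <- max(1L, round(min_sp_s * pre$sample_rate))
  r <- rle(sp)
  r$values[r$values & r$lengths < min_run] <- FALSE
  sp <- inverse.rle(r)
  labels <- ifelse(sp, "sp", "ap")
  segments <- mask_segments(labels)
  structure(list(labels = labels, segments = segments,
                 no_anchor = !any(sp),
                 sample_rate = pre$sample_rate),
            class = "activity_mask")
}

# derive alternating segments and ap anchors from per-sample labels
mask_segments <- function(labels) {
  r <- rle(labels)
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  seg <- data.frame(kind = r$values, first = first, last = last,
                    stringsAsFactors = FALSE)
  seg$n_ls <- NA_integer_
  seg$n_rs <- NA_integer_
  ap <- which(seg$kind == "ap")
  for (i in ap) {
    if (i > 1L) seg$n_ls[i] <- seg$last[i - 1L]
    if (i < nrow(seg)) seg$n_rs[i] <- seg$first[i + 1L]
  }
  seg
}

#' @export
print.activity_mask <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("sp", "ap")))
  cat("Activity mask:", tab[["sp"]], "sp /", tab[["ap"]], "ap samples in",
      nrow(x$segments), "segments\n")
  if (x$no_anchor) cat("  flag: no stationary anchor\n")
  invisible(x)
}

#' Tilt angle during stationary periods
#'
#' During a stationary period the accelerometer measures only gravity, so
#' the sagittal tilt follows from the vertical (x) and anterior-posterior
#' (z) components: `theta = atan2(g_z, g_x)`, mapped to `[0, 2*pi)` by
#' adding `2*pi` when `g_z < 0`.
#'
#' @param accel n x 3 filtered acceleration matrix, m/s^2.
#' @param mask an `activity_mask`; only sp samples are evaluated.
#' @return numeric vector of length n: tilt in radians on sp samples,
#'   `NA` elsewhere.
#' @export
tilt_stationary <- function(accel, mask) {
  if (mask$no_anchor) stop("no stationary samples in recording")
  th <- rep(NA_real_, nrow(accel))
  sp <- mask$labels == "sp"
  gx <- accel[sp, 1]
  gz <- accel[sp, 3]
  v <- atan2(gz, gx)
  v[gz < 0] <- v[gz < 0] + 2 * pi
  th[sp] <- v
  th
}

#' Tilt angle during active periods, drift-corrected
#'
#' For each active segment the medio-lateral angular velocity is
#' integrated (forward rectangle rule at `1/f_s`) from the tilt at the
#' left anchor `n_ls`, producing a drifting estimate; the linear drift
#' with slope `(theta_drift(n_rs) - theta_sp(n_rs)) / (n_rs - n_ls)` is
#' then subtracted so the corrected tilt matches the accelerometer-derived
#' tilt at both anchors. The integral is left unwrapped inside the
#' segment; the right-anchor target is taken modulo `2*pi` nearest to the
#' drifting estimate so a wrap of the stationary tilt cannot inject an
#' artificial `2*pi` ramp. Edge segments missing an anchor are integrated
#' from the available side without drift correction and flagged.
#'
#' @param gyro_unbiased n x 3 unbiased gyroscope matrix, rad/s.
#' @param mask an `activity_mask`.
#' @param theta_sp output of [tilt_stationary()].
#' @param sample_rate samples/s.
#' @return list with `theta_ap` (rad on ap samples, `NA` elsewhere),
#'   `theta_with_drift`, per-segment `drift_slope` (rad/sample) and
#'   logical `uncorrected` per ap segment.
#' @export
tilt_active <- function(gyro_unbiased, mask, theta_sp, sample_rate) {
  n <- nrow(gyro_unbiased)
  wy <- gyro_unbiased[, 2]
  theta_ap <- rep(NA_real_, n)
  theta_drift <- rep(NA_real_, n)
  seg <- mask$segments
  apseg <- which(seg$kind == "ap")
  slope <- rep(NA_real_, length(apseg))
  uncorrected <- rep(FALSE, length(apseg))
  dt <- 1 / sample_rate
  for (s in seq_along(apseg)) {
    i <- apseg[s]
    first <- seg$first[i]; last <- seg$last[i]
    n_ls <- seg$n_ls[i]; n_rs <- seg$n_rs[i]
    if (is.na(n_ls) && is.na(n_rs)) {
      uncorrected[s] <- TRUE
      next  # no anchor at all: tilt unavailable on this segment
    }
    if (!is.na(n_ls)) {
      # integrate forward from the left anchor over n_ls .. n_rs (or end)
      stop_at <- if (!is.na(n_rs)) n_rs else last
      idx <- n_ls:stop_at
      th <- theta_sp[n_ls] + c(0, cumsum(wy[idx[-length(idx)]])) * dt
      if (!is.na(n_rs)) {
        target <- theta_sp[n_rs]
        # nearest 2*pi representative of the target to the drifting endpoint
        target <- target + 2 * pi * round((th[length(th)] - target) / (2 * pi))
        k <- (th[length(th)] - target) / (n_rs - n_ls)
        slope[s] <- k
        corr <- th - k * (idx - n_ls)
      } else {
        uncorrected[s] <- TRUE
        corr <- th
      }
      inside <- idx >= first & idx <= last
      theta_drift[idx[inside]] <- th[inside]
      theta_ap[idx[inside]] <- corr[inside]
    } else {
      # only a right anchor: integrate backward, no drift correction
      idx <- first:n_rs
      th <- theta_sp[n_rs] - rev(c(0, cumsum(rev(wy[idx[-1]])))) * dt
      uncorrected[s] <- TRUE
      inside <- idx <= last
      theta_drift[idx[inside]] <- th[inside]
      theta_ap[idx[inside]] <- th[inside]
    }
  }
  list(theta_ap = theta_ap, theta_with_drift = theta_drift,
       drift_slope = slope, uncorrected = uncorrected)
}

#' Full tilt series with wavelet denoising
#'
#' Concatenates the stationary and active tilt estimates into one
#' continuous tilt angle, takes its sine (scaling to [-1, 1]) and computes
#' the level-3 / level-10 Coiflet-5 approximation reconstructions and
#' their difference, the band-passed signal whose prominent peaks mark
#' candidate postural transitions.
#'
#' @param pre a [preprocess_streams()] result.
#' @param mask an `activity_mask` from [detect_stationary()].
#' @param control a [pt_control()] list.
#' @return An object of class `tilt_series`: list with `theta`,
#'   `sin_theta`, `r3`, `r10`, `tilt_denoise`, `drift_slope`,
#'   `uncorrected`.
#' @export
tilt_series <- function(pre, mask, control = pt_control()) {
  po <- control$posture
  theta_sp <- tilt_stationary(pre$accel, mask)
  act <- tilt_active(pre$gyro_unbiased, mask, theta_sp, pre$sample_rate)
  theta <- ifelse(mask$labels == "sp", theta_sp, act$theta_ap)
  # samples with no tilt estimate (anchor-free edges): carry nearest value
  if (anyNA(theta)) theta <- fill_nearest(theta)
  s <- sin(theta)
  dn <- dwt_denoise(s, j_lo = po$j_lo, j_hi = po$j_hi)
  structure(list(theta = theta, sin_theta = s,
                 r3 = dn$r3, r10 = dn$r10,
                 tilt_denoise = dn$tilt_denoise,
                 drift_slope = act$drift_slope,
                 uncorrected = act$uncorrected),
            class = "tilt_series")
}

# replace NA runs by the nearest finite neighbour (constant extrapolation)
fill_nearest <- function(x) {
  ok <- which(!is.na(x))
  if (!length(ok)) stop("no finite samples to extend from")
  idx <- seq_along(x)
  x[] <- x[ok[pmax(1L, findInterval(idx, ok))]]
  # findInterval gives the left neighbour; leading NAs take the first value
  x
}
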
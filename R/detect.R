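# indices of strict local maxima; plateaus contribute their last sample
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  s <- sign(d)
  # carry the previous non-zero slope through plateaus
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  which(diff(s) < 0) + 1L
}

# topographic prominence of the peak at index i of series v (a maximum):
# height above the higher of the two minima separating it from higher
# terrain on each side; series ends act as walls
peak_prominence <- function(v, i) {
  n <- length(v)
  h <- v[i]
  left_base <- if (i == 1L) h else {
    j <- i - 1L; m <- v[j]
    while (j > 1L && v[j] <= h) { j <- j - 1L; if (v[j] < m) m <- v[j] }
    if (v[j] > h) m else min(m, v[j])
  }
  right_base <- if (i == n) h else {
    j <- i + 1L; m <- v[j]
    while (j < n && v[j] <= h) { j <- j + 1L; if (v[j] < m) m <- v[j] }
    if (v[j] > h) m else min(m, v[j])
  }
  h - max(left_base, right_base)
}

#' Find candidate postural-transition peaks
#'
#' Locates local extrema of the denoised tilt signal whose absolute
#' height and topographic prominence both exceed their thresholds. Both
#' polarities are examined (maxima of the signal and of its negation)
#' because the sagittal sign depends on sensor mounting; the transition
#' direction is decided later from the vertical displacement, never from
#' the peak sign. Candidates closer than the merge window keep only the
#' one with the larger absolute value (ties resolved to the earlier
#' sample).
#'
#' @param tilt_denoise numeric series (difference of wavelet
#'   reconstructions, dimensionless).
#' @param height minimum absolute peak height.
#' @param prominence minimum topographic prominence.
#' @param sample_rate samples/s (used for the merge window).
#' @param merge_window_s merge window in seconds.
#' @return integer vector of peak indices, sorted.
#' @export
find_pt_peaks <- function(tilt_denoise, height = 0.1, prominence = 0.1,
                          sample_rate = 128, merge_window_s = 1) {
  if (any(!is.finite(tilt_denoise))) stop("non-finite tilt signal")
  cand <- integer(0)
  val <- numeric(0)
  for (sgn in c(1, -1)) {
    v <- sgn * tilt_denoise
    for (i in local_maxima(v)) {
      if (v[i] > height && peak_prominence(v, i) > prominence) {
        cand <- c(cand, i)
        val <- c(val, v[i])
      }
    }
  }
  if (!length(cand)) return(integer(0))
  o <- order(-val, cand)
  keep <- integer(0)
  win <- merge_window_s * sample_rate
  for (i in o) {
    if (!length(keep) || all(abs(cand[keep] - cand[i]) >= win))
      keep <- c(keep, i)
  }
  sort(cand[keep])
}

#' Locate transition boundaries by gyroscope zero crossings
#'
#' The beginning of a postural transition is the nearest zero crossing of
#' the medio-lateral angular velocity left of the peak with negative
#' local slope (sample `k` with `omega_y(k) >= 0 > omega_y(k+1)`; the
#' boundary sits at `k`, the last non-negative sample), and the end is
#' the nearest such crossing at or right of the peak. The search is
#' capped at `max_search_s`; if no crossing is found the enclosing active
#' segment's stationary anchor is used and the event flagged.
#'
#' @param omega_y medio-lateral angular velocity, rad/s.
#' @param peak peak sample index.
#' @param sample_rate samples/s.
#' @param max_search_s search cap, seconds.
#' @param mask optional `activity_mask` supplying fallback anchors.
#' @return list with `start_index`, `end_index`, and logical
#'   `fallback` flags for each side.
#' @export
locate_boundaries <- function(omega_y, peak, sample_rate,
                              max_search_s = 5, mask = NULL) {
  n <- length(omega_y)
  if (peak < 1L || peak > n) stop("peak outside the series")
  span <- round(max_search_s * sample_rate)
  neg_cross <- function(k) omega_y[k] >= 0 && omega_y[k + 1L] < 0
  start_index <- NA_integer_
  for (k in seq(peak - 1L, max(1L, peak - span))) {
    if (k < 1L) break
    if (neg_cross(k)) { start_index <- k; break }
  }
  end_index <- NA_integer_
  if (peak < n) {
    for (k in seq(peak, min(n - 1L, peak + span))) {
      if (neg_cross(k)) { end_index <- k; break }
    }
  }
  fallback <- c(start = is.na(start_index), end = is.na(end_index))
  if (any(fallback)) {
    anchors <- fallback_anchors(mask, peak, n)
    if (is.na(start_index)) start_index <- anchors$left
    if (is.na(end_index)) end_index <- anchors$right
  }
  if (start_index >= peak) start_index <- max(1L, peak - 1L)
  if (end_index <= peak) end_index <- min(n, peak + 1L)
  list(start_index = start_index, end_index = end_index,
       fallback = fallback)
}

fallback_anchors <- function(mask, peak, n) {
  left <- 1L; right <- n
  if (!is.null(mask)) {
    seg <- mask$segments
    i <- which(seg$first <= peak & seg$last >= peak)
    if (length(i) == 1L && seg$kind[i] == "ap") {
      if (!is.na(seg$n_ls[i])) left <- seg$n_ls[i]
      if (!is.na(seg$n_rs[i])) right <- seg$n_rs[i]
    }
  }
  list(left = left, right = right)
}

#' Classify candidate transitions by vertical displacement
#'
#' Computes the vertical displacement change over each event span
#' (`d_z(end) - d_z(start)`). Events with `|delta_dz|` at or above the
#' threshold are effective postural transitions, directed sit-to-stand
#' for positive and stand-to-sit for negative displacement; the rest are
#' attempts (e.g. forward leans). Events spanning samples where the
#' displacement is unavailable are flagged attempts of unknown direction.
#'
#' @param peaks integer vector of peak indices.
#' @param boundaries list of boundary lists (one per peak, see
#'   [locate_boundaries()]).
#' @param d_z vertical displacement series, m.
#' @param tilt_denoise denoised tilt series (for the peak value).
#' @param sample_rate samples/s.
#' @param dz_threshold effective-transition threshold, m.
#' @param max_duration_s durations beyond this are flagged.
#' @return A `pt_events` data.frame: `peak_index`, `start_index`,
#'   `end_index`, `start_s`, `end_s`, `duration`, `delta_dz`, `direction`
#'   (`SiSt`/`StSi`/`unknown`), `klass` (`effective`/`attempt`),
#'   `peak_value`, `flags`.
#' @export
classify_events <- function(peaks, boundaries, d_z, tilt_denoise,
                            sample_rate, dz_threshold = 0.1,
                            max_duration_s = 10) {
  m <- length(peaks)
  ev <- data.frame(peak_index = integer(m), start_index = integer(m),
                   end_index = integer(m), start_s = numeric(m),
                   end_s = numeric(m), duration = numeric(m),
                   delta_dz = numeric(m),
                   direction = character(m), klass = character(m),
                   peak_value = numeric(m), flags = character(m),
                   stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    b <- boundaries[[i]]
    s <- b$start_index; e <- b$end_index
    flags <- character(0)
    if (any(b$fallback)) flags <- c(flags, "fallback_boundary")
    dz <- if (is.finite(d_z[s]) && is.finite(d_z[e]))
      d_z[e] - d_z[s] else NA_real_
    if (is.na(dz)) {
      klass <- "attempt"; dir <- "unknown"
      flags <- c(flags, "no_kinematics")
      dz_out <- NA_real_
    } else {
      klass <- if (abs(dz) >= dz_threshold) "effective" else "attempt"
      dir <- if (dz > 0) "SiSt" else if (dz < 0) "StSi" else "unknown"
      dz_out <- dz
    }
    dur <- (e - s) / sample_rate
    if (dur > max_duration_s) flags <- c(flags, "long_duration")
    ev[i, c("peak_index", "start_index", "end_index")] <- c(peaks[i], s, e)
    ev$start_s[i] <- (s - 1L) / sample_rate
    ev$end_s[i] <- (e - 1L) / sample_rate
    ev$duration[i] <- dur
    ev$delta_dz[i] <- dz_out
    ev$direction[i] <- dir
    ev$klass[i] <- klass
    ev$peak_value[i] <- tilt_denoise[peaks[i]]
    ev$flags[i] <- paste(flags, collapse = ";")
  }
  class(ev) <- c("pt_events", "data.frame")
  ev
}

#' Keep only effective postural transitions
#'
#' @param events a `pt_events` data.frame.
#' @return the effective subset.
#' @export
effective_events <- function(events) {
  out <- events[events$klass == "effective", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect postural transitions in an IMU recording
#'
#' Runs the full pipeline: accelerometer low-pass filtering and gyroscope
#' bias removal, stationary-period detection, drift-corrected tilt
#' estimation, Coiflet-5 wavelet denoising, quaternion 6DOF fusion to
#' drift-corrected vertical displacement, peak detection on the denoised
#' tilt, boundary localization by gyroscope zero crossings, and
#' classification into effective transitions versus attempts with
#' direction from the sign of the vertical displacement. Deterministic
#' for fixed input and control parameters.
#'
#' @param rec an [imu_recording()].
#' @param control a [pt_control()] list.
#' @param keep_series keep the intermediate per-sample series in the
#'   returned object (default `TRUE`; set `FALSE` to save memory).
#' @return An object of class `pt_detection`: list with `events`
#'   (all candidates, classified), `effective` (effective subset),
#'   `counts` (per-stage tallies), `mask`, `control`, `sample_rate` and,
#'   when `keep_series`, the `tilt` series and `kinematics`.
#' @export
pt_detect <- function(rec, control = pt_control(), keep_series = TRUE) {
  stopifnot(inherits(rec, "imu_recording"))
  po <- control$posture
  de <- control$detect
  pre <- preprocess_streams(rec, control)
  mask <- detect_stationary(pre,
                            accel_dev_thresh = po$accel_dev_thresh,
                            accel_var_thresh = po$accel_var_thresh,
                            gyro_var_thresh = po$gyro_var_thresh,
                            g0 = po$g0, min_sp_s = po$min_sp_s)
  if (mask$no_anchor) {
    events <- classify_events(integer(0), list(), numeric(0), numeric(0),
                              rec$sample_rate, de$dz_threshold)
    return(structure(list(events = events, effective = events,
                          counts = c(sp_segments = 0L, peaks = 0L,
                                     attempts = 0L, effective = 0L),
                          mask = mask, control = control,
                          sample_rate = rec$sample_rate,
                          no_anchor = TRUE),
                     class = "pt_detection"))
  }
  tilt <- tilt_series(pre, mask, control)
  qs <- fuse_orientation(pre, mask, control)
  ef <- to_earth_frame(pre$accel, qs, g0 = po$g0)
  kin <- vertical_displacement(ef$a_T, mask, rec$sample_rate)
  peaks <- find_pt_peaks(tilt$tilt_denoise, height = de$height,
                         prominence = de$prominence,
                         sample_rate = rec$sample_rate,
                         merge_window_s = de$merge_window_s)
  wy <- pre$gyro_unbiased[, 2]
  bounds <- lapply(peaks, function(p)
    locate_boundaries(wy, p, rec$sample_rate,
                      max_search_s = de$max_search_s, mask = mask))
  # denoising ripple can raise a second peak over the same transition;
  # events whose located spans overlap by more than half the shorter
  # span delimit one physical movement — keep the strongest peak
  if (length(peaks) > 1L) {
    s0 <- vapply(bounds, function(b) b$start_index, 0L)
    e0 <- vapply(bounds, function(b) b$end_index, 0L)
    mag <- abs(tilt$tilt_denoise[peaks])
    keep <- rep(TRUE, length(peaks))
    o <- order(-mag, peaks)
    for (i in o) {
      if (!keep[i]) next
      for (j in o) {
        if (j == i || !keep[j]) next
        ov <- min(e0[i], e0[j]) - max(s0[i], s0[j])
        if (ov > 0.5 * min(e0[i] - s0[i], e0[j] - s0[j]) && mag[j] <= mag[i])
          keep[j] <- FALSE
      }
    }
    peaks <- peaks[keep]
    bounds <- bounds[keep]
  }
  d_z_masked <- kin$d_z
  if (qs$start_index > 1L) d_z_masked[seq_len(qs$start_index - 1L)] <- NA
  events <- classify_events(peaks, bounds, d_z_masked, tilt$tilt_denoise,
                            rec$sample_rate,
                            dz_threshold = de$dz_threshold,
                            max_duration_s = de$max_duration_s)
  eff <- effective_events(events)
  out <- list(events = events, effective = eff,
              counts = c(sp_segments = sum(mask$segments$kind == "sp"),
                         peaks = length(peaks),
                         attempts = sum(events$klass == "attempt"),
                         effective = nrow(eff)),
              mask = mask, control = control,
              sample_rate = rec$sample_rate, no_anchor = FALSE)
  if (keep_series) {
    out$tilt <- tilt
    out$kinematics <- kin
    out$quaternions <- qs
  }
  structure(out, class = "pt_detection")
}

#' @export
print.pt_detection <- function(x, ...) {
  cat("Postural transition detection\n")
  cat("  candidate peaks :", x$counts[["peaks"]], "\n")
  cat("  effective PTs   :", x$counts[["effective"]],
      "(", sum(x$effective$direction == "SiSt"), "SiSt /",
      sum(x$effective$direction == "StSi"), "StSi )\n")
  cat("  attempts        :", x$counts[["attempts"]], "\n")
  invisible(x)
}

#' @export
summary.pt_detection <- function(object, ...) {
  eff <- object$effective
  cat("Postural transition detection summary\n")
  cat(sprintf("  stationary segments: %d\n",
              object$counts[["sp_segments"]]))
  cat(sprintf("  candidate peaks:     %d\n", object$counts[["peaks"]]))
  cat(sprintf("  effective PTs:       %d (%d SiSt, %d StSi)\n",
              nrow(eff), sum(eff$direction == "SiSt"),
              sum(eff$direction == "StSi")))
  cat(sprintf("  attempts:            %d\n", object$counts[["attempts"]]))
  if (nrow(eff)) {
    cat(sprintf("  duration: mean %.2f s, sd %.2f s\n",
                mean(eff$duration), stats::sd(eff$duration)))
    cat(sprintf("  |delta d_z|: mean %.3f m\n", mean(abs(eff$delta_dz))))
  }
  invisible(object)
}

#' Plot a detection result
#'
#' Draws the denoised tilt signal with detected peaks and event spans,
#' and the vertical displacement, against time.
#'
#' @param x a `pt_detection` object (needs `keep_series = TRUE`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.pt_detection <- function(x, ...) {
  if (is.null(x$tilt)) stop("detection was run with keep_series = FALSE")
  n <- length(x$tilt$tilt_denoise)
  t <- (seq_len(n) - 1L) / x$sample_rate
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(t, x$tilt$tilt_denoise, type = "l",
                 xlab = "time [s]", ylab = "denoised tilt [-]", ...)
  ev <- x$events
  if (nrow(ev)) {
    graphics::points(t[ev$peak_index], ev$peak_value,
                     pch = 8, col = ifelse(ev$klass == "effective",
                                           "red", "grey50"))
    graphics::segments(ev$start_s, 0, ev$end_s, 0, col = "blue", lwd = 2)
  }
  graphics::plot(t, x$kinematics$d_z, type = "l",
                 xlab = "time [s]", ylab = "vertical displacement [m]")
  invisible(x)
}
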
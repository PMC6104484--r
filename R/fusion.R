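# Hamilton quaternion product, scalar-first 4-vectors
quat_mult <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

quat_conj <- function(q) c(q[1], -q[2], -q[3], -q[4])

# rotate a 3-vector from the sensor frame to the earth frame by unit q
quat_rotate <- function(q, v) {
  quat_mult(quat_mult(q, c(0, v)), quat_conj(q))[2:4]
}

# estimated gravity direction in the sensor frame from a unit quaternion
quat_gravity <- function(q) {
  c(2 * (q[2] * q[4] - q[1] * q[3]),
    2 * (q[1] * q[2] + q[3] * q[4]),
    q[1]^2 - q[2]^2 - q[3]^2 + q[4]^2)
}

#' Estimate sensor orientation by 6DOF quaternion fusion
#'
#' Integrates the unbiased gyroscope through the quaternion kinematic
#' equation, steering the integration toward the accelerometer's gravity
#' direction during stationary periods: the feedback angular velocity is
#' the cross product of the normalized acceleration with the gravity
#' direction predicted by the current quaternion, added with gain `beta`
#' (0.5 during stationary periods, 0 — pure gyro strapdown — during
#' active periods). The quaternion is initialized at the first stationary
#' sample to the mounting orientation that maps the sensor's vertical (x)
#' axis to the earth's z axis, and renormalized after every update.
#' Samples before the first stationary period carry no orientation.
#'
#' @param pre a [preprocess_streams()] result.
#' @param mask an `activity_mask` from [detect_stationary()].
#' @param control a [pt_control()] list (`fusion` section: `beta_sp`,
#'   `beta_ap`, `q0`).
#' @return An object of class `quaternion_series`: list with n x 4 matrix
#'   `q` (unit, scalar-first; `NA` rows before the first stationary
#'   sample), n x 3 `g_est`, `beta` vector, and `start_index` of the first
#'   valid sample.
#' @export
fuse_orientation <- function(pre, mask, control = pt_control()) {
  fu <- control$fusion
  n <- nrow(pre$accel)
  sp <- mask$labels == "sp"
  if (!any(sp)) stop("no stationary sample: orientation unavailable")
  n0 <- which(sp)[1]
  dt <- 1 / pre$sample_rate
  accel <- pre$accel
  gyro <- pre$gyro_unbiased
  amag <- pre$accel_mag
  if (any(amag[n0:n] == 0))
    stop("normalization error: zero acceleration magnitude")
  beta <- ifelse(sp, fu$beta_sp, fu$beta_ap)
  qmat <- matrix(NA_real_, n, 4L)
  gmat <- matrix(NA_real_, n, 3L)
  q <- fu$q0 / sqrt(sum(fu$q0^2))
  for (k in n0:n) {
    g_est <- quat_gravity(q)
    qmat[k, ] <- q
    gmat[k, ] <- g_est
    if (k == n) break
    a_hat <- accel[k, ] / amag[k]
    # feedback fixation: cross product a_hat x g_est
    dw <- c(a_hat[2] * g_est[3] - a_hat[3] * g_est[2],
            a_hat[3] * g_est[1] - a_hat[1] * g_est[3],
            a_hat[1] * g_est[2] - a_hat[2] * g_est[1])
    w <- gyro[k, ] + beta[k] * dw
    qd <- 0.5 * quat_mult(q, c(0, w))
    q <- q + qd * dt
    q <- q / sqrt(sum(q^2))
  }
  structure(list(q = qmat, g_est = gmat, beta = beta, start_index = n0),
            class = "quaternion_series")
}

#' Rotate acceleration to the earth frame and remove gravity
#'
#' Accelerations are normalized by standard gravity, conjugated into the
#' earth frame by the fused quaternion, and the constant earth-frame
#' gravity `[0, 0, 1]` is subtracted; the remainder is rescaled to m/s^2,
#' giving the translational acceleration.
#'
#' @param accel n x 3 filtered acceleration matrix, m/s^2.
#' @param qs a `quaternion_series` from [fuse_orientation()].
#' @param g0 standard gravity, m/s^2.
#' @return list with n x 3 matrices `a_earth` (g-units) and `a_T` (m/s^2);
#'   rows before the fusion start are `NA`.
#' @export
to_earth_frame <- function(accel, qs, g0 = 9.81) {
  n <- nrow(accel)
  a_earth <- matrix(NA_real_, n, 3L)
  n0 <- qs$start_index
  q <- qs$q
  # vectorized quaternion conjugation q [0,v] q* over all samples
  idx <- n0:n
  w <- q[idx, 1]; x <- q[idx, 2]; y <- q[idx, 3]; z <- q[idx, 4]
  v <- accel[idx, , drop = FALSE] / g0
  vx <- v[, 1]; vy <- v[, 2]; vz <- v[, 3]
  # t = 2 q_vec x v ; v' = v + w t + q_vec x t
  tx <- 2 * (y * vz - z * vy)
  ty <- 2 * (z * vx - x * vz)
  tz <- 2 * (x * vy - y * vx)
  a_earth[idx, 1] <- vx + w * tx + (y * tz - z * ty)
  a_earth[idx, 2] <- vy + w * ty + (z * tx - x * tz)
  a_earth[idx, 3] <- vz + w * tz + (x * ty - y * tx)
  a_T <- a_earth
  a_T[idx, 3] <- a_T[idx, 3] - 1
  a_T <- a_T * g0
  list(a_earth = a_earth, a_T = a_T)
}

#' Drift-corrected translational velocity and vertical displacement
#'
#' The translational velocity is fixed to zero on stationary samples.
#' Over each bracketed active segment the translational acceleration is
#' integrated (forward rectangle rule) from zero at the left anchor; the
#' linear drift with slope `v(n_rs)/(n_rs - n_ls)` is removed so the
#' velocity returns to zero at the right anchor; the vertical velocity is
#' then integrated to the vertical displacement, which continues from the
#' segment's starting value and is frozen during stationary periods.
#' Segments missing an anchor get no drift removal and are flagged.
#'
#' @param a_T n x 3 translational acceleration, m/s^2 (from
#'   [to_earth_frame()]).
#' @param mask an `activity_mask`.
#' @param sample_rate samples/s.
#' @return An object of class `kinematics_series`: list with n x 3 `v_T`
#'   (m/s), vector `d_z` (m), per-ap-segment `drift_slope_v` (m/s per
#'   sample, vertical axis) and logical `uncorrected`.
#' @export
vertical_displacement <- function(a_T, mask, sample_rate) {
  n <- nrow(a_T)
  dt <- 1 / sample_rate
  v_T <- matrix(0, n, 3L)
  d_z <- numeric(n)
  seg <- mask$segments
  apseg <- which(seg$kind == "ap")
  slope_v <- rep(NA_real_, length(apseg))
  uncorrected <- rep(FALSE, length(apseg))
  d_cur <- 0
  last_end <- 0L
  for (s in seq_along(apseg)) {
    i <- apseg[s]
    n_ls <- seg$n_ls[i]; n_rs <- seg$n_rs[i]
    a0 <- if (!is.na(n_ls)) n_ls else seg$first[i]
    a1 <- if (!is.na(n_rs)) n_rs else seg$last[i]
    idx <- a0:a1
    acc <- a_T[idx[-length(idx)], , drop = FALSE]
    if (any(!is.finite(acc))) { uncorrected[s] <- TRUE; next }
    v <- rbind(0, apply(acc, 2L, cumsum)) * dt
    if (!is.na(n_ls) && !is.na(n_rs)) {
      k <- v[nrow(v), ] / (a1 - a0)
      slope_v[s] <- k[3]
      v <- v - outer(idx - a0, k)
    } else {
      uncorrected[s] <- TRUE
    }
    v_T[idx, ] <- v
    # displacement: integrate v_z across the segment, carry the entry level
    dz_seg <- d_cur + c(0, cumsum(v[-nrow(v), 3])) * dt
    d_z[idx] <- dz_seg
    # freeze between the previous segment end and this segment start
    if (a0 > last_end + 1L) d_z[(last_end + 1L):(a0 - 1L)] <- d_cur
    d_cur <- dz_seg[length(dz_seg)]
    last_end <- a1
  }
  if (last_end < n) d_z[(last_end + 1L):n] <- d_cur
  structure(list(v_T = v_T, d_z = d_z, drift_slope_v = slope_v,
                 uncorrected = uncorrected),
            class = "kinematics_series")
}
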
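test_that("the initial quaternion maps sensor x to the earth vertical", {
  q0 <- pt_control()$fusion$q0
  expect_equal(ptkit:::quat_gravity(q0), c(1, 0, 0), tolerance = 1e-12)
})

test_that("orientation locks onto gravity when still", {
  rec <- still_recording(duration = 60, noise = 0.01)
  pre <- preprocess_streams(rec)
  mask <- detect_stationary(pre)
  qs <- fuse_orientation(pre, mask)
  q0 <- pt_control()$fusion$q0
  n <- nrow(qs$q)
  expect_lt(max(abs(qs$q[n, ] - q0)), 1e-3)
  # unit norm throughout
  nz <- qs$start_index:n
  expect_lt(max(abs(sqrt(rowSums(qs$q[nz, ]^2)) - 1)), 1e-9)
  expect_lt(max(abs(sqrt(rowSums(qs$g_est[nz, ]^2)) - 1)), 1e-9)
  # beta schedule follows the mask
  expect_true(all(qs$beta[mask$labels == "sp"] == 0.5))
  expect_true(all(qs$beta[mask$labels == "ap"] == 0))
})

test_that("with feedback off the filter is pure strapdown integration", {
  # constant y-rate r for T seconds: rotation angle == r*T (closed form)
  fs <- 128
  r <- 1.0
  dur <- 10
  t <- seq(0, dur + 4, by = 1 / fs)
  n <- length(t)
  active <- t >= 2 & t < 2 + dur
  wy <- ifelse(active, r, 0)
  th <- cumsum(c(0, wy[-n])) / fs  # latent rotation about y
  accel <- cbind(9.81 * cos(th), 0, 9.81 * sin(th))
  # raw streams, no feedback, no bias latch: pure strapdown integration
  ctrl <- pt_control(fusion = list(beta_sp = 0, beta_ap = 0))
  si <- strapdown_inputs(accel, cbind(0, wy, 0), fs)
  qs <- fuse_orientation(si$pre, si$mask, ctrl)
  i1 <- max(which(active))
  onset <- min(which(active))
  q0 <- pt_control()$fusion$q0
  theta_exp <- r * (i1 - onset) / fs
  q_cf <- ptkit:::quat_mult(q0, c(cos(theta_exp / 2), 0,
                                  sin(theta_exp / 2), 0))
  q_err <- ptkit:::quat_mult(ptkit:::quat_conj(q_cf), qs$q[i1, ])
  ang_err <- 2 * atan2(sqrt(sum(q_err[2:4]^2)), abs(q_err[1]))
  expect_lt(ang_err / (r * dur), 0.005)
})

test_that("earth-frame rotation cancels gravity and preserves norms", {
  # identity quaternion with a = (0, 0, g0)
  qs <- structure(list(q = matrix(c(1, 0, 0, 0), 2, 4, byrow = TRUE),
                       start_index = 1L), class = "quaternion_series")
  ef <- to_earth_frame(matrix(c(0, 0, 9.81), 2, 3, byrow = TRUE), qs)
  expect_lt(max(abs(ef$a_T)), 1e-9)

  # converged still upright sensor
  rec <- still_recording(duration = 20, noise = 0.01)
  pre <- preprocess_streams(rec)
  mask <- detect_stationary(pre)
  qsr <- fuse_orientation(pre, mask)
  efr <- to_earth_frame(pre$accel, qsr)
  late <- (nrow(pre$accel) - 256):nrow(pre$accel)
  expect_lt(max(abs(efr$a_T[late, ])), 0.05)

  # rotation by any unit quaternion preserves the vector norm, matching
  # the rotation-matrix oracle built from the same quaternion
  set.seed(17)
  for (k in 1:20) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    v <- rnorm(3)
    qs1 <- structure(list(q = matrix(q, 1), start_index = 1L),
                     class = "quaternion_series")
    out <- to_earth_frame(matrix(v * 9.81, 1), qs1)$a_earth[1, ]
    R <- rbind(
      c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
        2 * (q[2] * q[4] + q[1] * q[3])),
      c(2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
        2 * (q[3] * q[4] - q[1] * q[2])),
      c(2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
        1 - 2 * (q[2]^2 + q[3]^2)))
    expect_equal(out, as.numeric(R %*% v), tolerance = 1e-9)
    expect_equal(sqrt(sum(out^2)), sqrt(sum(v^2)), tolerance = 1e-9)
  }
})

test_that("velocity drift removal zeroes anchors and constant spurious
           acceleration integrates to zero displacement", {
  n <- 1280L
  lab <- rep("sp", n)
  lab[400:900] <- "ap"
  mask <- structure(list(labels = lab,
                         segments = ptkit:::mask_segments(lab),
                         no_anchor = FALSE, sample_rate = 128),
                    class = "activity_mask")

  # a_T identically zero: no velocity, flat displacement
  kin0 <- vertical_displacement(matrix(0, n, 3), mask, 128)
  expect_true(all(kin0$v_T == 0))
  expect_equal(kin0$d_z, rep(0, n))

  # constant spurious a_T: linear velocity ramp is exactly linear drift
  aT <- matrix(0, n, 3); aT[, 3] <- 0.3
  kin <- vertical_displacement(aT, mask, 128)
  expect_lt(max(abs(kin$v_T[, 3])), 1e-9)
  expect_lt(abs(kin$d_z[n] - kin$d_z[1]), 1e-6)
  # v_T exactly zero at both anchors of the bracketed segment
  seg <- mask$segments
  ap <- seg[seg$kind == "ap" & !is.na(seg$n_ls), ][1, ]
  expect_equal(kin$v_T[ap$n_ls, 3], 0)
  expect_equal(kin$v_T[ap$n_rs, 3], 0)
})

test_that("a simulated stand-up recovers the vertical rise", {
  sim <- single_pt_session(rise = 0.25, noise_accel = 0.02,
                           noise_gyro = 0.005)
  det <- pt_detect(sim$recording)
  eff <- det$effective
  expect_equal(nrow(eff), 1L)
  expect_lt(abs(eff$delta_dz - 0.25), 0.05)
  expect_equal(eff$direction, "SiSt")
})

test_that("time reversal flips the displacement sign", {
  sim <- single_pt_session(direction = "SiSt", rise = 0.25,
                           noise_accel = 0.05, noise_gyro = 0.01)
  rec <- sim$recording
  n <- nrow(rec$accel)
  rev_rec <- imu_recording(rec$time, rec$accel[n:1, ], -rec$gyro[n:1, ],
                           sample_rate = rec$sample_rate)
  d1 <- pt_detect(rec)$effective
  d2 <- pt_detect(rev_rec)$effective
  expect_equal(nrow(d1), 1L)
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$direction, "StSi")
  expect_lt(abs(d2$delta_dz + d1$delta_dz) / abs(d1$delta_dz), 0.05)
})
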
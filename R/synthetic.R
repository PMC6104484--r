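# quintic smoothstep and derivatives: C^2 position profile so the
# simulated accelerometer contains no jump discontinuities
smoothstep5 <- function(u) 6 * u^5 - 15 * u^4 + 10 * u^3
smoothstep5_d2 <- function(u) 120 * u^3 - 180 * u^2 + 60 * u

#' Build a simulation configuration
#'
#' Describes a synthetic lower-back IMU session: scheduled postural
#' transitions (trunk flexion-extension plus a vertical center-of-mass
#' step), confounders, sensor imperfections and noise levels. Episodes
#' must not overlap, and the session must cover every scheduled item with
#' a 5 s margin.
#'
#' @param seed integer random seed; the session is reproducible from it.
#' @param duration session length, s.
#' @param sample_rate samples/s.
#' @param pt_schedule data.frame with columns `time` (episode start, s),
#'   `direction` (`"SiSt"`/`"StSi"`), `tilt_peak` (flexion amplitude,
#'   rad), `rise_height` (vertical displacement magnitude, m),
#'   `episode_duration` (s).
#' @param confounders data.frame with columns `time`, `kind`
#'   (`"lean"`: flexion bump with zero rise; `"dyskinesia"`: sustained
#'   band-limited 0.5-3 Hz angular noise on all axes; `"fidget"`: small
#'   brief flexion wiggle), `amplitude` (rad for lean/fidget, rad/s
#'   std for dyskinesia), `duration` (s).
#' @param gyro_bias constant gyroscope bias 3-vector, rad/s.
#' @param noise_accel accelerometer white-noise std per axis, m/s^2.
#' @param noise_gyro gyroscope white-noise std per axis, rad/s.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, duration = 60,
                              sample_rate = 128,
                              pt_schedule = NULL, confounders = NULL,
                              gyro_bias = c(0, 0, 0),
                              noise_accel = 0, noise_gyro = 0) {
  if (is.null(pt_schedule))
    pt_schedule <- data.frame(time = numeric(0), direction = character(0),
                              tilt_peak = numeric(0),
                              rise_height = numeric(0),
                              episode_duration = numeric(0))
  if (is.null(confounders))
    confounders <- data.frame(time = numeric(0), kind = character(0),
                              amplitude = numeric(0), duration = numeric(0))
  # tilt-shaped items (PTs, leans, fidgets) must not overlap one another
  tilt_items <- rbind(
    data.frame(time = pt_schedule$time, dur = pt_schedule$episode_duration),
    data.frame(time = confounders$time[confounders$kind != "dyskinesia"],
               dur = confounders$duration[confounders$kind != "dyskinesia"]))
  if (nrow(tilt_items) > 1L) {
    o <- order(tilt_items$time)
    ends <- tilt_items$time[o] + tilt_items$dur[o]
    if (any(tilt_items$time[o][-1L] < ends[-length(ends)]))
      stop("config error: overlapping scheduled episodes")
  }
  if (nrow(tilt_items) &&
      (any(tilt_items$time < 5) ||
       any(tilt_items$time + tilt_items$dur > duration - 5)))
    stop("config error: schedule must leave 5 s margins")
  structure(list(seed = as.integer(seed), duration = duration,
                 sample_rate = sample_rate, pt_schedule = pt_schedule,
                 confounders = confounders, gyro_bias = gyro_bias,
                 noise_accel = noise_accel, noise_gyro = noise_gyro),
            class = "simulation_config")
}

#' Simulate a lower-back IMU session with known ground truth
#'
#' The trunk is modeled as a single rigid segment rotating about the
#' medio-lateral (y) axis. Each postural transition of duration `T`
#' starting at `t0` produces a flexion-extension tilt bump
#' `-tilt_peak * sin^2(pi (t - t0) / T)` (forward flexion reads as a
#' negative sagittal tilt with the x-vertical, z-anterior mounting) and a
#' quintic-smoothstep vertical position change of `+rise_height` for
#' sit-to-stand or `-rise_height` for stand-to-sit. The gyroscope is the
#' tilt rate plus bias, noise, and any dyskinesia component; the
#' accelerometer is earth gravity plus the vertical translational
#' acceleration rotated into the sensor frame, plus noise. Leans reuse
#' the tilt bump with zero rise; dyskinesia adds band-limited
#' (0.5-3 Hz) angular velocity on all axes; fidgets are small flexion
#' wiggles. Output is reproducible from the config seed.
#'
#' @param config a [simulation_config()].
#' @return list with `recording` (an [imu_recording()]) and `truth`
#'   (list with `annotation`, an [annotation_set()] of the scheduled
#'   transitions, and `latent`: per-sample true `theta` (rad, sensor
#'   convention), `d_z` (m), `v_z` (m/s), `omega_y_clean` (rad/s)).
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  fs <- config$sample_rate
  n <- round(config$duration * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  g0 <- 9.81

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
  set.seed(config$seed)

  theta <- numeric(n)       # latent sagittal tilt, algorithm convention
  z <- numeric(n)           # vertical position of the sensor

  add_bump <- function(t0, T, amp) {
    idx <- which(t >= t0 & t <= t0 + T)
    u <- (t[idx] - t0) / T
    theta[idx] <<- theta[idx] - amp * sin(pi * u)^2
  }

  sched <- config$pt_schedule
  level <- 0
  if (nrow(sched)) {
    o <- order(sched$time)
    sched <- sched[o, , drop = FALSE]
    for (i in seq_len(nrow(sched))) {
      t0 <- sched$time[i]; T <- sched$episode_duration[i]
      add_bump(t0, T, sched$tilt_peak[i])
      h <- sched$rise_height[i] *
        (if (sched$direction[i] == "SiSt") 1 else -1)
      idx <- which(t >= t0 & t <= t0 + T)
      u <- (t[idx] - t0) / T
      z[idx] <- level + h * smoothstep5(u)
      level <- level + h
      after <- which(t > t0 + T)
      z[after] <- level
    }
  }

  conf <- config$confounders
  dysk <- matrix(0, n, 3L)
  if (nrow(conf)) {
    for (i in seq_len(nrow(conf))) {
      kind <- conf$kind[i]
      if (kind %in% c("lean", "fidget")) {
        add_bump(conf$time[i], conf$duration[i], conf$amplitude[i])
      } else if (kind == "dyskinesia") {
        idx <- which(t >= conf$time[i] & t <= conf$time[i] + conf$duration[i])
        if (length(idx) > fs) {
          bf <- signal::butter(2, c(0.5, 3) / (fs / 2), type = "pass")
          for (ax in 1:3) {
            w <- as.numeric(signal::filter(bf, stats::rnorm(length(idx))))
            w <- w / max(stats::sd(w), 1e-12) * conf$amplitude[i]
            dysk[idx, ax] <- dysk[idx, ax] + w
          }
        }
      } else stop("config error: unknown confounder kind: ", kind)
    }
  }

  # discrete kinematic consistency: the emitted rates are the per-step
  # average rates (forward differences of the sampled trajectory), so
  # rectangle-rule integration of the streams recovers the latent
  # trajectory sample-exactly
  theta_dot <- c(diff(theta), 0) * fs
  vz <- c(diff(z), 0) * fs
  zdd <- c(diff(vz), 0) * fs
  f <- g0 + zdd   # specific-force magnitude along earth vertical
  accel <- cbind(f * cos(theta), 0, f * sin(theta))
  gyro <- cbind(0, theta_dot, 0) + dysk
  gyro <- sweep(gyro, 2L, config$gyro_bias, "+")
  if (config$noise_accel > 0)
    accel <- accel + matrix(stats::rnorm(3L * n, sd = config$noise_accel),
                            n, 3L)
  if (config$noise_gyro > 0)
    gyro <- gyro + matrix(stats::rnorm(3L * n, sd = config$noise_gyro),
                          n, 3L)

  rec <- imu_recording(t, accel, gyro, sample_rate = fs,
                       meta = list(seed = config$seed,
                                   generator = "simulate_session"))
  ann <- if (nrow(sched))
    annotation_set(sched$time, sched$time + sched$episode_duration,
                   sched$direction, resolution = 1 / fs)
  else annotation_set(numeric(0), numeric(0), character(0),
                      resolution = 1 / fs)
  list(recording = rec,
       truth = list(annotation = ann,
                    latent = list(time = t, theta = theta, d_z = z,
                                  v_z = vz, omega_y_clean = theta_dot)))
}

#' The default synthetic benchmark session
#'
#' A 10-minute home-like session with 10 sit-to-stand and 10 stand-to-sit
#' transitions (flexion peak 0.7 rad, vertical rise 0.25 m, 2 s
#' episodes), interleaved with 10 forward leans (same flexion, zero
#' rise), constant gyroscope bias (0.01, 0.02, -0.01) rad/s,
#' accelerometer noise 0.05 m/s^2 and gyroscope noise 0.01 rad/s.
#' Episodes are spaced 20 s apart in the repeating order
#' sit-to-stand, lean, stand-to-sit.
#'
#' @param seed integer seed.
#' @param dyskinesia if `TRUE`, adds a sustained dyskinesia block
#'   (band-limited 0.5-3 Hz angular noise, 0.25 rad/s per axis) covering
#'   the first half of the session (0-305 s). The noise variance
#'   of its magnitude (about 0.028 rad^2/s^2) decisively exceeds the stationarity gyroscope
#'   threshold, so no stationary period is detected for the whole block
#'   while the induced trunk wobble stays near one degree — emulating a
#'   participant who is continuously moving from the start of the
#'   recording.
#' @return list with `recording` and `truth` (see [simulate_session()]).
#' @export
default_benchmark <- function(seed = 1L, dyskinesia = FALSE) {
  starts <- 10 + 20 * (0:29)
  kind <- rep(c("SiSt", "lean", "StSi"), 10)
  pts <- data.frame(time = starts[kind != "lean"],
                    direction = kind[kind != "lean"],
                    tilt_peak = 0.7, rise_height = 0.25,
                    episode_duration = 2)
  conf <- data.frame(time = starts[kind == "lean"], kind = "lean",
                     amplitude = 0.7, duration = 2)
  if (dyskinesia) {
    dy <- data.frame(time = 0, kind = "dyskinesia",
                     amplitude = 0.25, duration = 305)
    conf <- rbind(conf, dy)
  }
  cfg <- simulation_config(seed = seed, duration = 600, sample_rate = 128,
                           pt_schedule = pts, confounders = conf,
                           gyro_bias = c(0.01, 0.02, -0.01),
                           noise_accel = 0.05, noise_gyro = 0.01)
  simulate_session(cfg)
}
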
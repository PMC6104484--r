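test_that("an empty noise-free config is a motionless upright sensor", {
  cfg <- simulation_config(seed = 1, duration = 10)
  sim <- simulate_session(cfg)
  expect_true(all(sim$recording$accel[, 1] == 9.81))
  expect_true(all(sim$recording$accel[, 2:3] == 0))
  expect_true(all(sim$recording$gyro == 0))
})

test_that("a clean transition closes its angular loop and lifts by the
           configured rise", {
  sim <- single_pt_session(direction = "SiSt", rise = 0.25, T = 2)
  rec <- sim$recording
  ann <- sim$truth$annotation
  i0 <- round(ann$start * 128) + 1L
  i1 <- round(ann$end * 128) + 1L
  # integral of omega_y over the episode returns to zero (flexion then
  # extension), and the latent vertical gain equals the rise height
  expect_lt(abs(sum(rec$gyro[i0:(i1 - 1), 2]) / 128), 1e-9)
  lat <- sim$truth$latent
  expect_equal(lat$d_z[i1] - lat$d_z[i0], 0.25, tolerance = 1e-9)
  expect_equal(max(abs(lat$theta)), 0.7, tolerance = 1e-9)
})

test_that("generation is bit-identical for a fixed seed and leaves the
           global RNG untouched", {
  set.seed(123)
  before <- .Random.seed
  s1 <- default_benchmark(9)
  expect_identical(.Random.seed, before)
  s2 <- default_benchmark(9)
  expect_identical(s1$recording$accel, s2$recording$accel)
  expect_identical(s1$recording$gyro, s2$recording$gyro)
})

test_that("the generator is dynamically self-consistent", {
  # noise-free with bias: omega_y minus bias equals the derivative of the
  # latent tilt; accel norm equals |gravity + translational|
  pts <- data.frame(time = c(8, 16), direction = c("SiSt", "StSi"),
                    tilt_peak = 0.7, rise_height = 0.25,
                    episode_duration = 2)
  cfg <- simulation_config(seed = 2, duration = 25, pt_schedule = pts,
                           gyro_bias = c(0.01, 0.02, -0.01))
  sim <- simulate_session(cfg)
  lat <- sim$truth$latent
  wy <- sim$recording$gyro[, 2] - 0.02
  dtheta <- c(diff(lat$theta) * 128, 0)
  expect_lt(max(abs(wy - lat$omega_y_clean)), 1e-12)
  expect_lt(max(abs(dtheta - wy)), 1e-6)

  zdd <- c(diff(lat$v_z), 0) * 128
  amag <- vec_magnitude(sim$recording$accel)
  expect_lt(max(abs(amag - abs(9.81 + zdd))), 1e-9)
})

test_that("the default benchmark matches its stated composition", {
  sim <- default_benchmark(4)
  ann <- sim$truth$annotation
  expect_equal(nrow(ann), 20L)
  expect_equal(sum(ann$direction == "SiSt"), 10L)
  expect_equal(sum(ann$direction == "StSi"), 10L)
  # alternating without overlap
  expect_true(all(ann$start[-1] >= ann$end[-nrow(ann)]))
  # leans leave the latent height untouched: the latent vertical position
  # only changes inside annotated transitions
  lat <- sim$truth$latent
  outside <- rep(TRUE, length(lat$time))
  for (i in seq_len(nrow(ann)))
    outside[lat$time >= ann$start[i] & lat$time <= ann$end[i]] <- FALSE
  expect_lt(max(abs(diff(lat$d_z)[outside[-1]])), 1e-12)
  expect_equal(nrow(sim$recording$accel), 600 * 128 + 1)
})

test_that("schedule validation rejects overlap and missing margins", {
  pts <- data.frame(time = c(10, 11), direction = c("SiSt", "StSi"),
                    tilt_peak = 0.7, rise_height = 0.25,
                    episode_duration = 2)
  expect_error(simulation_config(duration = 30, pt_schedule = pts),
               "overlap")
  pts2 <- data.frame(time = 1, direction = "SiSt", tilt_peak = 0.7,
                     rise_height = 0.25, episode_duration = 2)
  expect_error(simulation_config(duration = 30, pt_schedule = pts2),
               "margin")
})

test_that("raising sensor noise does not raise detection sensitivity", {
  sens_at <- function(noise_mult) {
    vals <- sapply(1:10, function(s) {
      starts <- 8 + 15 * (0:3)
      pts <- data.frame(time = starts,
                        direction = rep(c("SiSt", "StSi"), 2),
                        tilt_peak = 0.7, rise_height = 0.25,
                        episode_duration = 2)
      cfg <- simulation_config(seed = s, duration = 75,
                               pt_schedule = pts,
                               gyro_bias = c(0.01, 0.02, -0.01),
                               noise_accel = 0.05 * noise_mult,
                               noise_gyro = 0.01 * noise_mult)
      sim <- simulate_session(cfg)
      det <- pt_detect(sim$recording, keep_series = FALSE)
      ev <- pt_evaluate(det, sim$truth$annotation)
      ev$sensitivity
    })
    mean(vals)
  }
  low <- sens_at(1)
  high <- sens_at(12)
  expect_lte(high, low + 5)  # tolerance for seed noise
})
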
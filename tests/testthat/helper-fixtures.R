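# shared fixture builders; everything is generated in code

# a motionless upright recording: gravity on x, optional noise
still_recording <- function(duration = 10, fs = 128, noise = 0,
                            gyro_bias = c(0, 0, 0), seed = 42L) {
  cfg <- simulation_config(seed = seed, duration = duration,
                           sample_rate = fs, gyro_bias = gyro_bias,
                           noise_accel = noise,
                           noise_gyro = if (noise > 0) noise / 5 else 0)
  simulate_session(cfg)$recording
}

# one clean transition episode bracketed by rest
single_pt_session <- function(direction = "SiSt", tilt_peak = 0.7,
                              rise = 0.25, T = 2, duration = 30,
                              noise_accel = 0, noise_gyro = 0,
                              gyro_bias = c(0, 0, 0), seed = 7L) {
  pts <- data.frame(time = (duration - T) / 2, direction = direction,
                    tilt_peak = tilt_peak, rise_height = rise,
                    episode_duration = T)
  cfg <- simulation_config(seed = seed, duration = duration,
                           sample_rate = 128, pt_schedule = pts,
                           gyro_bias = gyro_bias,
                           noise_accel = noise_accel,
                           noise_gyro = noise_gyro)
  simulate_session(cfg)
}

# literal double-loop evaluation of the trailing-window mean and the
# per-lag-mean variance (the brute-force oracle for short_term_stats)
stats_double_loop <- function(x, N) {
  n <- length(x)
  mu <- numeric(n)
  for (k in seq_len(n)) {
    w <- max(1L, k - N + 1L):k
    mu[k] <- sum(x[w]) / length(w)
  }
  v <- numeric(n)
  for (k in seq_len(n)) {
    w <- max(1L, k - N + 1L):k
    v[k] <- sum((x[w] - mu[w])^2) / length(w)
  }
  list(mean = mu, var = v)
}

# minimal fusion inputs for strapdown oracle checks (no preprocessing,
# no bias tracking): the gyro stream is used exactly as given
strapdown_inputs <- function(accel, gyro, fs) {
  n <- nrow(accel)
  pre <- structure(list(accel = accel, gyro_unbiased = gyro,
                        accel_mag = sqrt(rowSums(accel^2)),
                        sample_rate = fs),
                   class = "preprocessed_streams")
  lab <- c("sp", rep("ap", n - 1L))
  mask <- structure(list(labels = lab,
                         segments = ptkit:::mask_segments(lab),
                         no_anchor = FALSE, sample_rate = fs),
                    class = "activity_mask")
  list(pre = pre, mask = mask)
}

# brute-force topographic prominence of every local maximum of v
prominence_brute <- function(v) {
  n <- length(v)
  out <- data.frame(index = integer(0), prom = numeric(0))
  for (i in 2:(n - 1)) {
    if (v[i] > v[i - 1] && v[i] >= v[i + 1] && v[i] > v[max(1, i - 1)]) {
      if (!(v[i] > v[i - 1] && v[i] > v[i + 1])) next
      left <- if (any(v[1:(i - 1)] > v[i])) {
        j <- max(which(v[1:(i - 1)] > v[i]))
        min(v[j:(i - 1)])
      } else min(v[1:i])
      right <- if (any(v[(i + 1):n] > v[i])) {
        j <- i + min(which(v[(i + 1):n] > v[i]))
        min(v[(i + 1):j])
      } else min(v[i:n])
      out <- rbind(out, data.frame(index = i, prom = v[i] - max(left, right)))
    }
  }
  out
}
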
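# Shared fixtures: small, fast session configurations and hand-built series.

# A light session for pipeline tests: few events, short duration.
tiny_session_config <- function(seed = 1L, ...) {
  args <- list(
    duration_s = 20, n_impacts = 4, n_contacts = 4,
    artifact_rate_per_session = 0, vocalization_rate_per_session = 0,
    sensor_miss_prob = 0, video_miss_prob = 0, video_unclear_prob = 0,
    seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(session_config, args)
}

# A quiet recording (baseline noise only).
quiet_recording <- function(seed = 1L, duration_s = 5) {
  generate_session(session_config(
    duration_s = duration_s, n_impacts = 0, n_contacts = 0,
    artifact_rate_per_session = 0, vocalization_rate_per_session = 0,
    seed = seed
  ))$recording
}

# Noise-free single-sensor style recording built by hand around explicit
# pulse times; all three accelerometers see the same co-located signal
# (r = 0) so CG kinematics equal the injected signal.
manual_recording <- function(time, accel_matrix, gyro_time = NULL,
                             gyro_matrix = NULL, rate_hz = 3200,
                             gyro_rate_hz = 800) {
  if (is.null(gyro_time)) {
    gyro_time <- seq(0, max(time), by = 1 / gyro_rate_hz)
    gyro_matrix <- matrix(0, nrow = length(gyro_time), ncol = 3L)
  }
  structure(
    list(
      accel = lapply(1:3, function(s) {
        list(time = time, data = accel_matrix, rate_hz = rate_hz)
      }),
      gyro = list(time = gyro_time, data = gyro_matrix, rate_hz = gyro_rate_hz),
      duration_s = max(time),
      accel_rate_hz = rate_hz,
      gyro_rate_hz = gyro_rate_hz,
      sensor_positions_m = matrix(0, 3, 3),
      frame_rotation = diag(3)
    ),
    class = "img_recording"
  )
}

# Haversine test pulse on a uniform grid, peak exactly on a sample.
haversine_on_grid <- function(peak, t0, duration_s, rate_hz, t) {
  x <- t - (t0 - duration_s / 2)
  ifelse(x >= 0 & x <= duration_s,
         peak * 0.5 * (1 - cos(2 * pi * x / duration_s)), 0)
}

# Independent brute-force cross product for transform oracles.
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
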
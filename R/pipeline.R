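#' Resample a timestamped series onto a uniform grid
#'
#' The IMG's three accelerometers run at slightly different true rates and
#' the gyroscope at a quarter of the nominal rate, so all streams are
#' linearly interpolated onto one uniform grid before any further
#' processing.
#'
#' @param time strictly increasing sample timestamps (s), length >= 2.
#' @param values numeric vector or matrix (one column per axis).
#' @param target_rate_hz rate (Hz) of the output grid.
#' @param t_out optional explicit output grid; by default a grid at
#'   `target_rate_hz` spanning the input range (endpoints preserved).
#' @return list with `time` (the uniform grid) and `values` (matrix).
#' @export
resample_to_uniform <- function(time, values, target_rate_hz, t_out = NULL) {
  if (length(time) < 2L) data_error("resampling needs at least 2 samples")
  if (any(diff(time) <= 0)) data_error("timestamps must be strictly increasing")
  if (!is_pos(target_rate_hz)) config_error("target_rate_hz must be positive")
  values <- as.matrix(values)
  if (nrow(values) != length(time)) data_error("time and values lengths differ")
  if (is.null(t_out)) {
    t_out <- time[1L] + seq(0, floor((time[length(time)] - time[1L]) * target_rate_hz)) /
      target_rate_hz
  }
  out <- matrix(0, nrow = length(t_out), ncol = ncol(values))
  for (j in seq_len(ncol(values))) {
    out[, j] <- approx(time, values[, j], xout = t_out, method = "linear",
                       rule = 2, ties = "ordered")$y
  }
  list(time = t_out, values = out)
}

#' Low-pass Butterworth filter
#'
#' A digital Butterworth low-pass of the given order. With
#' `zero_phase = TRUE` the filter is applied forward and backward
#' (zero net phase, squared magnitude response) as used for event
#' kinematics; with `zero_phase = FALSE` a single causal pass is applied, as
#' in the device's on-line vocalization/noise screen. The single-pass
#' response is -3 dB at the cutoff.
#'
#' @param values numeric vector or matrix (columns filtered independently).
#' @param rate_hz sampling rate of `values` (Hz).
#' @param cutoff_hz cutoff frequency (Hz), strictly below `rate_hz / 2`.
#' @param order filter order.
#' @param zero_phase logical; forward-backward filtering if `TRUE`.
#' @return filtered values, same shape as the input.
#' @export
lowpass_filter <- function(values, rate_hz, cutoff_hz, order = 4,
                           zero_phase = TRUE) {
  if (!is_pos(rate_hz)) config_error("rate_hz must be positive")
  if (!is_pos(cutoff_hz) || cutoff_hz >= rate_hz / 2) {
    config_error("cutoff (%g Hz) must lie in (0, Nyquist = %g Hz)",
                 cutoff_hz, rate_hz / 2)
  }
  bf <- signal::butter(order, 2 * cutoff_hz / rate_hz, type = "low")
  vec <- is.null(dim(values))
  m <- as.matrix(values)
  out <- m
  for (j in seq_len(ncol(m))) {
    out[, j] <- if (zero_phase) {
      zero_phase_filter(bf$b, bf$a, m[, j])
    } else {
      iir_filter(bf$b, bf$a, m[, j])
    }
  }
  if (vec) drop(out) else out
}

# One causal IIR pass via stats::filter: moving-average part, then the
# autoregressive recursion.
iir_filter <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[-seq_len(nb - 1)]
  if (length(a) > 1L) {
    v <- as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
  }
  v
}

# Forward-backward filtering with constant end-padding to suppress edge
# transients (the padding is trimmed from the result).
zero_phase_filter <- function(b, a, x) {
  n <- length(x)
  np <- min(n - 1L, 12L * max(length(a), length(b)))
  xe <- c(rep(x[1L], np), x, rep(x[n], np))
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  y[np + seq_len(n)]
}

#' Detect trigger crossings
#'
#' The device records an event when the absolute value of any single axis of
#' the trigger accelerometer exceeds the threshold. A trigger is the first
#' sample of each upward crossing (previous sample at or below the
#' threshold, current sample above it); a series starting above the
#' threshold triggers at its first sample. Crossings on different axes are
#' pooled and returned sorted; re-triggers inside an open capture window are
#' handled by [extract_event_windows()].
#'
#' @param time uniform sample times (s).
#' @param values numeric vector or matrix of axis signals (g).
#' @param threshold_g trigger level (g), compared against absolute values.
#' @return sorted numeric vector of trigger times (possibly empty).
#' @export
detect_triggers <- function(time, values, threshold_g) {
  if (!is_pos(threshold_g)) config_error("threshold_g must be positive")
  m <- abs(as.matrix(values))
  if (nrow(m) != length(time)) data_error("time and values lengths differ")
  hits <- logical(nrow(m))
  for (j in seq_len(ncol(m))) {
    above <- m[, j] > threshold_g
    hits <- hits | (above & !c(FALSE, above[-length(above)]))
  }
  time[hits]
}

#' Build capture windows from trigger times
#'
#' Each window opens `pre_window_ms` before its first trigger and closes
#' `post_window_ms` after it; any further trigger inside the open window
#' extends the close to `extension_ms` after that trigger, so multiple
#' acceleration peaks from a single impact are captured as one event.
#' Windows are returned sorted and disjoint (a window opening within the
#' previous one's tail is clipped at the previous close).
#'
#' @param triggers sorted trigger times (s).
#' @param config a [pipeline_config()] supplying the window parameters.
#' @return data.frame with `start_s`, `end_s`, `trigger_time_s` (first
#'   trigger of the window) and `n_triggers`.
#' @export
extract_event_windows <- function(triggers, config = pipeline_config()) {
  config <- validate_pipeline_config(config)
  if (is.unsorted(triggers)) data_error("triggers must be sorted ascending")
  pre <- config$pre_window_ms / 1000
  post <- config$post_window_ms / 1000
  ext <- config$extension_ms / 1000
  n <- length(triggers)
  if (!n) {
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      trigger_time_s = numeric(), n_triggers = integer()))
  }
  starts <- ends <- firsts <- numeric(0)
  counts <- integer(0)
  cur_start <- triggers[1L] - pre
  cur_end <- triggers[1L] + post
  cur_first <- triggers[1L]
  cur_n <- 1L
  for (t in triggers[-1L]) {
    if (t <= cur_end) {
      cur_end <- t + ext
      cur_n <- cur_n + 1L
    } else {
      starts <- c(starts, cur_start); ends <- c(ends, cur_end)
      firsts <- c(firsts, cur_first); counts <- c(counts, cur_n)
      cur_start <- max(t - pre, cur_end)
      cur_end <- t + post
      cur_first <- t
      cur_n <- 1L
    }
  }
  starts <- c(starts, cur_start); ends <- c(ends, cur_end)
  firsts <- c(firsts, cur_first); counts <- c(counts, cur_n)
  data.frame(start_s = starts, end_s = ends, trigger_time_s = firsts,
             n_triggers = counts)
}

#' Differentiate angular velocity
#'
#' Five-point central finite differences (exact for polynomials up to degree
#' four), with matching one-sided five-point stencils at the series ends, so
#' the output has the same length as the input.
#'
#' @param omega numeric vector or n x 3 matrix of angular velocity (rad/s)
#'   on a uniform grid.
#' @param rate_hz sampling rate (Hz).
#' @return angular acceleration (rad/s2), same shape as `omega`.
#' @export
differentiate_angular_velocity <- function(omega, rate_hz) {
  if (!is_pos(rate_hz)) config_error("rate_hz must be positive")
  vec <- is.null(dim(omega))
  m <- as.matrix(omega)
  n <- nrow(m)
  if (n < 5L) data_error("differentiation needs at least 5 samples")
  h <- 1 / rate_hz
  out <- m
  for (j in seq_len(ncol(m))) {
    f <- m[, j]
    d <- numeric(n)
    i <- 3:(n - 2)
    d[i] <- (f[i - 2] - 8 * f[i - 1] + 8 * f[i + 1] - f[i + 2]) / (12 * h)
    d[1] <- (-25 * f[1] + 48 * f[2] - 36 * f[3] + 16 * f[4] - 3 * f[5]) / (12 * h)
    d[2] <- (-3 * f[1] - 10 * f[2] + 18 * f[3] - 6 * f[4] + f[5]) / (12 * h)
    d[n - 1] <- (3 * f[n] + 10 * f[n - 1] - 18 * f[n - 2] + 6 * f[n - 3] - f[n - 4]) / (12 * h)
    d[n] <- (25 * f[n] - 48 * f[n - 1] + 36 * f[n - 2] - 16 * f[n - 3] + 3 * f[n - 4]) / (12 * h)
    out[, j] <- d
  }
  if (vec) drop(out) else out
}

#' Transform sensor acceleration to the head centre of gravity
#'
#' Classical rigid-body kinematics: with `r` the sensor position relative to
#' the head centre of gravity (head frame, metres) and `R` the
#' mouthguard-to-head rotation,
#' `a_cg = R a_sensor - alpha x r - omega x (omega x r)`.
#' Accelerations are converted g -> m/s2 internally and returned in g.
#'
#' @param a_sensor_g n x 3 matrix of sensor-frame linear acceleration (g).
#' @param omega n x 3 matrix of angular velocity (rad/s), time-aligned.
#' @param alpha n x 3 matrix of angular acceleration (rad/s2), time-aligned.
#' @param r length-3 sensor position (m) relative to the head CG.
#' @param rotation 3 x 3 mouthguard-to-head rotation matrix.
#' @return n x 3 matrix of CG linear acceleration (g).
#' @export
transform_to_head_cg <- function(a_sensor_g, omega, alpha, r,
                                 rotation = diag(3)) {
  a_sensor_g <- as.matrix(a_sensor_g)
  omega <- as.matrix(omega)
  alpha <- as.matrix(alpha)
  n <- nrow(a_sensor_g)
  if (nrow(omega) != n || nrow(alpha) != n) {
    data_error("a_sensor, omega and alpha must have matching lengths")
  }
  if (length(r) != 3L) config_error("`r` must be a length-3 position vector")
  a_ms <- (a_sensor_g %*% t(rotation)) * G_MS2
  a_cg <- a_ms - cross_rows(alpha, r) - cross_rows(omega, cross_rows(omega, r))
  a_cg / G_MS2
}

#' Fuse per-sensor centre-of-gravity estimates
#'
#' Sample-wise unweighted mean of the CG-referenced acceleration estimates
#' from the three accelerometers.
#'
#' @param estimates list of time-aligned n x 3 matrices.
#' @return n x 3 matrix.
#' @export
fuse_accelerometers <- function(estimates) {
  if (!length(estimates)) data_error("no estimates to fuse")
  dims <- vapply(estimates, function(m) nrow(as.matrix(m)), integer(1L))
  if (length(unique(dims)) != 1L) data_error("estimate lengths differ")
  Reduce(`+`, lapply(estimates, as.matrix)) / length(estimates)
}

#' Noise / vocalization rejection rule
#'
#' Stand-in for the device's event classifier: an event that triggered on
#' the raw signal is rejected when its 300 Hz low-pass-filtered resultant
#' never reaches the inclusion threshold — the signature of vocalization and
#' other high-frequency noise, whose energy lies above the capture band.
#'
#' @param event list with elements `raw` and `filtered`: n x 3 matrices (g)
#'   of the trigger-sensor window before and after low-pass filtering.
#' @param config a [pipeline_config()].
#' @return `TRUE` to keep the event, `FALSE` to reject it.
#' @export
reject_noise_events <- function(event, config = pipeline_config()) {
  config <- validate_pipeline_config(config)
  max(resultant(as.matrix(event$filtered))) >= config$inclusion_threshold_g
}

#' Process a raw recording into head acceleration events
#'
#' The full capture chain: resample the trigger accelerometer to the uniform
#' grid, detect single-axis 10 g triggers on its raw resampled signal, build
#' capture windows (20 ms pre / 80 ms post, 80 ms re-trigger extension),
#' then within each window resample all sensors, apply the zero-phase
#' 4th-order 300 Hz Butterworth filter, transform each accelerometer to the
#' head centre of gravity using gyroscope-derived angular velocity and
#' acceleration, fuse the three estimates, and extract peak linear (PLA) and
#' peak rotational (PRA) acceleration as maxima of the resultant series over
#' the half-open window `[start, end)`. Events failing the high-frequency
#' noise screen or with PLA below the inclusion threshold are dropped.
#'
#' @param recording an `img_recording`.
#' @param config a [pipeline_config()].
#' @param keep_waveforms logical; attach per-event CG kinematics as the
#'   `"waveforms"` attribute.
#' @return data.frame of head acceleration events, sorted by trigger time:
#'   `event_id`, `trigger_time_s`, `window_start_s`, `window_end_s`,
#'   `pla_g`, `pra_rads2`, `n_triggers`, `saturated`.
#' @export
process_recording <- function(recording, config = pipeline_config(),
                              keep_waveforms = FALSE) {
  if (!inherits(recording, "img_recording")) {
    data_error("`recording` must be an img_recording")
  }
  config <- validate_pipeline_config(config)
  rate <- config$target_rate_hz
  trig_stream <- recording$accel[[config$trigger_sensor]]
  grid_n <- floor(recording$duration_s * rate) + 1L
  t_grid <- (seq_len(grid_n) - 1L) / rate
  trig_vals <- resample_stream(trig_stream, t_grid, rate)
  triggers <- detect_triggers(t_grid, trig_vals, config$trigger_threshold_g)
  windows <- extract_event_windows(triggers, config)
  if (!nrow(windows)) return(empty_hae_table(keep_waveforms))

  windows$start_s <- pmax(windows$start_s, 0)
  windows$end_s <- pmin(windows$end_s, recording$duration_s)
  pad <- 0.05  # filter-transient margin around each window (s)

  keep <- logical(nrow(windows))
  pla <- pra <- numeric(nrow(windows))
  saturated <- logical(nrow(windows))
  waveforms <- if (keep_waveforms) vector("list", nrow(windows))

  for (w in seq_len(nrow(windows))) {
    lo <- max(0, windows$start_s[w] - pad)
    hi <- min(recording$duration_s, windows$end_s[w] + pad)
    i0 <- max(1L, floor(lo * rate) + 1L)
    i1 <- min(grid_n, ceiling(hi * rate) + 1L)
    tsub <- t_grid[i0:i1]
    core <- tsub >= windows$start_s[w] & tsub < windows$end_s[w]
    if (!any(core)) next

    gyro_r <- resample_stream(recording$gyro, tsub, rate)
    omega_f <- lowpass_filter(gyro_r, rate, config$filter_cutoff_hz,
                              config$filter_order, zero_phase = TRUE)
    alpha <- differentiate_angular_velocity(omega_f, rate)

    cg_est <- vector("list", 3L)
    sat <- FALSE
    left_filtered <- NULL
    for (s in 1:3) {
      raw <- resample_stream(recording$accel[[s]], tsub, rate)
      sat <- sat || any(abs(raw) >= config$saturation_g)
      filt <- lowpass_filter(raw, rate, config$filter_cutoff_hz,
                             config$filter_order, zero_phase = TRUE)
      if (s == config$trigger_sensor) left_filtered <- filt
      cg_est[[s]] <- transform_to_head_cg(
        filt, omega_f, alpha, config$sensor_positions_m[s, ],
        config$frame_rotation
      )
    }
    a_cg <- fuse_accelerometers(cg_est)
    pla[w] <- max(resultant(a_cg[core, , drop = FALSE]))
    pra[w] <- max(resultant(alpha[core, , drop = FALSE]))
    saturated[w] <- sat
    keep[w] <- reject_noise_events(
      list(raw = NULL, filtered = left_filtered[core, , drop = FALSE]),
      config
    ) && pla[w] >= config$inclusion_threshold_g
    if (keep_waveforms && keep[w]) {
      waveforms[[w]] <- list(
        time = tsub[core],
        cg_linear_accel = a_cg[core, , drop = FALSE],
        angular_velocity = omega_f[core, , drop = FALSE],
        angular_accel = alpha[core, , drop = FALSE]
      )
    }
  }
  out <- data.frame(
    event_id = seq_len(sum(keep)),
    trigger_time_s = windows$trigger_time_s[keep],
    window_start_s = windows$start_s[keep],
    window_end_s = windows$end_s[keep],
    pla_g = pla[keep],
    pra_rads2 = pra[keep],
    n_triggers = windows$n_triggers[keep],
    saturated = saturated[keep]
  )
  if (keep_waveforms) attr(out, "waveforms") <- waveforms[keep]
  out
}

empty_hae_table <- function(keep_waveforms = FALSE) {
  out <- data.frame(
    event_id = integer(), trigger_time_s = numeric(),
    window_start_s = numeric(), window_end_s = numeric(),
    pla_g = numeric(), pra_rads2 = numeric(),
    n_triggers = integer(), saturated = logical()
  )
  if (keep_waveforms) attr(out, "waveforms") <- list()
  out
}

# Resample one raw sensor stream onto an explicit sub-grid, touching only the
# raw samples that cover it. Inlined linear interpolation (same result as
# resample_to_uniform with rule-2 edges) keeps the per-window cost low.
resample_stream <- function(stream, t_out, rate) {
  n <- length(stream$time)
  j0 <- max(1L, floor(t_out[1L] * stream$rate_hz) - 1L)
  j1 <- min(n, ceiling(t_out[length(t_out)] * stream$rate_hz) + 2L)
  tt <- stream$time[j0:j1]
  yy <- stream$data[j0:j1, , drop = FALSE]
  k <- findInterval(t_out, tt, all.inside = TRUE)
  w <- (t_out - tt[k]) / (tt[k + 1L] - tt[k])
  w <- pmin(pmax(w, 0), 1)  # constant extension beyond the stream's ends
  yy[k, , drop = FALSE] * (1 - w) + yy[k + 1L, , drop = FALSE] * w
}
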
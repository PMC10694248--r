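#' Session configuration for the synthetic IMG data generator
#'
#' Defines one simulated athlete exposure: a continuous multi-sensor IMG
#' recording plus the contact events that occur during it. Defaults emulate
#' the per-exposure event mix and magnitude laws observed in an elite rugby
#' union season (roughly 33 contact events per athlete exposure, of which
#' ~11.5 involve a direct head impact; verified-impact PLA median 21.5 g, IQR
#' 15.4-33.9 g; PRA median 1,702 rad/s2, IQR 1,170-2,772 rad/s2; handling
#' false-positive magnitudes with PLA median 62.6 g, IQR 24.6-106.7 g), at a
#' session length short enough to simulate cheaply.
#'
#' @param duration_s session duration in seconds. The default (60 s) is a
#'   condensed session: per-exposure event counts are kept at season-realistic
#'   values while the quiet time between events is compressed.
#' @param n_impacts number of direct head impacts in the session.
#' @param n_contacts number of contact events without direct head involvement.
#' @param pla_median_g,pla_iqr_g median and quartiles (g) of the direct-impact
#'   peak linear acceleration law.
#' @param pra_median_rads2,pra_iqr_rads2 median and quartiles (rad/s2) of the
#'   direct-impact peak rotational acceleration law.
#' @param pulse_duration_range_ms range (ms) from which impact pulse durations
#'   are drawn uniformly; must lie within [2, 50] ms.
#' @param artifact_rate_per_session expected number of mouthguard
#'   handling/removal artifacts per session (Poisson).
#' @param vocalization_rate_per_session expected number of vocalization /
#'   high-frequency noise bursts per session (Poisson).
#' @param artifact_pla_median_g,artifact_pla_iqr_g handling-artifact magnitude
#'   law (g).
#' @param artifact_pra_median_rads2,artifact_pra_iqr_rads2 handling-artifact
#'   rotational magnitude law (rad/s2).
#' @param sensor_miss_prob probability that a true direct head impact is not
#'   represented by a capturable waveform (decoupling, sub-threshold
#'   loading). The default is calibrated with [tuned_miss_prob()] so that
#'   the end-to-end detection sensitivity equals the season's observed value
#'   655/700 = 0.936 (the capture chain itself loses a further ~1% of
#'   near-threshold impacts).
#' @param capture_threshold_g device capture threshold (g) used to couple
#'   impact magnitudes to the miss indicator: missed impacts draw magnitudes
#'   below it, captured ones at or above it.
#' @param video_miss_prob probability that a true direct head impact is coded
#'   on video as contact-only (reviewer false negative).
#' @param video_unclear_prob probability that a contact event is coded
#'   "unclear" (player obstructed, e.g. in a maul or ruck). Default 257/2018.
#' @param bop_fraction_of_artifacts fraction of handling artifacts occurring
#'   while the ball is out of play. Default 43/54.
#' @param video_jitter_s half-width (s) of the uniform timestamp error between
#'   the video log and the sensor clock.
#' @param noise_rms_g baseline accelerometer noise RMS per axis (g).
#' @param gyro_noise_rms_rads baseline gyroscope noise RMS per axis (rad/s).
#' @param accel_rate_hz,gyro_rate_hz nominal sensor sampling rates (Hz).
#' @param rate_jitter maximal relative per-sensor sampling-rate offset;
#'   each sensor's true rate is drawn uniformly within +/- this fraction.
#' @param seed integer seed; identical configuration and seed give
#'   byte-identical sessions.
#' @return an object of class `img_session_config` (a validated list).
#' @seealso [generate_session()]
#' @export
session_config <- function(duration_s = 60,
                           n_impacts = 11,
                           n_contacts = 22,
                           pla_median_g = 21.5,
                           pla_iqr_g = c(15.4, 33.9),
                           pra_median_rads2 = 1702,
                           pra_iqr_rads2 = c(1170, 2772),
                           pulse_duration_range_ms = c(8, 16),
                           artifact_rate_per_session = 54 / 61,
                           vocalization_rate_per_session = 2,
                           artifact_pla_median_g = 62.6,
                           artifact_pla_iqr_g = c(24.6, 106.7),
                           artifact_pra_median_rads2 = 6168,
                           artifact_pra_iqr_rads2 = c(2174, 10690),
                           sensor_miss_prob = tuned_miss_prob(655 / 700),
                           capture_threshold_g = 10,
                           video_miss_prob = 0.005,
                           video_unclear_prob = 257 / 2018,
                           bop_fraction_of_artifacts = 43 / 54,
                           video_jitter_s = 0.5,
                           noise_rms_g = 0.3,
                           gyro_noise_rms_rads = 0.05,
                           accel_rate_hz = 3200,
                           gyro_rate_hz = 800,
                           rate_jitter = 0.01,
                           seed = 1L) {
  cfg <- list(
    duration_s = duration_s, n_impacts = n_impacts, n_contacts = n_contacts,
    pla_median_g = pla_median_g, pla_iqr_g = pla_iqr_g,
    pra_median_rads2 = pra_median_rads2, pra_iqr_rads2 = pra_iqr_rads2,
    pulse_duration_range_ms = pulse_duration_range_ms,
    artifact_rate_per_session = artifact_rate_per_session,
    vocalization_rate_per_session = vocalization_rate_per_session,
    artifact_pla_median_g = artifact_pla_median_g,
    artifact_pla_iqr_g = artifact_pla_iqr_g,
    artifact_pra_median_rads2 = artifact_pra_median_rads2,
    artifact_pra_iqr_rads2 = artifact_pra_iqr_rads2,
    sensor_miss_prob = sensor_miss_prob,
    capture_threshold_g = capture_threshold_g,
    video_miss_prob = video_miss_prob,
    video_unclear_prob = video_unclear_prob,
    bop_fraction_of_artifacts = bop_fraction_of_artifacts,
    video_jitter_s = video_jitter_s,
    noise_rms_g = noise_rms_g, gyro_noise_rms_rads = gyro_noise_rms_rads,
    accel_rate_hz = accel_rate_hz, gyro_rate_hz = gyro_rate_hz,
    rate_jitter = rate_jitter, seed = seed
  )
  validate_session_config(cfg)
}

validate_session_config <- function(cfg) {
  if (!is_pos(cfg$duration_s)) config_error("duration_s must be positive")
  if (!is_count(cfg$n_impacts)) config_error("n_impacts must be a non-negative count")
  if (!is_count(cfg$n_contacts)) config_error("n_contacts must be a non-negative count")
  magnitude_params(cfg$pla_median_g, cfg$pla_iqr_g)
  magnitude_params(cfg$pra_median_rads2, cfg$pra_iqr_rads2)
  magnitude_params(cfg$artifact_pla_median_g, cfg$artifact_pla_iqr_g)
  magnitude_params(cfg$artifact_pra_median_rads2, cfg$artifact_pra_iqr_rads2)
  pd <- cfg$pulse_duration_range_ms
  if (!is.numeric(pd) || length(pd) != 2L || pd[1L] > pd[2L] ||
      pd[1L] < 2 || pd[2L] > 50) {
    config_error("pulse_duration_range_ms must be an increasing pair within [2, 50] ms")
  }
  for (f in c("artifact_rate_per_session", "vocalization_rate_per_session")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || !is.finite(cfg[[f]]) ||
        cfg[[f]] < 0) {
      config_error("%s must be a non-negative rate", f)
    }
  }
  for (f in c("sensor_miss_prob", "video_miss_prob", "video_unclear_prob",
              "bop_fraction_of_artifacts")) {
    if (!is_prob(cfg[[f]])) config_error("%s must be a probability in [0, 1]", f)
  }
  if (!is_pos(cfg$capture_threshold_g)) config_error("capture_threshold_g must be positive")
  if (!is.numeric(cfg$video_jitter_s) || cfg$video_jitter_s < 0) {
    config_error("video_jitter_s must be non-negative")
  }
  if (!is.numeric(cfg$noise_rms_g) || cfg$noise_rms_g < 0) {
    config_error("noise_rms_g must be non-negative")
  }
  if (!is_pos(cfg$accel_rate_hz) || !is_pos(cfg$gyro_rate_hz)) {
    config_error("sensor rates must be positive")
  }
  if (!is.numeric(cfg$rate_jitter) || cfg$rate_jitter < 0 || cfg$rate_jitter >= 0.5) {
    config_error("rate_jitter must be in [0, 0.5)")
  }
  if (!is.null(cfg$seed) && !is_count(abs(cfg$seed))) {
    config_error("seed must be an integer")
  }
  structure(cfg, class = "img_session_config")
}

#' Signal-pipeline configuration
#'
#' Parameters of the IMG capture and kinematics chain: the 10 g single-axis
#' trigger, the 20 ms pre / 80 ms post capture window with 80 ms re-trigger
#' extension, resampling of every sensor stream to a common 3,200 Hz grid, the
#' 4th-order 300 Hz low-pass Butterworth filter (zero-phase for kinematics, a
#' causal pass for the noise-rejection check), the rigid-body transform of
#' each accelerometer to the head centre of gravity, and the 10 g inclusion
#' threshold on centre-of-gravity peak linear acceleration.
#'
#' @param trigger_threshold_g single-axis absolute-value trigger level (g).
#' @param pre_window_ms,post_window_ms capture window extent around the first
#'   trigger (ms).
#' @param extension_ms extension added after each re-trigger inside an open
#'   window (ms).
#' @param target_rate_hz uniform grid rate all streams are resampled to (Hz).
#' @param filter_cutoff_hz low-pass Butterworth cutoff (Hz); must be below the
#'   Nyquist rate of `target_rate_hz`.
#' @param filter_order Butterworth order (even, >= 2).
#' @param inclusion_threshold_g minimal centre-of-gravity PLA (g) for a
#'   captured event to be retained.
#' @param sensor_positions_m 3 x 3 numeric matrix; row i is the position (m)
#'   of accelerometer i relative to the head centre of gravity, in the head
#'   anatomical frame (x anterior, y left, z superior). The default places
#'   the three sensors on a 60 mm dental arch roughly 80 mm anterior-inferior
#'   of the centre of gravity.
#' @param frame_rotation 3 x 3 rotation taking the mouthguard sensor frame to
#'   the head anatomical frame.
#' @param trigger_sensor index (1-3) of the accelerometer whose raw resampled
#'   per-axis signal drives trigger detection; sensor 1 is the left sensor,
#'   which is also the stream used by the noise-rejection rule.
#' @param saturation_g sensor full-scale magnitude (g); samples at or beyond
#'   it are flagged as saturated.
#' @return an object of class `img_pipeline_config`.
#' @seealso [process_recording()]
#' @export
pipeline_config <- function(trigger_threshold_g = 10,
                            pre_window_ms = 20,
                            post_window_ms = 80,
                            extension_ms = 80,
                            target_rate_hz = 3200,
                            filter_cutoff_hz = 300,
                            filter_order = 4,
                            inclusion_threshold_g = 10,
                            sensor_positions_m = default_sensor_positions(),
                            frame_rotation = diag(3),
                            trigger_sensor = 1L,
                            saturation_g = 200) {
  cfg <- list(
    trigger_threshold_g = trigger_threshold_g,
    pre_window_ms = pre_window_ms, post_window_ms = post_window_ms,
    extension_ms = extension_ms, target_rate_hz = target_rate_hz,
    filter_cutoff_hz = filter_cutoff_hz, filter_order = filter_order,
    inclusion_threshold_g = inclusion_threshold_g,
    sensor_positions_m = sensor_positions_m,
    frame_rotation = frame_rotation,
    trigger_sensor = as.integer(trigger_sensor),
    saturation_g = saturation_g
  )
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  for (f in c("trigger_threshold_g", "pre_window_ms", "post_window_ms",
              "extension_ms", "target_rate_hz", "filter_cutoff_hz",
              "inclusion_threshold_g", "saturation_g")) {
    if (!is_pos(cfg[[f]])) config_error("%s must be positive", f)
  }
  if (cfg$filter_cutoff_hz >= cfg$target_rate_hz / 2) {
    config_error(
      "filter cutoff (%g Hz) must be below the Nyquist rate (%g Hz)",
      cfg$filter_cutoff_hz, cfg$target_rate_hz / 2
    )
  }
  if (!is_count(cfg$filter_order) || cfg$filter_order < 2 ||
      cfg$filter_order %% 2 != 0) {
    config_error("filter_order must be an even integer >= 2")
  }
  p <- cfg$sensor_positions_m
  if (!is.matrix(p) || !identical(dim(p), c(3L, 3L)) || !all(is.finite(p))) {
    config_error("sensor_positions_m must be a finite 3 x 3 matrix")
  }
  r <- cfg$frame_rotation
  if (!is.matrix(r) || !identical(dim(r), c(3L, 3L)) ||
      max(abs(crossprod(r) - diag(3))) > 1e-8) {
    config_error("frame_rotation must be an orthonormal 3 x 3 matrix")
  }
  if (!cfg$trigger_sensor %in% 1:3) config_error("trigger_sensor must be 1, 2 or 3")
  structure(cfg, class = "img_pipeline_config")
}

#' @rdname pipeline_config
#' @export
default_sensor_positions <- function() {
  # left / centre / right sensor positions on the dental arch (head frame, m)
  matrix(
    c(
      0.055,  0.030, -0.055,
      0.075,  0.000, -0.050,
      0.055, -0.030, -0.055
    ),
    nrow = 3L, byrow = TRUE,
    dimnames = list(c("left", "centre", "right"), c("x", "y", "z"))
  )
}

#' Full run configuration
#'
#' Bundles the session generator, the signal pipeline, the video-matching
#' tolerance and the reporting settings for a multi-session (multi-exposure)
#' end-to-end run. The seed deterministically derives one sub-seed per
#' session, so a run is fully reproducible from its configuration alone.
#'
#' @param session an [session_config()] object (per-exposure settings).
#' @param pipeline a [pipeline_config()] object.
#' @param n_sessions number of athlete exposures to simulate.
#' @param match_tolerance_s maximal |time difference| (s) for pairing a video
#'   event with a head acceleration event.
#' @param boot_resamples bootstrap resamples for medians' confidence intervals.
#' @param conf_level confidence level of those intervals.
#' @param prop_forward probability that an exposure belongs to a forward
#'   (vs. back) positional group; default 536/655 reflecting the share of
#'   verified impacts sustained by forwards.
#' @param seed integer master seed.
#' @return an object of class `img_run_config`.
#' @seealso [run_end_to_end()]
#' @export
run_config <- function(session = session_config(),
                       pipeline = pipeline_config(),
                       n_sessions = 61,
                       match_tolerance_s = 2,
                       boot_resamples = 2000,
                       conf_level = 0.95,
                       prop_forward = 536 / 655,
                       seed = 1L) {
  if (!inherits(session, "img_session_config")) {
    session <- validate_session_config(session)
  }
  if (!inherits(pipeline, "img_pipeline_config")) {
    pipeline <- validate_pipeline_config(pipeline)
  }
  if (!is_count(n_sessions) || n_sessions < 1) {
    config_error("n_sessions must be a positive count")
  }
  if (!is.numeric(match_tolerance_s) || match_tolerance_s < 0) {
    config_error("match_tolerance_s must be non-negative")
  }
  if (!is_count(boot_resamples) || boot_resamples < 1) {
    config_error("boot_resamples must be a positive count")
  }
  if (!is_prob(conf_level) || conf_level <= 0 || conf_level >= 1) {
    config_error("conf_level must be in (0, 1)")
  }
  if (!is_prob(prop_forward)) config_error("prop_forward must be in [0, 1]")
  structure(
    list(
      session = session, pipeline = pipeline, n_sessions = n_sessions,
      match_tolerance_s = match_tolerance_s, boot_resamples = boot_resamples,
      conf_level = conf_level, prop_forward = prop_forward, seed = seed
    ),
    class = "img_run_config"
  )
}
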
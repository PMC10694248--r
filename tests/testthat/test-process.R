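test_that("a quiet recording yields no events", {
  rec <- quiet_recording(seed = 3)
  expect_equal(nrow(process_recording(rec)), 0)
})

test_that("well-separated impacts are all recovered with accurate PLA", {
  # generator ground truth as oracle: 20 capturable impacts (PLA roughly
  # 15-40 g, comfortably above threshold) over 5 sessions
  total <- 0
  errs <- c()
  for (seed in 1:5) {
    cfg <- tiny_session_config(seed = seed, pla_median_g = 24,
                               pla_iqr_g = c(19, 30))
    ses <- generate_session(cfg)
    hae <- process_recording(ses$recording)
    imp <- ses$truth[ses$truth$kind == "direct_head_impact", ]
    for (i in seq_len(nrow(imp))) {
      j <- which.min(abs(hae$trigger_time_s - imp$time_s[i]))
      expect_lt(abs(hae$trigger_time_s[j] - imp$time_s[i]), 0.05)
      errs <- c(errs, abs(hae$pla_g[j] - imp$true_pla_g[i]) / imp$true_pla_g[i])
    }
    total <- total + nrow(imp)
    # headless contacts (1-6 g) must not produce events
    expect_equal(nrow(hae), nrow(imp))
  }
  expect_equal(total, 20)
  expect_lt(max(errs), 0.05)
})

test_that("stored PLA/PRA equal maxima of the stored resultant series", {
  cfg <- tiny_session_config(seed = 6)
  ses <- generate_session(cfg)
  hae <- process_recording(ses$recording, keep_waveforms = TRUE)
  wf <- attr(hae, "waveforms")
  expect_equal(length(wf), nrow(hae))
  for (k in seq_len(nrow(hae))) {
    expect_equal(max(sqrt(rowSums(wf[[k]]$cg_linear_accel^2))), hae$pla_g[k])
    expect_equal(max(sqrt(rowSums(wf[[k]]$angular_accel^2))), hae$pra_rads2[k])
    expect_true(all(wf[[k]]$time >= hae$window_start_s[k]))
    expect_true(all(wf[[k]]$time < hae$window_end_s[k]))
  }
})

test_that("two impacts 50 ms apart merge into one captured event", {
  rate <- 3200
  t <- seq(0, 3, by = 1 / rate)
  sig <- haversine_on_grid(25, 1.0, 0.010, rate, t) +
    haversine_on_grid(18, 1.05, 0.010, rate, t)
  rec <- manual_recording(t, cbind(sig, 0 * t, 0 * t))
  hae <- process_recording(rec)
  expect_equal(nrow(hae), 1)
  expect_gte(hae$n_triggers, 2)
  expect_gt(hae$window_end_s, 1.05)
  expect_equal(hae$pla_g, 25, tolerance = 0.01)
})

test_that("high-frequency bursts trigger but are rejected by the noise rule", {
  rate <- 3200
  t <- seq(0, 2, by = 1 / rate)
  env <- haversine_on_grid(15, 1.0, 0.020, rate, t)
  burst <- env * cos(2 * pi * 600 * (t - 1.0))
  rec <- manual_recording(t, cbind(burst, 0 * t, 0 * t))
  # raw stream triggers...
  expect_gt(length(detect_triggers(t, rec$accel[[1]]$data, 10)), 0)
  # ...but no event survives the 300 Hz screen
  expect_equal(nrow(process_recording(rec)), 0)
})

test_that("saturated samples are flagged", {
  rate <- 3200
  t <- seq(0, 2, by = 1 / rate)
  sig <- haversine_on_grid(250, 1.0, 0.010, rate, t)
  rec <- manual_recording(t, cbind(pmin(sig, 200), 0 * t, 0 * t))
  hae <- process_recording(rec)
  expect_equal(nrow(hae), 1)
  expect_true(hae$saturated)
})

test_that("reject_noise_events keeps band-limited pulses and drops pure HF content", {
  rate <- 3200
  t <- seq(0, 0.12, by = 1 / rate)
  cfg <- pipeline_config()
  pulse <- cbind(haversine_on_grid(20, 0.06, 0.010, rate, t), 0 * t, 0 * t)
  keep <- reject_noise_events(
    list(raw = pulse, filtered = lowpass_filter(pulse, rate, 300, 4)), cfg
  )
  expect_true(keep)
  hf <- cbind(haversine_on_grid(15, 0.06, 0.020, rate, t) *
                cos(2 * pi * 600 * (t - 0.06)), 0 * t, 0 * t)
  drop_hf <- reject_noise_events(
    list(raw = hf, filtered = lowpass_filter(hf, rate, 300, 4)), cfg
  )
  expect_false(drop_hf)
})
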
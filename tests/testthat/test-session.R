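test_that("empty session is pure baseline noise with empty logs", {
  cfg <- session_config(duration_s = 5, n_impacts = 0, n_contacts = 0,
                        artifact_rate_per_session = 0,
                        vocalization_rate_per_session = 0, seed = 2)
  ses <- generate_session(cfg)
  expect_equal(nrow(ses$truth), 0)
  expect_equal(nrow(ses$video), 0)
  # all samples well below trigger level: noise only
  for (s in 1:3) {
    expect_lt(max(abs(ses$recording$accel[[s]]$data)), 5)
  }
})

test_that("sessions are byte-identical under a fixed seed", {
  cfg <- tiny_session_config(seed = 99, artifact_rate_per_session = 1,
                             vocalization_rate_per_session = 1)
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a, b)
  expect_equal(sum(a$truth$kind == "direct_head_impact"), 4)
})

test_that("ground-truth magnitudes match the configured law", {
  # truth-level check at n = 10^4 impacts (no waveforms needed)
  cfg <- session_config(duration_s = 36000, n_impacts = 10000, n_contacts = 0,
                        artifact_rate_per_session = 0,
                        vocalization_rate_per_session = 0, seed = 31)
  truth <- imgval:::with_seed(31, simulate_session_truth(cfg))
  imp <- truth[truth$kind == "direct_head_impact", ]
  expect_equal(nrow(imp), 10000)
  expect_lt(abs(median(imp$true_pla_g) - 21.5) / 21.5, 0.02)
  expect_lt(abs(median(imp$true_pra_rads2) - 1702) / 1702, 0.02)
  expect_true(all(imp$true_pla_g > 0))
  expect_true(all(truth$time_s > 0 & truth$time_s < cfg$duration_s))
})

test_that("video observation is faithful when error-free and masks everything at unclear_prob one", {
  cfg <- tiny_session_config(seed = 7)
  truth <- imgval:::with_seed(7, simulate_session_truth(cfg))
  v0 <- imgval:::with_seed(1, simulate_video_observation(truth, 0, 0))
  expect_equal(nrow(v0), sum(truth$kind %in% c("direct_head_impact", "contact_no_head")))
  tr <- truth[match(v0$truth_id, truth$event_id), ]
  expect_equal(v0$is_direct_head_impact, tr$kind == "direct_head_impact")
  expect_equal(v0$time_s, tr$time_s)
  expect_false(any(v0$is_unclear))

  v1 <- imgval:::with_seed(1, simulate_video_observation(truth, 0, 1))
  expect_true(all(v1$is_unclear))
  expect_true(all(is.na(v1$is_direct_head_impact)))
})

test_that("video log conserves and references ground truth", {
  cfg <- tiny_session_config(seed = 13, artifact_rate_per_session = 2)
  ses <- generate_session(cfg)
  expect_lte(nrow(ses$video), nrow(ses$truth))
  expect_true(all(ses$video$truth_id %in% ses$truth$event_id))
  expect_false(any(duplicated(ses$video$truth_id)))
  # artifacts are invisible on video
  art_ids <- ses$truth$event_id[ses$truth$kind %in% c("handling_artifact", "vocalization")]
  expect_false(any(ses$video$truth_id %in% art_ids))
})

test_that("unclear coding rate reproduces the season's unclear count", {
  # 2,018 contacts at the season's unclear probability: the realized count
  # must fall in the binomial 95% interval around 257
  n <- 2018
  p <- 257 / 2018
  truth <- data.frame(
    event_id = seq_len(n), time_s = seq_len(n),
    kind = rep(c("direct_head_impact", "contact_no_head"), length.out = n),
    true_pla_g = 20, true_pra_rads2 = 1500, duration_ms = 10,
    scenario = "ruck", ball_in_play = TRUE, detected = TRUE,
    stringsAsFactors = FALSE
  )
  v <- imgval:::with_seed(17, simulate_video_observation(truth, 0, p))
  ci <- qbinom(c(0.025, 0.975), n, p)
  expect_gte(sum(v$is_unclear), ci[1])
  expect_lte(sum(v$is_unclear), ci[2])
})

test_that("handling artifacts add supra-threshold intervals, vocalizations are filter-rejected", {
  rec <- quiet_recording(seed = 21)
  art <- data.frame(
    event_id = 1L, time_s = 2.5, kind = "handling_artifact",
    true_pla_g = 60, true_pra_rads2 = 6000, duration_ms = 6,
    scenario = "other", ball_in_play = FALSE, detected = NA,
    stringsAsFactors = FALSE
  )
  set.seed(1)
  rec2 <- inject_artifacts(rec, art)
  res <- sqrt(rowSums(rec2$accel[[1]]$data^2))
  expect_gt(max(res), 10)
  touched <- which(abs(res - sqrt(rowSums(rec$accel[[1]]$data^2))) > 1e-9)
  expect_lt(diff(range(rec2$accel[[1]]$time[touched])), 0.02)

  voc <- art
  voc$kind <- "vocalization"
  voc$true_pla_g <- 18
  voc$true_pra_rads2 <- 10
  voc$duration_ms <- 20
  set.seed(2)
  rec3 <- inject_artifacts(rec, voc)
  raw <- rec3$accel[[1]]$data
  rate <- rec3$accel[[1]]$rate_hz
  expect_gt(max(abs(raw)), 10)  # triggers on the raw stream
  filt <- lowpass_filter(raw, rate, 300, 4, zero_phase = TRUE)
  expect_lt(max(sqrt(rowSums(filt^2))), 10)  # but not after the 300 Hz filter
})

test_that("injecting an empty artifact list leaves the recording unchanged", {
  rec <- quiet_recording(seed = 5)
  rec2 <- inject_artifacts(rec, imgval:::empty_truth())
  expect_identical(rec, rec2)
  expect_error(
    inject_artifacts(rec, data.frame(kind = "direct_head_impact")),
    "handling_artifact or vocalization"
  )
})
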
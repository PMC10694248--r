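paper_counts <- c(TP = 655, FP = 54, FN = 45, TN = 1061, UNCLEAR = 257)

test_that("the report reproduces all five printed accuracy percentages", {
  rep <- build_report(paper_counts, vhis = data.frame(pla_g = numeric(),
                                                      pra_rads2 = numeric()),
                      n_exposures = 61, n_bop_fps = 43, boot_resamples = 10)
  s <- rep$scenarios
  vv <- s[s$scenario == "visually_verified", ]
  expect_equal(round(100 * vv$sensitivity, 1), 93.6)
  expect_equal(round(100 * vv$ppv, 1), 92.4)
  best <- s[s$scenario == "best_case", ]
  expect_equal(round(100 * best$sensitivity, 1), 95.3)
  expect_equal(round(100 * best$ppv, 1), 94.4)
  worst <- s[s$scenario == "worst_case", ]
  expect_equal(round(100 * worst$sensitivity, 1), 93.6)
  expect_equal(round(100 * worst$ppv, 1), 67.8)
  expect_equal(round(100 * rep$ppv_bop_excluded, 1), 98.3)
  expect_equal(rep$rates$vhi_per_exposure, 10.7)
})

test_that("an empty season yields a degenerate but valid report", {
  rep <- build_report(
    c(TP = 0, FP = 0, FN = 0, TN = 0, UNCLEAR = 0),
    vhis = data.frame(pla_g = numeric(), pra_rads2 = numeric()),
    n_exposures = 5, boot_resamples = 10
  )
  expect_equal(rep$rates$vhi_per_exposure, 0)
  expect_true(is.na(rep$scenarios$sensitivity[1]))
  expect_equal(rep$magnitude_tables$overall$n, 0)
})

test_that("report JSON serialization round-trips and is byte-stable", {
  set.seed(2)
  vhis <- data.frame(
    pla_g = sample_magnitude(80, 21.5, c(15.4, 33.9)),
    pra_rads2 = sample_magnitude(80, 1702, c(1170, 2772)),
    half = sample(c("first", "second"), 80, replace = TRUE),
    scenario = sample(c("ruck", "maul"), 80, replace = TRUE)
  )
  rep <- build_report(paper_counts, vhis, 61, 43, boot_resamples = 50)
  p1 <- file.path(tempdir(), "r1.json")
  p2 <- file.path(tempdir(), "r2.json")
  write_report(rep, p1, "json")
  write_report(rep, p2, "json")
  expect_identical(readLines(p1), readLines(p2))

  back <- read_report(p1)
  expect_equal(back$scenarios, rep$scenarios)
  expect_equal(back$ppv_bop_excluded, rep$ppv_bop_excluded)
  expect_equal(back$magnitude_tables$half, rep$magnitude_tables$half)
  expect_equal(unlist(back$counts), unlist(rep$counts))

  md <- file.path(tempdir(), "r.md")
  write_report(rep, md, "markdown")
  lines <- readLines(md)
  expect_true(any(grepl("93.6", lines, fixed = TRUE)))
  expect_true(any(grepl("Magnitudes by half", lines)))
  expect_error(write_report(rep, p1, "xml"))
})

test_that("event logs round-trip through CSV with schema validation", {
  ses <- generate_session(tiny_session_config(seed = 44))
  tpath <- file.path(tempdir(), "truth.csv")
  vpath <- file.path(tempdir(), "video.csv")
  write_event_log(ses$truth, tpath)
  write_event_log(ses$video, vpath)

  truth <- read_event_log(tpath, "truth")
  expect_equal(truth$time_s, ses$truth$time_s)
  expect_equal(truth$kind, ses$truth$kind)
  video <- read_event_log(vpath, "video")
  expect_equal(video$is_direct_head_impact, ses$video$is_direct_head_impact)

  # empty log with header
  write_event_log(ses$truth[0, ], tpath)
  expect_equal(nrow(read_event_log(tpath, "truth")), 0)

  # schema violations name the row
  bad <- ses$truth
  bad$scenario[2] <- "lineout-typo"
  write_event_log(bad, tpath)
  expect_error(read_event_log(tpath, "truth"), "row 2")

  bad2 <- ses$truth
  bad2$time_s <- as.character(bad2$time_s)
  bad2$time_s[3] <- "noon"
  write_event_log(bad2, tpath)
  expect_error(read_event_log(tpath, "truth"), "non-numeric")

  expect_error(read_event_log(file.path(tempdir(), "missing.csv"), "truth"),
               "no such file")
})

test_that("recordings round-trip through the CSV directory layout", {
  rec <- quiet_recording(seed = 9, duration_s = 0.5)
  dir <- file.path(tempdir(), "rec_rt")
  write_recording(rec, dir)
  back <- read_recording(dir)
  expect_equal(back$accel[[2]]$data, rec$accel[[2]]$data, tolerance = 1e-12)
  expect_equal(back$gyro$time, rec$gyro$time, tolerance = 1e-12)
  expect_equal(back$duration_s, rec$duration_s)
  expect_equal(back$sensor_positions_m, unname(rec$sensor_positions_m))
})
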
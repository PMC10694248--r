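vlog <- function(times, impact = TRUE, unclear = FALSE) {
  n <- length(times)
  data.frame(
    event_id = seq_len(n), truth_id = seq_len(n), time_s = times,
    is_contact = rep(TRUE, n),
    is_direct_head_impact = ifelse(rep(unclear, n), NA, rep(impact, n)),
    is_unclear = rep(unclear, n), ball_in_play = rep(TRUE, n),
    scenario = rep("ruck", n),
    stringsAsFactors = FALSE
  )
}

hlog <- function(times) {
  data.frame(event_id = seq_along(times), trigger_time_s = times)
}

test_that("clock synchronization shifts and composes", {
  v <- vlog(c(1, 5, 9))
  expect_equal(synchronize_clocks(v, 0), v)
  expect_equal(synchronize_clocks(v, 3.2)$time_s, c(4.2, 8.2, 12.2))
  expect_equal(
    synchronize_clocks(synchronize_clocks(v, 1.5), -2.5),
    synchronize_clocks(v, -1)
  )
})

test_that("matching pairs within tolerance and leaves distant events unmatched", {
  m <- match_events(vlog(10.0), hlog(10.3), 1.0)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$dt_s, 0.3)

  m2 <- match_events(vlog(10.0), hlog(12.0), 1.0)
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(m2$unmatched_video, 1)
  expect_equal(m2$unmatched_hae, 1)

  expect_error(match_events(vlog(1), hlog(1), -1), "non-negative")
})

test_that("greedy matching takes the globally closest pairs", {
  # one HAE between two video events pairs with the nearer one
  m <- match_events(vlog(c(10.0, 10.8)), hlog(10.6), 2)
  expect_equal(m$pairs$video_id, 2)
  expect_equal(m$unmatched_video, 1)
})

test_that("matching agrees with brute-force enumeration on small instances", {
  # oracle: enumerate all one-to-one assignments, apply the same greedy
  # closest-first rule by exhaustive search over pair orderings
  greedy_oracle <- function(vt, ht, tol) {
    pairs <- expand.grid(v = seq_along(vt), h = seq_along(ht))
    pairs$dt <- abs(ht[pairs$h] - vt[pairs$v])
    pairs <- pairs[pairs$dt <= tol, ]
    pairs <- pairs[order(pairs$dt, vt[pairs$v]), ]
    used_v <- used_h <- integer(0)
    out <- NULL
    while (nrow(pairs)) {
      p <- pairs[1, ]
      out <- rbind(out, p)
      used_v <- c(used_v, p$v); used_h <- c(used_h, p$h)
      pairs <- pairs[!(pairs$v %in% used_v) & !(pairs$h %in% used_h), ]
    }
    out
  }
  set.seed(99)
  for (rep in 1:20) {
    vt <- sort(runif(sample(1:5, 1), 0, 20))
    ht <- sort(runif(sample(1:5, 1), 0, 20))
    m <- match_events(vlog(vt), hlog(ht), 2)
    oracle <- greedy_oracle(vt, ht, 2)
    if (is.null(oracle)) {
      expect_equal(nrow(m$pairs), 0)
    } else {
      expect_equal(nrow(m$pairs), nrow(oracle))
      expect_setequal(
        paste(m$pairs$video_id, m$pairs$hae_id),
        paste(oracle$v, oracle$h)
      )
    }
  }
})

test_that("matching is invariant under joint time translation", {
  set.seed(5)
  vt <- sort(runif(6, 0, 30))
  ht <- sort(runif(5, 0, 30))
  m0 <- match_events(vlog(vt), hlog(ht), 2)
  m1 <- match_events(vlog(vt + 100), hlog(ht + 100), 2)
  expect_equal(m0$pairs[c("video_id", "hae_id")],
               m1$pairs[c("video_id", "hae_id")])
})

test_that("outcome labels implement the verification logic", {
  # matched direct head impact -> TP
  v <- vlog(10); h <- hlog(10.2)
  lab <- label_outcomes(match_events(v, h, 2), v)
  expect_equal(unname(lab$counts["TP"]), 1)

  # contact without head impact, no HAE -> TN
  v <- vlog(10, impact = FALSE)
  lab <- label_outcomes(match_events(v, hlog(numeric(0)), 2), v)
  expect_equal(unname(lab$counts["TN"]), 1)

  # HAE with no video event in tolerance -> FP
  v <- vlog(numeric(0))
  lab <- label_outcomes(match_events(v, hlog(50), 2), v)
  expect_equal(unname(lab$counts["FP"]), 1)

  # unmatched direct head impact -> FN
  v <- vlog(10)
  lab <- label_outcomes(match_events(v, hlog(numeric(0)), 2), v)
  expect_equal(unname(lab$counts["FN"]), 1)

  # unclear events are held out whether or not they absorbed an HAE
  v <- vlog(c(10, 20), unclear = TRUE)
  lab <- label_outcomes(match_events(v, hlog(10.1), 2), v)
  expect_equal(unname(lab$counts["UNCLEAR"]), 2)
  expect_equal(sum(lab$counts[c("TP", "FP", "FN", "TN")]), 0)

  # a contact-only event that absorbed an HAE is a sensor false positive
  v <- vlog(10, impact = FALSE)
  lab <- label_outcomes(match_events(v, hlog(10.1), 2), v)
  expect_equal(unname(lab$counts["FP"]), 1)
})

test_that("scenario tables reproduce the unclear arithmetic", {
  base <- c(TP = 655, FP = 54, FN = 45, TN = 1061, UNCLEAR = 257)
  vv <- build_contingency(base, "visually_verified")
  expect_equal(c(vv$tp, vv$fp, vv$fn, vv$tn), c(655, 54, 45, 1061))

  best <- build_contingency(base, "best_case")
  expect_equal(c(best$tp, best$fp, best$fn, best$tn), c(912, 54, 45, 1061))

  worst <- build_contingency(base, "worst_case")
  expect_equal(c(worst$tp, worst$fp, worst$fn, worst$tn), c(655, 311, 45, 1061))

  # no unclear events: the three scenarios coincide
  none <- c(TP = 10, FP = 2, FN = 1, TN = 5, UNCLEAR = 0)
  for (s in c("best_case", "worst_case")) {
    tb <- build_contingency(none, s)
    expect_equal(c(tb$tp, tb$fp), c(10, 2))
  }
  expect_error(build_contingency(base, "optimistic"))
})

test_that("ball-out-of-play exclusion reduces FP only, within bounds", {
  tb <- contingency_table(tp = 655, fp = 54, fn = 45, tn = 1061)
  ex <- exclude_ball_out_of_play(tb, 43)
  expect_equal(ex$fp, 11)
  expect_equal(c(ex$tp, ex$fn, ex$tn), c(655, 45, 1061))
  expect_equal(exclude_ball_out_of_play(tb, 0), tb)
  expect_error(exclude_ball_out_of_play(tb, 55), "between 0 and FP")
})
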
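test_that("sensitivity and PPV reproduce the printed season accuracy", {
  tb <- contingency_table(tp = 655, fp = 54, fn = 45, tn = 1061)
  expect_equal(round(100 * sensitivity(tb), 1), 93.6)
  expect_equal(round(100 * ppv(tb), 1), 92.4)

  best <- contingency_table(tp = 912, fp = 54, fn = 45, tn = 1061)
  expect_equal(round(100 * sensitivity(best), 1), 95.3)

  expect_equal(sensitivity(contingency_table(0, 2, 5, 1)), 0)
  expect_error(sensitivity(contingency_table(0, 2, 0, 1)), "undefined")
  expect_error(ppv(contingency_table(0, 0, 3, 1)), "undefined")
})

test_that("athlete-exposure rates are reported to one decimal", {
  expect_equal(rate_per_athlete_exposure(655, 61), 10.7)
  expect_equal(rate_per_athlete_exposure(0, 61), 0)
  expect_equal(rate_per_athlete_exposure(61, 61), 1)
  expect_error(rate_per_athlete_exposure(5, 0), "positive")
})

test_that("magnitude summaries stratify, partition, and bracket the law's median", {
  single <- data.frame(pla_g = 20, pra_rads2 = 1500)
  s1 <- summarize_magnitudes(single)
  expect_equal(s1$pla_median, 20)
  expect_equal(s1$pla_q25, 20)
  expect_equal(s1$pla_q75, 20)

  set.seed(20)
  vhis <- data.frame(
    pla_g = sample_magnitude(655, 21.5, c(15.4, 33.9)),
    pra_rads2 = sample_magnitude(655, 1702, c(1170, 2772)),
    scenario = sample(c("ruck", "maul", "primary_tackler"), 655, replace = TRUE)
  )
  tb <- summarize_magnitudes(vhis, "scenario", boot_seed = 5)
  expect_equal(sum(tb$n[tb$stratum != "Total"]), 655)
  expect_equal(tb$n[tb$stratum == "Total"], 655)
  tot <- tb[tb$stratum == "Total", ]
  # bootstrap CI of the sample median brackets the law's median
  expect_lte(tot$pla_ci_lo, 21.5 * 1.02)
  expect_gte(tot$pla_ci_hi, 21.5 * 0.98)
  # empty stratum row: n = 0, NA summaries
  tb2 <- summarize_magnitudes(vhis, "scenario",
                              levels = c("ruck", "maul", "primary_tackler", "scrum"))
  expect_equal(tb2$n[tb2$stratum == "scrum"], 0)
  expect_true(is.na(tb2$pla_median[tb2$stratum == "scrum"]))
})

test_that("rank-sum comparison matches exact enumeration and is rank-invariant", {
  # a = {1,2,3}, b = {10,11,12}: U = 0; exact two-sided p by enumerating
  # all choose(6,3) = 20 rank assignments: only the two extreme ones give
  # U <= 0 or U >= 9, so p = 2/20 = 0.1
  combos <- combn(6, 3)
  u_all <- apply(combos, 2, function(idx) sum(rank(1:6)[idx]) - 6)
  p_exact <- mean(u_all <= 0) + mean(u_all >= 9)
  res <- compare_groups(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, p_exact)
  expect_equal(p_exact, 0.1)

  ident <- compare_groups(c(2, 4, 6, 8), c(2, 4, 6, 8))
  expect_equal(ident$p_value, 1)

  set.seed(9)
  a <- rlnorm(30); b <- rlnorm(25, meanlog = 0.5)
  r1 <- compare_groups(a, b)
  r2 <- compare_groups(log(a), log(b))  # monotone transform
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$statistic, r2$statistic)
  expect_error(compare_groups(numeric(0), 1), "non-empty")
})

test_that("Shapiro-Wilk behaves on normal and log-normal samples", {
  set.seed(14)
  normal <- rnorm(1000)
  rn <- normality_test(normal)
  expect_gt(rn$W, 0.99)

  heavy <- rlnorm(500, sdlog = 1)
  rh <- normality_test(heavy)
  expect_lt(rh$W, 0.9)
  expect_lt(rh$p_value, 0.001)

  expect_error(normality_test(c(1, 2)), "3 <= n")
  expect_error(normality_test(rnorm(5001)), "3 <= n")
})

test_that("rater agreement and Cohen's kappa", {
  ident <- rater_agreement(c("c", "n", "c", "c"), c("c", "n", "c", "c"))
  expect_equal(ident$percent_agreement, 100)
  expect_equal(ident$kappa, 1)

  # constructed 2x2 code table: p_o = 0.9 with 0.5/0.5 marginals -> kappa 0.8
  a <- rep(c("x", "y"), each = 10)
  b <- c(rep("x", 9), "y", "x", rep("y", 9))
  res <- rater_agreement(a, b)
  expect_equal(res$percent_agreement, 90)
  expect_equal(res$kappa, 0.8)

  # one rater constant: agreement equals chance, kappa 0
  const <- rater_agreement(rep("x", 10), rep(c("x", "y"), 5))
  expect_equal(const$kappa, 0)

  expect_error(rater_agreement(c("a", "b"), "a"), "equal length")
})
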
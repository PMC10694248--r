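#' Diagnostic accuracy metrics
#'
#' Sensitivity is `TP / (TP + FN)`; positive predictive value is
#' `TP / (TP + FP)`, both computed from a 2 x 2 video-vs-sensor contingency
#' table.
#'
#' @param table an `img_contingency` (see [contingency_table()]).
#' @return a proportion in [0, 1].
#' @examples
#' tb <- contingency_table(tp = 655, fp = 54, fn = 45, tn = 1061)
#' sensitivity(tb)  # 0.9357
#' ppv(tb)          # 0.9238
#' @export
sensitivity <- function(table) {
  if (!inherits(table, "img_contingency")) {
    data_error("`table` must be an img_contingency")
  }
  if (table$tp + table$fn == 0) {
    data_error("sensitivity undefined: TP + FN = 0")
  }
  table$tp / (table$tp + table$fn)
}

#' @rdname sensitivity
#' @export
ppv <- function(table) {
  if (!inherits(table, "img_contingency")) {
    data_error("`table` must be an img_contingency")
  }
  if (table$tp + table$fp == 0) {
    data_error("PPV undefined: TP + FP = 0")
  }
  table$tp / (table$tp + table$fp)
}

#' Events per athlete exposure
#'
#' An athlete exposure is one player wearing an IMG participating in one
#' game; event counts are reported as rates per exposure, rounded to one
#' decimal for reporting.
#'
#' @param count non-negative event count.
#' @param n_exposures positive number of athlete exposures.
#' @param digits decimals used for the reported rate.
#' @return the rounded rate.
#' @examples
#' rate_per_athlete_exposure(655, 61)  # 10.7
#' @export
rate_per_athlete_exposure <- function(count, n_exposures, digits = 1) {
  if (!is.numeric(count) || length(count) != 1L || count < 0) {
    data_error("count must be a non-negative number")
  }
  if (!is_pos(n_exposures)) data_error("n_exposures must be positive")
  round(count / n_exposures, digits)
}

#' Stratified magnitude summaries
#'
#' Summarizes verified-head-impact peak linear and rotational accelerations
#' per stratum: count, median, interquartile range, and a seeded
#' percentile-bootstrap confidence interval of the median, plus a Total row.
#' Empty strata are emitted with `n = 0` and `NA` summaries.
#'
#' @param vhis data.frame of verified head impacts carrying `pla_g` and
#'   `pra_rads2` plus the stratum column.
#' @param strata_key name of the stratum column, or `NULL` for the total
#'   row only.
#' @param levels optional explicit stratum levels (order of rows).
#' @param boot_resamples bootstrap resamples for the CI of the median.
#' @param conf_level confidence level.
#' @param boot_seed integer seed for the bootstrap, for reproducible
#'   intervals.
#' @return data.frame with one row per stratum plus `Total`.
#' @export
summarize_magnitudes <- function(vhis, strata_key = NULL, levels = NULL,
                                 boot_resamples = 2000, conf_level = 0.95,
                                 boot_seed = 1L) {
  if (!is.null(strata_key) && !strata_key %in% names(vhis)) {
    data_error("stratum column '%s' not found", strata_key)
  }
  groups <- if (is.null(strata_key)) {
    list()
  } else {
    lv <- if (is.null(levels)) {
      unique(vhis[[strata_key]][!is.na(vhis[[strata_key]])])
    } else {
      levels
    }
    stats::setNames(lapply(lv, function(l) {
      which(!is.na(vhis[[strata_key]]) & vhis[[strata_key]] == l)
    }), as.character(lv))
  }
  groups$Total <- seq_len(nrow(vhis))
  rows <- with_seed(boot_seed, {
    lapply(names(groups), function(g) {
      idx <- groups[[g]]
      pla <- vhis$pla_g[idx]
      pra <- vhis$pra_rads2[idx]
      cbind(
        data.frame(stratum = g, n = length(idx), stringsAsFactors = FALSE),
        magnitude_row(pla, "pla", boot_resamples, conf_level),
        magnitude_row(pra, "pra", boot_resamples, conf_level)
      )
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

magnitude_row <- function(x, prefix, boot_resamples, conf_level) {
  if (!length(x)) {
    row <- data.frame(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_)
  } else {
    q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
    ci <- boot_median_ci(x, boot_resamples, conf_level)
    row <- data.frame(q[2L], q[1L], q[3L], ci[1L], ci[2L])
  }
  names(row) <- paste0(prefix, c("_median", "_q25", "_q75", "_ci_lo", "_ci_hi"))
  row
}

# Percentile bootstrap CI of the median; degenerates gracefully for n = 1.
boot_median_ci <- function(x, resamples, conf_level) {
  n <- length(x)
  if (n == 1L) return(c(x, x))
  meds <- vapply(seq_len(resamples), function(i) {
    median(x[sample.int(n, n, replace = TRUE)])
  }, numeric(1L))
  alpha <- (1 - conf_level) / 2
  unname(quantile(meds, c(alpha, 1 - alpha), type = 7))
}

#' Non-parametric two-group comparison
#'
#' Two-sided Mann-Whitney rank-sum test, exact for small samples without
#' ties and a tie-corrected normal approximation otherwise (the default
#' behaviour of [stats::wilcox.test()]). Impact magnitudes are strongly
#' non-normal, so group contrasts (halves, positional groups, expected vs
#' unexpected impacts) use ranks.
#'
#' @param values_a,values_b numeric vectors, each non-empty.
#' @return list with `statistic` (the Mann-Whitney U of the first group)
#'   and `p_value`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) {
    data_error("both groups must be non-empty")
  }
  ht <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Shapiro-Wilk normality test
#'
#' Used to decide between parametric and rank-based summaries; on-field
#' impact magnitudes characteristically fail it with W well below 1.
#'
#' @param values numeric vector with 3 to 5000 observations.
#' @return list with `W` and `p_value`.
#' @export
normality_test <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) {
    data_error("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)", n)
  }
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p_value = ht$p.value)
}

#' Inter-rater agreement
#'
#' Raw percent agreement and Cohen's kappa,
#' `kappa = (p_o - p_e) / (1 - p_e)`, with the chance agreement `p_e`
#' computed from the two raters' marginal coding frequencies. Used to
#' quantify agreement between independent video reviewers coding the same
#' game.
#'
#' @param codes_a,codes_b equal-length categorical vectors (one code per
#'   event).
#' @return list with `percent_agreement` (0-100) and `kappa`.
#' @examples
#' rater_agreement(c("c", "c", "n"), c("c", "c", "n"))
#' @export
rater_agreement <- function(codes_a, codes_b) {
  if (length(codes_a) != length(codes_b)) {
    data_error("code sequences must have equal length")
  }
  if (!length(codes_a)) data_error("code sequences must be non-empty")
  lev <- union(unique(codes_a), unique(codes_b))
  a <- factor(codes_a, levels = lev)
  b <- factor(codes_b, levels = lev)
  p_o <- mean(a == b)
  p_e <- sum(prop.table(table(a)) * prop.table(table(b)))
  kappa <- if (1 - p_e < 1e-12) {
    # both raters constant and identical: perfect agreement by convention
    1
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  list(percent_agreement = 100 * p_o, kappa = kappa)
}
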
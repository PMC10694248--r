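#' Assemble a validation report
#'
#' Collects everything the accuracy analysis produces into one serializable
#' object: the 2 x 2 contingency tables and their sensitivity/PPV under the
#' visually-verified, best-case and worst-case handling of unclear events;
#' PPV after excluding ball-out-of-play false positives; verified-head-impact
#' and contact-event rates per athlete exposure; stratified magnitude tables
#' (game half, positional group, anticipation, game scenario, direction of
#' contact, tackle intent); and non-parametric test records for the standard
#' group contrasts.
#'
#' @param labels an `img_labels` from [label_outcomes()], or a named count
#'   vector (`TP`, `FP`, `FN`, `TN`, `UNCLEAR`).
#' @param vhis data.frame of verified head impacts (one row per TP) with
#'   `pla_g`, `pra_rads2` and any of the stratum columns `half`, `position`,
#'   `anticipated`, `scenario`, `direction`, `tackle_intent`.
#' @param n_exposures number of athlete exposures.
#' @param n_bop_fps count of false positives attributable to ball-out-of-play
#'   mouthguard handling.
#' @param boot_resamples,conf_level,boot_seed bootstrap settings for the
#'   magnitude tables (see [summarize_magnitudes()]).
#' @return object of class `img_report`.
#' @export
build_report <- function(labels, vhis, n_exposures, n_bop_fps = 0,
                         boot_resamples = 2000, conf_level = 0.95,
                         boot_seed = 1L) {
  counts <- if (inherits(labels, "img_labels")) labels$counts else labels
  scen_names <- c("visually_verified", "best_case", "worst_case")
  tables <- lapply(scen_names, function(s) build_contingency(counts, s))
  names(tables) <- scen_names
  scenarios <- data.frame(
    scenario = scen_names,
    tp = vapply(tables, function(t) t$tp, numeric(1L)),
    fp = vapply(tables, function(t) t$fp, numeric(1L)),
    fn = vapply(tables, function(t) t$fn, numeric(1L)),
    tn = vapply(tables, function(t) t$tn, numeric(1L)),
    sensitivity = vapply(tables, safe_metric, numeric(1L), fn = sensitivity),
    ppv = vapply(tables, safe_metric, numeric(1L), fn = ppv),
    stringsAsFactors = FALSE
  )
  rownames(scenarios) <- NULL
  ppv_bop <- safe_metric(
    exclude_ball_out_of_play(tables$visually_verified, n_bop_fps), ppv
  )

  n_contacts <- sum(counts[c("TP", "FN", "TN", "UNCLEAR")])
  rates <- list(
    vhi_per_exposure = rate_per_athlete_exposure(counts[["TP"]], n_exposures),
    contacts_per_exposure = rate_per_athlete_exposure(n_contacts, n_exposures)
  )

  strata <- c("half", "position", "anticipated", "scenario", "direction",
              "tackle_intent")
  strata <- strata[strata %in% names(vhis)]
  magnitude_tables <- lapply(strata, function(s) {
    summarize_magnitudes(vhis, s, boot_resamples = boot_resamples,
                         conf_level = conf_level, boot_seed = boot_seed)
  })
  names(magnitude_tables) <- strata
  magnitude_tables$overall <- summarize_magnitudes(
    vhis, NULL, boot_resamples = boot_resamples, conf_level = conf_level,
    boot_seed = boot_seed
  )

  tests <- report_tests(vhis)

  structure(
    list(
      counts = as.list(counts),
      scenarios = scenarios,
      ppv_bop_excluded = ppv_bop,
      n_bop_fps = n_bop_fps,
      n_exposures = n_exposures,
      rates = rates,
      magnitude_tables = magnitude_tables,
      tests = tests
    ),
    class = "img_report"
  )
}

# A metric that is undefined on degenerate tables (e.g. no impacts at all)
# is reported as NA rather than aborting the report.
safe_metric <- function(table, fn) {
  tryCatch(fn(table), imgval_error = function(e) NA_real_)
}

# Standard group contrasts and normality checks, skipped when a stratum is
# empty on one side.
report_tests <- function(vhis) {
  out <- list()
  two_group <- function(var, a, b) {
    x <- vhis[!is.na(vhis[[var]]) & vhis[[var]] == a, ]
    y <- vhis[!is.na(vhis[[var]]) & vhis[[var]] == b, ]
    if (!nrow(x) || !nrow(y)) return(NULL)
    lapply(c(pla = "pla_g", pra = "pra_rads2"), function(col) {
      compare_groups(x[[col]], y[[col]])
    })
  }
  if ("half" %in% names(vhis)) {
    out$half <- two_group("half", "first", "second")
  }
  if ("position" %in% names(vhis)) {
    out$position <- two_group("position", "back", "forward")
  }
  if ("anticipated" %in% names(vhis)) {
    out$anticipated <- two_group("anticipated", TRUE, FALSE)
  }
  n <- nrow(vhis)
  if (n >= 3 && n <= 5000) {
    out$normality <- list(
      pla = normality_test(vhis$pla_g),
      pra = normality_test(vhis$pra_rads2)
    )
  }
  out[!vapply(out, is.null, logical(1L))]
}

#' @export
print.img_report <- function(x, ...) {
  cat("<img_report>\n\n")
  s <- x$scenarios
  cat("Accuracy by verification scenario:\n")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-17s TP %4d  FP %3d  FN %3d  TN %4d  sens %5.1f%%  PPV %5.1f%%\n",
                s$scenario[i], s$tp[i], s$fp[i], s$fn[i], s$tn[i],
                100 * s$sensitivity[i], 100 * s$ppv[i]))
  }
  cat(sprintf("  PPV after excluding %d ball-out-of-play FPs: %.1f%%\n",
              x$n_bop_fps, 100 * x$ppv_bop_excluded))
  cat(sprintf("\n%.1f verified head impacts and %.1f contact events per athlete exposure (n = %d)\n",
              x$rates$vhi_per_exposure, x$rates$contacts_per_exposure,
              x$n_exposures))
  ov <- x$magnitude_tables$overall
  if (nrow(ov) && ov$n[nrow(ov)] > 0) {
    tot <- ov[nrow(ov), ]
    cat(sprintf("VHI magnitudes: PLA median %.1f g (IQR %.1f-%.1f), PRA median %.0f rad/s2 (IQR %.0f-%.0f)\n",
                tot$pla_median, tot$pla_q25, tot$pla_q75,
                tot$pra_median, tot$pra_q25, tot$pra_q75))
  }
  invisible(x)
}

#' Render a report as markdown
#'
#' Human-readable rendering of the contingency scenarios and the stratified
#' magnitude tables.
#'
#' @param report an `img_report`.
#' @return character vector of markdown lines.
#' @export
report_to_markdown <- function(report) {
  lines <- c("# IMG validation report", "")
  lines <- c(lines, "## Accuracy by verification scenario", "",
             "| Scenario | TP | FP | FN | TN | Sensitivity | PPV |",
             "|---|---|---|---|---|---|---|")
  s <- report$scenarios
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, sprintf(
      "| %s | %d | %d | %d | %d | %.1f%% | %.1f%% |",
      s$scenario[i], s$tp[i], s$fp[i], s$fn[i], s$tn[i],
      100 * s$sensitivity[i], 100 * s$ppv[i]
    ))
  }
  lines <- c(lines, "", sprintf(
    "PPV excluding %d ball-out-of-play false positives: **%.1f%%**",
    report$n_bop_fps, 100 * report$ppv_bop_excluded
  ), "", sprintf(
    "%.1f verified head impacts / %.1f contact events per athlete exposure (n = %d).",
    report$rates$vhi_per_exposure, report$rates$contacts_per_exposure,
    report$n_exposures
  ))
  for (nm in names(report$magnitude_tables)) {
    tb <- report$magnitude_tables[[nm]]
    lines <- c(lines, "", sprintf("## Magnitudes by %s", nm), "",
               "| Stratum | n | PLA median (g) | PLA 95% CI | PRA median (rad/s2) | PRA 95% CI |",
               "|---|---|---|---|---|---|")
    for (i in seq_len(nrow(tb))) {
      lines <- c(lines, sprintf(
        "| %s | %d | %s | %s | %s | %s |",
        tb$stratum[i], tb$n[i],
        fmt_num(tb$pla_median[i], 1),
        fmt_ci(tb$pla_ci_lo[i], tb$pla_ci_hi[i], 1),
        fmt_num(tb$pra_median[i], 0),
        fmt_ci(tb$pra_ci_lo[i], tb$pra_ci_hi[i], 0)
      ))
    }
  }
  lines
}

fmt_num <- function(x, digits) {
  if (is.na(x)) "-" else formatC(x, format = "f", digits = digits)
}

fmt_ci <- function(lo, hi, digits) {
  if (is.na(lo) || is.na(hi)) "-" else {
    paste0(fmt_num(lo, digits), "-", fmt_num(hi, digits))
  }
}
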
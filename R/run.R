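#' Run a full synthetic validation study end to end
#'
#' Simulates `n_sessions` athlete exposures, processes every recording into
#' head acceleration events, matches them against the session's video log,
#' labels TP/FP/FN/TN/unclear outcomes, and assembles the season-level
#' validation report. Everything is reproducible from the configuration and
#' master seed: each session receives a deterministically derived sub-seed.
#'
#' False positives are attributed to ball-out-of-play mouthguard handling by
#' looking up the nearest ground-truth event for each false-positive HAE —
#' the simulated analogue of reviewers re-examining footage around each
#' unexplained capture.
#'
#' @param config an [run_config()].
#' @param out_dir optional directory; when given, per-session truth/video/HAE
#'   logs and the final JSON and markdown reports are written under it.
#' @param verbose print per-session progress.
#' @return list of class `img_run`: `report` (see [build_report()]), `counts`
#'   (season TP/FP/FN/TN/UNCLEAR), `vhis` (one row per verified head impact
#'   with magnitudes and strata), `pla_recovery` (injected vs recovered PLA
#'   for captured direct head impacts), `n_bop_fps`, and `sessions`
#'   (per-session tallies).
#' @export
run_end_to_end <- function(config = run_config(), out_dir = NULL,
                           verbose = FALSE) {
  if (!inherits(config, "img_run_config")) {
    config_error("`config` must come from run_config()")
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  positions <- with_seed(config$seed, {
    ifelse(runif(config$n_sessions) < config$prop_forward, "forward", "back")
  })
  total <- c(TP = 0L, FP = 0L, FN = 0L, TN = 0L, UNCLEAR = 0L)
  vhis <- list()
  recovery <- list()
  n_bop <- 0L
  sessions <- vector("list", config$n_sessions)

  for (i in seq_len(config$n_sessions)) {
    scfg <- config$session
    scfg$seed <- session_seed(config$seed, i)
    ses <- generate_session(scfg,
                            sensor_positions_m = config$pipeline$sensor_positions_m,
                            frame_rotation = config$pipeline$frame_rotation)
    hae <- process_recording(ses$recording, config$pipeline)
    match <- match_events(ses$video, hae, config$match_tolerance_s)
    labels <- label_outcomes(match, ses$video)
    total <- total + labels$counts

    vhis[[i]] <- session_vhis(ses, hae, match, labels, positions[i], i)
    recovery[[i]] <- session_recovery(ses$truth, hae)
    n_bop <- n_bop + count_bop_fps(ses, hae, match, labels)

    sessions[[i]] <- data.frame(
      session = i, position = positions[i], n_truth = nrow(ses$truth),
      n_video = nrow(ses$video), n_hae = nrow(hae),
      tp = labels$counts[["TP"]], fp = labels$counts[["FP"]],
      fn = labels$counts[["FN"]], tn = labels$counts[["TN"]],
      unclear = labels$counts[["UNCLEAR"]], stringsAsFactors = FALSE
    )
    if (!is.null(out_dir)) {
      write_event_log(ses$truth, file.path(out_dir, sprintf("truth_%02d.csv", i)))
      write_event_log(ses$video, file.path(out_dir, sprintf("video_%02d.csv", i)))
      write_event_log(hae, file.path(out_dir, sprintf("hae_%02d.csv", i)))
    }
    if (verbose) {
      message(sprintf("session %d/%d: %d HAEs, TP %d FP %d FN %d",
                      i, config$n_sessions, nrow(hae), labels$counts[["TP"]],
                      labels$counts[["FP"]], labels$counts[["FN"]]))
    }
  }
  vhis <- do.call(rbind, vhis)
  if (is.null(vhis)) vhis <- empty_vhis()
  recovery <- do.call(rbind, recovery)
  if (is.null(recovery)) recovery <- empty_recovery()
  report <- build_report(
    total, vhis, n_exposures = config$n_sessions, n_bop_fps = n_bop,
    boot_resamples = config$boot_resamples, conf_level = config$conf_level,
    boot_seed = config$seed
  )
  out <- list(
    report = report, counts = total, vhis = vhis, pla_recovery = recovery,
    n_bop_fps = n_bop, sessions = do.call(rbind, sessions)
  )
  class(out) <- "img_run"
  if (!is.null(out_dir)) {
    write_report(report, file.path(out_dir, "report.json"), "json")
    write_report(report, file.path(out_dir, "report.md"), "markdown")
  }
  out
}

empty_vhis <- function() {
  data.frame(
    session = integer(), pla_g = numeric(), pra_rads2 = numeric(),
    half = character(), position = character(), anticipated = logical(),
    scenario = character(), direction = character(),
    tackle_intent = character(), stringsAsFactors = FALSE
  )
}

empty_recovery <- function() {
  data.frame(
    true_pla_g = numeric(), pla_g = numeric(), true_pra_rads2 = numeric(),
    pra_rads2 = numeric(), duration_ms = numeric()
  )
}

# Deterministic 32-bit sub-seed for session i of a run.
session_seed <- function(seed, i) {
  (as.numeric(seed) * 1009 + i * 9973) %% 2147483647
}

# One row per verified head impact (TP pair), with magnitudes from the HAE
# and strata from the video coding.
session_vhis <- function(ses, hae, match, labels, position, session_idx) {
  tp_ids <- labels$video$event_id[labels$video$label == "TP"]
  if (!length(tp_ids)) return(NULL)
  pairs <- match$pairs[match$pairs$video_id %in% tp_ids, ]
  v <- ses$video[base::match(pairs$video_id, ses$video$event_id), ]
  h <- hae[base::match(pairs$hae_id, hae$event_id), ]
  data.frame(
    session = session_idx,
    pla_g = h$pla_g,
    pra_rads2 = h$pra_rads2,
    half = ifelse(v$time_s < ses$recording$duration_s / 2, "first", "second"),
    position = position,
    anticipated = v$anticipated,
    scenario = v$scenario,
    direction = v$direction,
    tackle_intent = v$tackle_intent,
    stringsAsFactors = FALSE
  )
}

# Injected vs recovered PLA for captured direct head impacts, paired by
# trigger-to-event time proximity.
session_recovery <- function(truth, hae, tol_s = 0.06) {
  imp <- truth[truth$kind == "direct_head_impact", ]
  if (!nrow(imp) || !nrow(hae)) return(NULL)
  rows <- lapply(seq_len(nrow(hae)), function(j) {
    d <- abs(imp$time_s - hae$trigger_time_s[j])
    k <- which.min(d)
    if (d[k] > tol_s) return(NULL)
    data.frame(
      true_pla_g = imp$true_pla_g[k], pla_g = hae$pla_g[j],
      true_pra_rads2 = imp$true_pra_rads2[k], pra_rads2 = hae$pra_rads2[j],
      duration_ms = imp$duration_ms[k]
    )
  })
  do.call(rbind, rows)
}

# False-positive HAEs arising from out-of-play mouthguard handling: nearest
# ground-truth event is a handling artifact with ball_in_play = FALSE.
count_bop_fps <- function(ses, hae, match, labels, tol_s = 0.1) {
  fp_hae <- c(
    labels$hae$event_id,
    match$pairs$hae_id[match$pairs$video_id %in%
                         labels$video$event_id[labels$video$label == "FP"]]
  )
  if (!length(fp_hae) || !nrow(ses$truth)) return(0L)
  art <- ses$truth[ses$truth$kind == "handling_artifact" & !ses$truth$ball_in_play, ]
  if (!nrow(art)) return(0L)
  times <- hae$trigger_time_s[base::match(fp_hae, hae$event_id)]
  sum(vapply(times, function(t) any(abs(art$time_s - t) <= tol_s), logical(1L)))
}

#' @export
print.img_run <- function(x, ...) {
  cat(sprintf("<img_run> %d sessions\n\n", nrow(x$sessions)))
  print(x$report)
  invisible(x)
}
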
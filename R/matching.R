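#' Shift a video log onto the sensor clock
#'
#' Video logs are time-stamped against a world clock recorded at the start
#' of each video; aligning them to the sensor stream is a single constant
#' offset. Order is preserved and offsets compose additively.
#'
#' @param video_log data.frame with a `time_s` column.
#' @param offset_s finite offset (s) added to every timestamp.
#' @return the shifted log.
#' @export
synchronize_clocks <- function(video_log, offset_s) {
  if (!is.numeric(offset_s) || length(offset_s) != 1L || !is.finite(offset_s)) {
    config_error("offset_s must be a finite number")
  }
  video_log$time_s <- video_log$time_s + offset_s
  video_log
}

#' Match video events to head acceleration events
#'
#' Greedy nearest-in-time one-to-one matching: the globally closest
#' (video event, HAE) pair with |time difference| at most `tolerance_s` is
#' paired first, then the next closest among the remaining events, and so
#' on; ties are broken in favour of the earlier video event. Each video
#' event and each HAE appears in at most one pair.
#'
#' @param video_events data.frame with `event_id` and `time_s`.
#' @param haes data.frame with `event_id` and `trigger_time_s`.
#' @param tolerance_s maximal |time difference| (s) for a pair.
#' @return list of class `img_match` with `pairs` (data.frame `video_id`,
#'   `hae_id`, `dt_s`), `unmatched_video` and `unmatched_hae` (id vectors).
#' @export
match_events <- function(video_events, haes, tolerance_s = 2) {
  if (!is.numeric(tolerance_s) || length(tolerance_s) != 1L || tolerance_s < 0) {
    config_error("tolerance_s must be non-negative")
  }
  nv <- nrow(video_events)
  nh <- nrow(haes)
  pairs <- data.frame(video_id = integer(), hae_id = integer(), dt_s = numeric())
  if (nv && nh) {
    dt <- outer(haes$trigger_time_s, video_events$time_s, `-`)
    cand <- which(abs(dt) <= tolerance_s, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(abs(dt[cand]), video_events$time_s[cand[, 2L]])
      cand <- cand[ord, , drop = FALSE]
      used_h <- logical(nh)
      used_v <- logical(nv)
      vi <- hi <- integer(0)
      for (k in seq_len(nrow(cand))) {
        h <- cand[k, 1L]
        v <- cand[k, 2L]
        if (!used_h[h] && !used_v[v]) {
          used_h[h] <- used_v[v] <- TRUE
          vi <- c(vi, v)
          hi <- c(hi, h)
        }
      }
      pairs <- data.frame(
        video_id = video_events$event_id[vi],
        hae_id = haes$event_id[hi],
        dt_s = haes$trigger_time_s[hi] - video_events$time_s[vi]
      )
    }
  }
  structure(
    list(
      pairs = pairs,
      unmatched_video = setdiff(video_events$event_id, pairs$video_id),
      unmatched_hae = setdiff(haes$event_id, pairs$hae_id)
    ),
    class = "img_match"
  )
}

#' Label matched and unmatched events
#'
#' Applies the study's verification logic to a matching result:
#' a video-coded direct head impact matched to an HAE is a true positive
#' (a verified head impact); an unmatched direct head impact is a false
#' negative; a contact event without direct head impact is a true negative
#' when unmatched and a false positive (of the sensor) when it absorbed an
#' HAE; an HAE matched to no video event at all is a false positive; video
#' events coded unclear are labelled `UNCLEAR` and held out of the base
#' contingency table, whether or not an HAE accompanied them.
#'
#' @param match an `img_match` from [match_events()].
#' @param video_events the video log used for the matching; must carry
#'   `event_id`, `is_direct_head_impact` (NA allowed when unclear) and
#'   `is_unclear`.
#' @return list of class `img_labels`: `video` (data.frame `event_id`,
#'   `label`), `hae` (data.frame `event_id`, `label`), and `counts`
#'   (named vector TP, FP, FN, TN, UNCLEAR).
#' @export
label_outcomes <- function(match, video_events) {
  v <- video_events
  if (any(!v$is_unclear & is.na(v$is_direct_head_impact))) {
    data_error("video event with undefined head-impact status but not unclear")
  }
  if (any(v$is_unclear & !is.na(v$is_direct_head_impact))) {
    data_error("video event flagged both unclear and coded for head impact")
  }
  matched_v <- match$pairs$video_id
  vlab <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    is_matched <- v$event_id[i] %in% matched_v
    vlab[i] <- if (v$is_unclear[i]) {
      "UNCLEAR"
    } else if (isTRUE(v$is_direct_head_impact[i])) {
      if (is_matched) "TP" else "FN"
    } else {
      if (is_matched) "FP" else "TN"
    }
  }
  hlab <- data.frame(
    event_id = match$unmatched_hae,
    label = rep("FP", length(match$unmatched_hae)),
    stringsAsFactors = FALSE
  )
  counts <- c(
    TP = sum(vlab == "TP"),
    FP = sum(vlab == "FP") + nrow(hlab),
    FN = sum(vlab == "FN"),
    TN = sum(vlab == "TN"),
    UNCLEAR = sum(vlab == "UNCLEAR")
  )
  structure(
    list(
      video = data.frame(event_id = v$event_id, label = vlab,
                         stringsAsFactors = FALSE),
      hae = hlab,
      counts = counts
    ),
    class = "img_labels"
  )
}

#' Construct a contingency table under a verification scenario
#'
#' The base (`visually_verified`) table uses only clearly-coded video
#' events. The `best_case` scenario assumes every unclear contact event was
#' a direct head impact and adds the unclear count to the true positives;
#' the `worst_case` scenario assumes none was and adds it to the false
#' positives.
#'
#' @param labels an `img_labels` from [label_outcomes()], or a named vector
#'   of base counts (`TP`, `FP`, `FN`, `TN`, `UNCLEAR`).
#' @param scenario one of `"visually_verified"`, `"best_case"`,
#'   `"worst_case"`.
#' @return object of class `img_contingency`: fields `tp`, `fp`, `fn`,
#'   `tn`, `unclear`, `scenario`.
#' @examples
#' base <- contingency_table(tp = 655, fp = 54, fn = 45, tn = 1061, unclear = 257)
#' build_contingency(base, "best_case")
#' @export
build_contingency <- function(labels,
                              scenario = c("visually_verified", "best_case",
                                           "worst_case")) {
  scenario <- match.arg(scenario)
  counts <- if (inherits(labels, "img_labels")) {
    labels$counts
  } else if (inherits(labels, "img_contingency")) {
    c(TP = labels$tp, FP = labels$fp, FN = labels$fn, TN = labels$tn,
      UNCLEAR = labels$unclear)
  } else {
    labels
  }
  tp <- unname(counts[["TP"]])
  fp <- unname(counts[["FP"]])
  if (scenario == "best_case") tp <- tp + unname(counts[["UNCLEAR"]])
  if (scenario == "worst_case") fp <- fp + unname(counts[["UNCLEAR"]])
  contingency_table(
    tp = tp, fp = fp, fn = unname(counts[["FN"]]), tn = unname(counts[["TN"]]),
    unclear = unname(counts[["UNCLEAR"]]), scenario = scenario
  )
}

#' @rdname build_contingency
#' @param tp,fp,fn,tn,unclear non-negative counts.
#' @export
contingency_table <- function(tp, fp, fn, tn, unclear = 0,
                              scenario = "visually_verified") {
  for (x in list(tp, fp, fn, tn, unclear)) {
    if (!is_count(x)) data_error("contingency counts must be non-negative integers")
  }
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn, unclear = unclear,
         scenario = scenario),
    class = "img_contingency"
  )
}

#' Exclude ball-out-of-play false positives
#'
#' Most sensor false positives arise from mouthguard removal or handling
#' while the ball is out of play; excluding those re-evaluates the device
#' over active play only.
#'
#' @param table an `img_contingency`.
#' @param n_bop_fps number of excludable false positives, between 0 and
#'   `table$fp`.
#' @return the table with `fp` reduced by `n_bop_fps`.
#' @export
exclude_ball_out_of_play <- function(table, n_bop_fps) {
  if (!inherits(table, "img_contingency")) {
    data_error("`table` must be an img_contingency")
  }
  if (!is_count(n_bop_fps) || n_bop_fps > table$fp) {
    data_error("n_bop_fps must be a count between 0 and FP (= %d)", table$fp)
  }
  table$fp <- table$fp - n_bop_fps
  table
}

#' @export
print.img_contingency <- function(x, ...) {
  cat(sprintf("<img_contingency> scenario: %s\n", x$scenario))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2, byrow = TRUE,
              dimnames = list(c("video impact: yes", "video impact: no"),
                              c("HAE: yes", "HAE: no")))
  print(m)
  if (x$unclear > 0) cat(sprintf("unclear events held out: %d\n", x$unclear))
  cat(sprintf("sensitivity: %.2f%%   PPV: %.2f%%\n",
              100 * safe_metric(x, sensitivity), 100 * safe_metric(x, ppv)))
  invisible(x)
}
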
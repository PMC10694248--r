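# File formats: CSV event logs (UTF-8, comma-separated, "." decimal, times in
# seconds since session start), CSV-per-sensor recording layout with a JSON
# meta file, and JSON/markdown report serialization.

truth_log_columns <- c("event_id", "time_s", "kind", "true_pla_g",
                       "true_pra_rads2", "duration_ms", "scenario",
                       "ball_in_play", "detected")

video_log_columns <- c("event_id", "truth_id", "time_s", "is_contact",
                       "is_direct_head_impact", "is_unclear", "ball_in_play",
                       "scenario", "direction", "anticipated", "tackle_intent",
                       "speed", "body_position")

#' Read a ground-truth or video event log
#'
#' Reads and validates a CSV event log written by [write_event_log()] (or an
#' equivalent external export). Schema violations name the offending row and
#' column.
#'
#' @param path CSV file path.
#' @param type `"truth"` for ground-truth logs, `"video"` for video-coded
#'   logs.
#' @return validated data.frame.
#' @export
read_event_log <- function(path, type = c("video", "truth")) {
  type <- match.arg(type)
  if (!file.exists(path)) data_error("no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  wanted <- if (type == "truth") truth_log_columns else video_log_columns
  missing <- setdiff(wanted, names(df))
  if (length(missing)) {
    data_error("missing column(s) in %s: %s", path,
               paste(missing, collapse = ", "))
  }
  check_numeric_col(df, "time_s", path)
  if (type == "truth") {
    check_numeric_col(df, "true_pla_g", path)
    check_numeric_col(df, "true_pra_rads2", path)
    check_enum_col(df, "kind",
                   c("direct_head_impact", "contact_no_head",
                     "handling_artifact", "vocalization"), path)
    check_enum_col(df, "scenario", scenario_levels(), path)
    df$ball_in_play <- as.logical(df$ball_in_play)
    df$detected <- as.logical(df$detected)
  } else {
    check_enum_col(df, "scenario", scenario_levels(), path)
    for (col in c("is_contact", "is_direct_head_impact", "is_unclear",
                  "ball_in_play", "anticipated")) {
      df[[col]] <- as.logical(df[[col]])
    }
  }
  df
}

check_numeric_col <- function(df, col, path) {
  x <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(x) & !is.na(df[[col]]) & df[[col]] != "")
  if (length(bad)) {
    data_error("non-numeric value in column '%s' of %s at row %d",
               col, path, bad[1L])
  }
  invisible(TRUE)
}

check_enum_col <- function(df, col, levels, path) {
  x <- df[[col]]
  bad <- which(!is.na(x) & !(x %in% levels))
  if (length(bad)) {
    data_error("invalid value '%s' in column '%s' of %s at row %d",
               x[bad[1L]], col, path, bad[1L])
  }
  invisible(TRUE)
}

#' @rdname read_event_log
#' @param log data.frame to write.
#' @export
write_event_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' Write and read a recording as a directory of CSV files
#'
#' Columnar plain-text layout: one `accel<k>.csv` per accelerometer and one
#' `gyro.csv` (columns `t_s`, `x`, `y`, `z`) plus a `meta.json` with the
#' rates and duration.
#'
#' @param recording an `img_recording`.
#' @param dir directory to create/fill.
#' @return `dir` (write) or the reconstructed `img_recording` (read).
#' @export
write_recording <- function(recording, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in 1:3) {
    str <- recording$accel[[s]]
    utils::write.csv(
      data.frame(t_s = str$time, x = str$data[, 1L], y = str$data[, 2L],
                 z = str$data[, 3L]),
      file.path(dir, sprintf("accel%d.csv", s)), row.names = FALSE
    )
  }
  utils::write.csv(
    data.frame(t_s = recording$gyro$time, x = recording$gyro$data[, 1L],
               y = recording$gyro$data[, 2L], z = recording$gyro$data[, 3L]),
    file.path(dir, "gyro.csv"), row.names = FALSE
  )
  meta <- list(
    duration_s = recording$duration_s,
    accel_rate_hz = recording$accel_rate_hz,
    gyro_rate_hz = recording$gyro_rate_hz,
    accel_rates_hz = vapply(recording$accel, `[[`, numeric(1L), "rate_hz"),
    gyro_rate_actual_hz = recording$gyro$rate_hz,
    sensor_positions_m = recording$sensor_positions_m,
    frame_rotation = recording$frame_rotation
  )
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "meta.json"))
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) data_error("no meta.json in %s", dir)
  meta <- jsonlite::fromJSON(meta_path)
  read_stream <- function(f, rate) {
    df <- utils::read.csv(file.path(dir, f))
    list(time = df$t_s, data = unname(as.matrix(df[, c("x", "y", "z")])),
         rate_hz = rate)
  }
  accel <- lapply(1:3, function(s) {
    read_stream(sprintf("accel%d.csv", s), meta$accel_rates_hz[s])
  })
  structure(
    list(
      accel = accel,
      gyro = read_stream("gyro.csv", meta$gyro_rate_actual_hz),
      duration_s = meta$duration_s,
      accel_rate_hz = meta$accel_rate_hz,
      gyro_rate_hz = meta$gyro_rate_hz,
      sensor_positions_m = if (!is.null(meta$sensor_positions_m)) {
        matrix(unlist(meta$sensor_positions_m), nrow = 3L, byrow = FALSE)
      } else {
        default_sensor_positions()
      },
      frame_rotation = if (!is.null(meta$frame_rotation)) {
        matrix(unlist(meta$frame_rotation), nrow = 3L, byrow = FALSE)
      } else {
        diag(3)
      }
    ),
    class = "img_recording"
  )
}

#' Serialize a validation report
#'
#' JSON serialization is deterministic (fixed key order, full precision), so
#' writing the same report twice yields byte-identical files; the markdown
#' format renders the contingency scenarios and magnitude tables for human
#' reading.
#'
#' @param report an `img_report`.
#' @param path output file path.
#' @param format `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "markdown")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- unclass(report)
    payload$counts <- lapply(payload$counts, as.integer)
    writeLines(
      jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", pretty = TRUE),
      path
    )
  } else {
    writeLines(report_to_markdown(report), path)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  x$scenarios <- as.data.frame(x$scenarios, stringsAsFactors = FALSE)
  x$magnitude_tables <- lapply(x$magnitude_tables, function(tb) {
    as.data.frame(tb, stringsAsFactors = FALSE)
  })
  structure(x, class = "img_report")
}
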
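#' Write typing sessions to an event-log file
#'
#' Serializes sessions to the event-log schema read by
#' [parse_event_log()]: each session object carries `participant_id`,
#' `session_id` and an `events` array of `{t, action, key}` records.
#' Output is deterministic for a given session list, so identical seeds
#' yield byte-identical logs.
#'
#' @param sessions list of [typing_session] objects.
#' @param path output file.
#' @param format `"json"` (single array) or `"ndjson"` (one session per
#'   line).
#' @return `path`, invisibly.
#' @export
write_event_log <- function(sessions, path, format = c("json", "ndjson")) {
  format <- match.arg(format)
  objs <- lapply(sessions, function(s) {
    list(participant_id = s$participant_id,
         session_id = s$session_id,
         events = if (nrow(s$events)) s$events else list())
  })
  if (format == "json") {
    json <- jsonlite::toJSON(objs, dataframe = "rows", auto_unbox = TRUE,
                             digits = NA)
    writeLines(json, path)
  } else {
    lines <- vapply(objs, function(o)
      as.character(jsonlite::toJSON(o, dataframe = "rows", auto_unbox = TRUE,
                                    digits = NA)),
      character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write / read the participant feature table
#'
#' CSV with header `participant_id, mean_ht_ms, mean_ft_ms,
#' n_sessions_total, n_sessions_retained, n_keystrokes, n_excluded_ht,
#' n_excluded_ft` (plus the `no_data` flag).
#'
#' @param features data.frame from [extract_features()].
#' @param path file path.
#' @return `path` (write) / the data.frame (read), invisibly for write.
#' @export
write_features_csv <- function(features, path) {
  cols <- c("participant_id", "mean_ht_ms", "mean_ft_ms", "n_sessions_total",
            "n_sessions_retained", "n_keystrokes", "n_excluded_ht",
            "n_excluded_ft", "no_data")
  write.csv(features[, intersect(cols, names(features))], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  if (!file.exists(path))
    kd_validation_error(sprintf("features file not found: %s", path))
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read the participant metadata table
#'
#' Delimited text with at least `participant_id` and `group` columns;
#' cognitive and demographic columns as produced by [simulate_study()].
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_metadata_csv <- function(path) {
  if (!file.exists(path))
    kd_validation_error(sprintf("metadata file not found: %s", path))
  meta <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("participant_id", "group") %in% names(meta)))
    kd_validation_error("metadata must have participant_id and group columns")
  meta
}
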
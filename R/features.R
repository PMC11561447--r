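#' Hold times of a session
#'
#' Hold time (HT) is the interval between pressing and releasing one key,
#' in milliseconds: `HT_i = release_time_i - press_time_i`, one value per
#' keystroke, order preserved.
#'
#' @param keystrokes a keystroke data.frame from [pair_events()] or a
#'   [typing_session] (paired on the fly).
#' @return Numeric vector of HT values (ms); `numeric(0)` for an empty
#'   session.
#' @export
compute_hold_times <- function(keystrokes) {
  ks <- as_keystrokes(keystrokes)
  ks$release_time - ks$press_time
}

#' Flight times of a session
#'
#' Flight time (FT) is the interval between releasing a key and pressing
#' the next key, in milliseconds: `FT_j = press_time_{j+1} -
#' release_time_j` over consecutive keystrokes sorted by press time.
#' Negative values arise under rollover typing (the next key goes down
#' before the previous comes up) and are retained. FT is only defined
#' within a session, never across session boundaries.
#'
#' @inheritParams compute_hold_times
#' @return Numeric vector of length `max(0, n_keystrokes - 1)`.
#' @export
compute_flight_times <- function(keystrokes) {
  ks <- as_keystrokes(keystrokes)
  n <- nrow(ks)
  if (n < 2) return(numeric(0))
  ks$press_time[-1] - ks$release_time[-n]
}

as_keystrokes <- function(x) {
  if (inherits(x, "typing_session")) x <- pair_events(x)
  if (!is.data.frame(x) || !all(c("press_time", "release_time") %in% names(x)))
    kd_validation_error("expected a keystroke data.frame or typing_session")
  x
}

#' Bundle raw HT/FT values into a feature set
#'
#' @param hold_times,flight_times numeric vectors, ms.
#' @param n_excluded_ht,n_excluded_ft counts of values already removed by
#'   preprocessing (zero for a raw set).
#' @return An object of class `kd_features`.
#' @export
feature_set <- function(hold_times, flight_times,
                        n_excluded_ht = 0L, n_excluded_ft = 0L) {
  structure(list(hold_times = as.numeric(hold_times),
                 flight_times = as.numeric(flight_times),
                 n_excluded_ht = as.integer(n_excluded_ht),
                 n_excluded_ft = as.integer(n_excluded_ft)),
            class = "kd_features")
}

#' @export
print.kd_features <- function(x, ...) {
  cat(sprintf("<kd_features: %d HT (%d excluded), %d FT (%d excluded)>\n",
              length(x$hold_times), x$n_excluded_ht,
              length(x$flight_times), x$n_excluded_ft))
  invisible(x)
}

#' Apply the preprocessing exclusion filters
#'
#' Removes implausible latencies: hold times strictly greater than
#' `ht_max_ms` (default 700 ms) and flight times strictly greater than
#' `ft_max_ms` (default 3000 ms, i.e. 3 s). Both rules are strict
#' inequalities, so boundary values are retained. Exclusion counts
#' accumulate across repeated application, and the operation is
#' idempotent. An optional lower FT bound can drop rollover values; by
#' default none is applied.
#'
#' @param features a `kd_features` object.
#' @param ht_max_ms,ft_max_ms upper exclusion thresholds, ms.
#' @param ft_min_ms optional lower FT bound (values strictly below are
#'   excluded); `NULL` (default) retains negative/rollover FT.
#' @return The filtered `kd_features` with updated exclusion counts.
#' @export
apply_preprocessing_filters <- function(features, ht_max_ms = 700,
                                        ft_max_ms = 3000, ft_min_ms = NULL) {
  stopifnot(inherits(features, "kd_features"))
  if (ht_max_ms <= 0 || ft_max_ms <= 0)
    kd_validation_error("filter thresholds must be positive")
  keep_ht <- features$hold_times <= ht_max_ms
  keep_ft <- features$flight_times <= ft_max_ms
  if (!is.null(ft_min_ms)) keep_ft <- keep_ft & features$flight_times >= ft_min_ms
  feature_set(features$hold_times[keep_ht],
              features$flight_times[keep_ft],
              features$n_excluded_ht + sum(!keep_ht),
              features$n_excluded_ft + sum(!keep_ft))
}

#' Retain sessions with enough key presses
#'
#' Sessions with more than 40 key presses (i.e. `n_presses >=
#' min_presses` with the default `min_presses = 41`) are retained, so
#' that each session carries enough data for a meaningful comparison.
#'
#' @param sessions list of [typing_session] objects.
#' @param min_presses minimum number of press events for retention
#'   (inclusive); the default 41 encodes the strict "more than 40" rule.
#' @return The retained sessions, with attribute `"retention"`: a list
#'   with `n_total`, `n_retained` and `retention_pct` (percent).
#' @export
filter_sessions <- function(sessions, min_presses = 41) {
  keep <- vapply(sessions, function(s) s$n_presses >= min_presses, logical(1))
  structure(sessions[keep], retention = list(
    n_total = length(sessions),
    n_retained = sum(keep),
    retention_pct = if (length(sessions)) 100 * sum(keep) / length(sessions) else NA_real_))
}

#' Aggregate one participant's sessions into feature means
#'
#' Runs the per-participant tail of the pipeline: session retention,
#' pairing, HT/FT computation, value filters, then aggregation. The
#' default aggregation is the pooled keystroke-level mean across all the
#' participant's retained sessions (weighting sessions by keystroke
#' count); `"session_mean"` instead averages per-session means.
#'
#' @param sessions list of [typing_session] objects, all belonging to one
#'   participant.
#' @param participant_id identifier for the output row; defaults to the
#'   id carried by the sessions.
#' @param aggregation `"pooled"` (default) or `"session_mean"`.
#' @param ht_max_ms,ft_max_ms,ft_min_ms value filters, see
#'   [apply_preprocessing_filters()].
#' @param min_presses session filter, see [filter_sessions()].
#' @return One-row data.frame with columns `participant_id`,
#'   `mean_ht_ms`, `mean_ft_ms`, `n_sessions_total`, `n_sessions_retained`,
#'   `n_keystrokes`, `n_excluded_ht`, `n_excluded_ft`, `no_data`. A
#'   participant with zero retained keystrokes is flagged `no_data = TRUE`
#'   with `NA` means, to be excluded from downstream analysis.
#' @export
aggregate_participant <- function(sessions, participant_id = NULL,
                                  aggregation = c("pooled", "session_mean"),
                                  ht_max_ms = 700, ft_max_ms = 3000,
                                  ft_min_ms = NULL, min_presses = 41) {
  aggregation <- match.arg(aggregation)
  if (is.null(participant_id))
    participant_id <- if (length(sessions)) sessions[[1]]$participant_id else NA_character_
  retained <- filter_sessions(sessions, min_presses)
  per_session <- lapply(retained, function(s) {
    ks <- pair_events(s)
    apply_preprocessing_filters(
      feature_set(compute_hold_times(ks), compute_flight_times(ks)),
      ht_max_ms = ht_max_ms, ft_max_ms = ft_max_ms, ft_min_ms = ft_min_ms)
  })
  ht_all <- lapply(per_session, `[[`, "hold_times")
  ft_all <- lapply(per_session, `[[`, "flight_times")
  n_ks <- sum(lengths(ht_all))
  mean_of <- function(lst) {
    vals <- unlist(lst, use.names = FALSE)
    if (!length(vals)) return(NA_real_)
    if (aggregation == "pooled") mean(vals)
    else mean(vapply(lst[lengths(lst) > 0], mean, numeric(1)))
  }
  data.frame(participant_id = participant_id,
             mean_ht_ms = mean_of(ht_all),
             mean_ft_ms = mean_of(ft_all),
             n_sessions_total = length(sessions),
             n_sessions_retained = length(retained),
             n_keystrokes = n_ks,
             n_excluded_ht = sum(vapply(per_session, `[[`, integer(1), "n_excluded_ht")),
             n_excluded_ft = sum(vapply(per_session, `[[`, integer(1), "n_excluded_ft")),
             no_data = n_ks == 0L,
             stringsAsFactors = FALSE)
}

#' Extract the participant feature table from a session list
#'
#' Applies [aggregate_participant()] to every participant present in a
#' mixed session list (the output of [parse_event_log()]).
#'
#' @param sessions list of [typing_session] objects, possibly spanning
#'   many participants.
#' @inheritParams aggregate_participant
#' @return data.frame with one row per participant (columns as in
#'   [aggregate_participant()]); attribute `"extraction_report"` carries
#'   the pooled session-retention summary and exclusion counts.
#' @export
extract_features <- function(sessions, aggregation = c("pooled", "session_mean"),
                             ht_max_ms = 700, ft_max_ms = 3000,
                             ft_min_ms = NULL, min_presses = 41) {
  aggregation <- match.arg(aggregation)
  pids <- vapply(sessions, `[[`, character(1), "participant_id")
  rows <- lapply(unique(pids), function(p)
    aggregate_participant(sessions[pids == p], participant_id = p,
                          aggregation = aggregation, ht_max_ms = ht_max_ms,
                          ft_max_ms = ft_max_ms, ft_min_ms = ft_min_ms,
                          min_presses = min_presses))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- aggregate_participant(list())[0, ]
  n_tot <- sum(out$n_sessions_total)
  n_ret <- sum(out$n_sessions_retained)
  structure(out, extraction_report = list(
    n_participants = nrow(out),
    n_participants_no_data = sum(out$no_data),
    n_sessions_total = n_tot,
    n_sessions_retained = n_ret,
    retention_pct = if (n_tot) 100 * n_ret / n_tot else NA_real_,
    n_excluded_ht = sum(out$n_excluded_ht),
    n_excluded_ft = sum(out$n_excluded_ft)))
}
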
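#' Construct a typing session
#'
#' A typing session is one uninterrupted episode of keyboard use by one
#' participant: an ordered stream of time-stamped press ("down") and
#' release ("up") events with opaque, anonymized key tokens. Flight times
#' are never computed across session boundaries.
#'
#' @param participant_id,session_id opaque tokens (length-1 character).
#' @param events data.frame with columns `t` (numeric, milliseconds since
#'   an arbitrary epoch, finite and non-negative), `action` (`"down"` or
#'   `"up"`) and `key` (character). Events are stably sorted by `t`.
#' @return An object of class `typing_session` with fields
#'   `participant_id`, `session_id`, `events` and `n_presses` (number of
#'   press events).
#' @export
typing_session <- function(participant_id, session_id, events) {
  if (!is.data.frame(events) || !all(c("t", "action", "key") %in% names(events)))
    kd_validation_error("'events' must have columns t, action, key")
  if (nrow(events)) {
    if (!is.numeric(events$t) || any(!is.finite(events$t)) || any(events$t < 0))
      kd_validation_error("event timestamps must be finite and non-negative")
    if (!all(events$action %in% c("down", "up")))
      kd_validation_error("event action must be 'down' or 'up'")
    events <- events[order(events$t), , drop = FALSE]  # stable sort
    rownames(events) <- NULL
  }
  structure(list(participant_id = as.character(participant_id),
                 session_id = as.character(session_id),
                 events = events,
                 n_presses = sum(events$action == "down")),
            class = "typing_session")
}

#' @export
print.typing_session <- function(x, ...) {
  cat(sprintf("<typing_session %s/%s: %d events, %d presses>\n",
              x$participant_id, x$session_id, nrow(x$events), x$n_presses))
  invisible(x)
}

empty_events <- function() {
  data.frame(t = numeric(0), action = character(0), key = character(0),
             stringsAsFactors = FALSE)
}

#' Parse a raw keystroke event log
#'
#' Reads an event-log file in either of two layouts: a JSON array of
#' session objects, or newline-delimited JSON (one session object per
#' line). Each session object has fields `participant_id`, `session_id`
#' and `events`, the latter an array of `{t, action, key}` records with
#' `action` one of `"down"`/`"up"`.
#'
#' Malformed event records (missing field, non-finite or negative
#' timestamp, unknown action) are rejected individually and counted;
#' session objects missing their identifiers are rejected whole. Events
#' arriving out of timestamp order are sorted, with a single summary
#' warning.
#'
#' @param path path to the event-log file.
#' @return A list of [typing_session] objects, grouped by participant
#'   (all sessions of a participant are contiguous, in order of first
#'   appearance). The attribute `"parse_report"` holds counts:
#'   `n_sessions`, `n_events`, `n_rejected_events`, `n_rejected_sessions`,
#'   `n_unsorted_sessions`.
#' @export
parse_event_log <- function(path) {
  if (!file.exists(path))
    kd_validation_error(sprintf("event log not found: %s", path))
  txt <- readLines(path, warn = FALSE)
  body <- trimws(paste(txt, collapse = "\n"))
  raw <- if (!nzchar(body)) {
    list()
  } else if (startsWith(body, "[")) {
    jsonlite::fromJSON(body, simplifyVector = FALSE)
  } else {
    lines <- txt[nzchar(trimws(txt))]
    lapply(lines, jsonlite::fromJSON, simplifyVector = FALSE)
  }

  n_rejected_events <- 0L
  n_rejected_sessions <- 0L
  n_unsorted <- 0L
  sessions <- list()
  for (obj in raw) {
    pid <- obj$participant_id
    sid <- obj$session_id
    if (is.null(pid) || is.null(sid) || !is.list(obj$events %||% list())) {
      n_rejected_sessions <- n_rejected_sessions + 1L
      next
    }
    ok <- vapply(obj$events, function(e) {
      !is.null(e$t) && !is.null(e$action) && !is.null(e$key) &&
        is.numeric(e$t) && is.finite(e$t) && e$t >= 0 &&
        is.character(e$action) && e$action %in% c("down", "up")
    }, logical(1))
    n_rejected_events <- n_rejected_events + sum(!ok)
    evs <- obj$events[ok]
    events <- if (length(evs)) {
      data.frame(t = vapply(evs, function(e) as.numeric(e$t), numeric(1)),
                 action = vapply(evs, function(e) e$action, character(1)),
                 key = vapply(evs, function(e) as.character(e$key), character(1)),
                 stringsAsFactors = FALSE)
    } else empty_events()
    if (nrow(events) > 1 && is.unsorted(events$t)) n_unsorted <- n_unsorted + 1L
    sessions[[length(sessions) + 1L]] <- typing_session(pid, sid, events)
  }
  if (n_unsorted > 0)
    warning(sprintf("%d session(s) had non-monotone timestamps; sorted", n_unsorted))

  # group by participant, preserving order of first appearance
  pids <- vapply(sessions, `[[`, character(1), "participant_id")
  sessions <- sessions[order(match(pids, unique(pids)))]
  structure(sessions,
            parse_report = list(
              n_sessions = length(sessions),
              n_events = sum(vapply(sessions, function(s) nrow(s$events), integer(1))),
              n_rejected_events = n_rejected_events,
              n_rejected_sessions = n_rejected_sessions,
              n_unsorted_sessions = n_unsorted))
}

#' Pair press and release events into keystrokes
#'
#' Matches each press ("down") event to the earliest subsequent release
#' ("up") event carrying the same key token (first-in-first-out per key),
#' so that rollover typing — pressing the next key before releasing the
#' previous one — is preserved. Unmatched presses and releases are
#' dropped and counted.
#'
#' @param events a data.frame of raw events (`t`, `action`, `key`) sorted
#'   by timestamp, or a [typing_session].
#' @return A data.frame of keystrokes with columns `press_time`,
#'   `release_time`, `key_id`, sorted by `press_time`; invariant
#'   `release_time >= press_time` holds row-wise. The attribute
#'   `"pairing_report"` counts `n_press_events`, `n_release_events`,
#'   `n_pairs`, `n_orphan_presses`, `n_orphan_releases`; pairing conserves
#'   events: `n_pairs + n_orphan_presses == n_press_events`.
#' @export
pair_events <- function(events) {
  if (inherits(events, "typing_session")) events <- events$events
  press_t <- numeric(0); release_t <- numeric(0); key_id <- character(0)
  n_orphan_press <- 0L; n_orphan_release <- 0L
  n_down <- sum(events$action == "down")
  n_up <- sum(events$action == "up")
  if (nrow(events)) {
    for (k in unique(events$key)) {
      ke <- events[events$key == k, , drop = FALSE]
      pt <- ke$t[ke$action == "down"]
      rt <- ke$t[ke$action == "up"]
      j <- 1L
      for (p in pt) {
        # releases strictly before this press can never match it, nor any
        # later press of the same key (presses are in time order): orphans
        while (j <= length(rt) && rt[j] < p) {
          n_orphan_release <- n_orphan_release + 1L
          j <- j + 1L
        }
        if (j <= length(rt)) {
          press_t <- c(press_t, p); release_t <- c(release_t, rt[j])
          key_id <- c(key_id, k)
          j <- j + 1L
        } else {
          n_orphan_press <- n_orphan_press + 1L
        }
      }
      n_orphan_release <- n_orphan_release + max(0L, length(rt) - j + 1L)
    }
  }
  ks <- data.frame(press_time = press_t, release_time = release_t,
                   key_id = key_id, stringsAsFactors = FALSE)
  ks <- ks[order(ks$press_time), , drop = FALSE]
  rownames(ks) <- NULL
  structure(ks, pairing_report = list(
    n_press_events = n_down, n_release_events = n_up,
    n_pairs = nrow(ks), n_orphan_presses = n_orphan_press,
    n_orphan_releases = n_orphan_release))
}
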
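# fixture builders shared across test files; everything is generated in
# code, nothing is read from disk

ev <- function(t, action, key = "A") {
  data.frame(t = t, action = action, key = rep_len(key, length(t)),
             stringsAsFactors = FALSE)
}

events_df <- function(...) do.call(rbind, list(...))

# build a session from paired keystroke times (interleaves down/up events)
session_from_ks <- function(press, release, keys = NULL,
                            pid = "p1", sid = "s1") {
  n <- length(press)
  keys <- keys %||% sprintf("k%02d", seq_len(n))
  typing_session(pid, sid, data.frame(
    t = c(rbind(press, release)),
    action = rep(c("down", "up"), n),
    key = rep(keys, each = 2),
    stringsAsFactors = FALSE))
}

# minimal stub carrying only a press count (filter_sessions uses nothing
# else); cheaper than materializing thousands of event frames
counted_session_stub <- function(n_presses, pid = "p", sid = "s") {
  structure(list(participant_id = pid, session_id = sid,
                 events = NULL, n_presses = n_presses),
            class = "typing_session")
}

# random raw event stream (not guaranteed well-paired) for property tests
random_event_stream <- function(n, seed) {
  set.seed(seed)
  data.frame(t = sort(sample.int(10 * n, n)),
             action = sample(c("down", "up"), n, replace = TRUE,
                             prob = c(0.55, 0.45)),
             key = sample(LETTERS[1:4], n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# brute-force all-pairs concordance AUC (ties count 1/2): the oracle the
# trapezoidal ROC must reproduce
bruteforce_auc <- function(pos, neg) {
  s <- 0
  for (x in pos) for (y in neg) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(pos) * length(neg))
}

# exhaustive Youden search over the midpoint threshold set, independent
# of the package's ROC representation
bruteforce_youden <- function(pos, neg) {
  v <- sort(unique(c(pos, neg)))
  thr <- c(v[1] - 1, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
           v[length(v)] + 1)
  j <- vapply(thr, function(t) mean(pos > t) + mean(neg <= t) - 1, numeric(1))
  max(j)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pooled-calibrated default config is expensive (~1 s); compute once per run
.kd_cache <- new.env(parent = emptyenv())
calibrated_default_config <- function() {
  if (is.null(.kd_cache$cfg))
    .kd_cache$cfg <- suppressMessages(calibrate_cohort_config(cohort_config()))
  .kd_cache$cfg
}
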
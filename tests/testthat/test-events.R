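test_that("parse_event_log reads JSON-array and NDJSON logs", {
  sessions <- list(
    session_from_ks(c(0, 150), c(120, 260), pid = "pA", sid = "s1"),
    session_from_ks(1000, 1120, pid = "pB", sid = "s1"),
    session_from_ks(2000, 2050, pid = "pA", sid = "s2"))
  for (fmt in c("json", "ndjson")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_event_log(sessions, path, format = fmt)
    parsed <- parse_event_log(path)
    expect_length(parsed, 3)
    # grouped by participant: pA's two sessions are contiguous
    pids <- vapply(parsed, `[[`, character(1), "participant_id")
    expect_equal(pids, c("pA", "pA", "pB"))
    rep <- attr(parsed, "parse_report")
    expect_equal(rep$n_events, 8)
    expect_equal(rep$n_rejected_events, 0)
  }
})

test_that("empty file parses to an empty session list", {
  path <- withr::local_tempfile()
  writeLines("", path)
  parsed <- parse_event_log(path)
  expect_length(parsed, 0)
  expect_equal(attr(parsed, "parse_report")$n_sessions, 0)
})

test_that("one session with a single press/release pair yields one keystroke", {
  path <- withr::local_tempfile()
  writeLines(paste0('[{"participant_id":"p1","session_id":"s1",',
                    '"events":[{"t":0,"action":"down","key":"A"},',
                    '{"t":120,"action":"up","key":"A"}]}]'), path)
  parsed <- parse_event_log(path)
  expect_length(parsed, 1)
  ks <- pair_events(parsed[[1]])
  expect_equal(nrow(ks), 1)
  expect_equal(ks$press_time, 0)
  expect_equal(ks$release_time, 120)
})

test_that("malformed records are rejected individually and counted", {
  # 10 event records, one lacks its timestamp
  good <- paste(sprintf('{"t":%d,"action":"%s","key":"A"}',
                        seq(0, 160, by = 20),
                        rep(c("down", "up"), length.out = 9)),
                collapse = ",")
  bad <- '{"action":"down","key":"A"}'
  path <- withr::local_tempfile()
  writeLines(sprintf('[{"participant_id":"p1","session_id":"s1","events":[%s]}]',
                     paste(c(good, bad), collapse = ",")), path)
  parsed <- parse_event_log(path)
  rep <- attr(parsed, "parse_report")
  expect_equal(rep$n_events, 9)
  expect_equal(rep$n_rejected_events, 1)
})

test_that("non-monotone timestamps are sorted with a warning", {
  path <- withr::local_tempfile()
  writeLines(paste0('[{"participant_id":"p1","session_id":"s1",',
                    '"events":[{"t":120,"action":"up","key":"A"},',
                    '{"t":0,"action":"down","key":"A"}]}]'), path)
  expect_warning(parsed <- parse_event_log(path), "non-monotone")
  expect_equal(parsed[[1]]$events$t, c(0, 120))
})

test_that("missing file is a fatal validation error", {
  expect_error(parse_event_log("/nonexistent/events.json"),
               class = "kd_validation_error")
})

test_that("pair_events matches presses to earliest subsequent same-key release", {
  expect_equal(nrow(pair_events(ev(numeric(0), character(0)))), 0)

  simple <- events_df(ev(0, "down", "A"), ev(120, "up", "A"))
  expect_equal(pair_events(simple)$release_time, 120)

  # rollover: B goes down before A comes up
  roll <- events_df(ev(0, "down", "A"), ev(150, "down", "B"),
                    ev(200, "up", "A"), ev(260, "up", "B"))
  ks <- pair_events(roll)
  expect_equal(ks$key_id, c("A", "B"))
  expect_equal(ks$press_time, c(0, 150))
  expect_equal(ks$release_time, c(200, 260))

  # FIFO within a repeated key
  rep2 <- events_df(ev(0, "down", "A"), ev(10, "down", "A"),
                    ev(20, "up", "A"), ev(30, "up", "A"))
  ks2 <- pair_events(rep2)
  expect_equal(ks2$release_time, c(20, 30))
})

test_that("orphan events are dropped and counted", {
  evs <- events_df(ev(5, "up", "A"),          # release before any press
                   ev(10, "down", "A"), ev(20, "up", "A"),
                   ev(30, "down", "B"))        # press never released
  ks <- pair_events(evs)
  rep <- attr(ks, "pairing_report")
  expect_equal(nrow(ks), 1)
  expect_equal(rep$n_orphan_presses, 1)
  expect_equal(rep$n_orphan_releases, 1)
})

test_that("pairing conserves press events on random streams", {
  for (seed in 1:25) {
    evs <- random_event_stream(60, seed)
    rep <- attr(pair_events(evs), "pairing_report")
    expect_equal(rep$n_pairs + rep$n_orphan_presses, rep$n_press_events)
    expect_equal(rep$n_pairs + rep$n_orphan_releases, rep$n_release_events)
  }
})

test_that("extraction is stable under permutation of event records", {
  for (seed in 1:10) {
    evs <- random_event_stream(40, seed)
    sess <- typing_session("p", "s", evs)
    set.seed(seed + 1000)
    perm <- typing_session("p", "s", evs[sample.int(nrow(evs)), ])
    expect_equal(pair_events(sess), pair_events(perm),
                 ignore_attr = "pairing_report")
    expect_equal(compute_hold_times(sess), compute_hold_times(perm))
    expect_equal(compute_flight_times(sess), compute_flight_times(perm))
  }
})
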
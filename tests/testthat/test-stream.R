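test_that("degenerate noise reproduces the latent means up to rounding", {
  set.seed(50)
  st <- stream_config(within_participant_cv = 0, ht_outlier_rate = 0,
                      ft_outlier_rate = 0, presses_mean = 30,
                      presses_dispersion = NA)
  ss <- generate_event_stream("p", 150, 600, st, n_sessions = 2)
  ht <- unlist(lapply(ss, compute_hold_times))
  ft <- unlist(lapply(ss, compute_flight_times))
  expect_length(ht, 60)
  expect_true(all(abs(ht - 150) <= 1))   # integer-ms rounding only
  expect_true(all(abs(ft - 600) <= 1))
})

test_that("configured sessions and presses are conserved in the event count", {
  set.seed(51)
  st <- stream_config(presses_mean = 50, presses_dispersion = NA)
  ss <- generate_event_stream("p", 120, 500, st, n_sessions = 10)
  expect_length(ss, 10)
  for (s in ss) {
    expect_equal(s$n_presses, 50)
    expect_equal(sum(s$events$action == "up"), 50)
    expect_equal(nrow(pair_events(s)), 50)
  }
  # flight times never span sessions: n - 1 per session, not n*k - 1 pooled
  expect_equal(sum(lengths(lapply(ss, compute_flight_times))), 10 * 49)
})

test_that("outlier injection hits its configured rate", {
  set.seed(52)
  st <- stream_config(ht_outlier_rate = 0.05, ft_outlier_rate = 0.03,
                      presses_mean = 100, presses_dispersion = NA,
                      within_participant_cv = 0.2)
  ss <- generate_event_stream("p", 150, 700, st, n_sessions = 100)
  ht <- unlist(lapply(ss, compute_hold_times))
  ft <- unlist(lapply(ss, compute_flight_times))
  expect_equal(mean(ht > 700), 0.05, tolerance = 0.2)  # +-0.01 absolute
  expect_equal(mean(ft > 3000), 0.03, tolerance = 0.34)
  expect_true(all(ht[ht > 700] <= 1400))
  expect_true(all(ft[ft > 3000] <= 10000))
})

test_that("stream validation rejects impossible parameters", {
  expect_error(generate_event_stream("p", -5, 600), class = "kd_validation_error")
  expect_error(stream_config(ht_outlier_rate = 1), class = "kd_validation_error")
  expect_error(stream_config(within_participant_cv = -1),
               class = "kd_validation_error")
})

small_cfg <- function(seed = 1) {
  cohort_config(hc = hc_reference(n = 4), mci = mci_reference(n = 3),
                calibration = "within_group",
                stream = stream_config(sessions_mean = 3, presses_mean = 60),
                seed = seed)
}

test_that("simulate_study writes byte-identical files for identical seeds", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- simulate_study(small_cfg(), d1, seed = 7)
  r2 <- simulate_study(small_cfg(), d2, seed = 7)
  for (f in c("events", "metadata", "truth")) {
    expect_identical(unname(tools::md5sum(r1[[f]])), unname(tools::md5sum(r2[[f]])))
  }
  d3 <- withr::local_tempdir()
  r3 <- simulate_study(small_cfg(), d3, seed = 8)
  expect_false(identical(unname(tools::md5sum(r1$events)),
                         unname(tools::md5sum(r3$events))))
})

test_that("round trip: extraction recovers latent means within MC tolerance", {
  set.seed(60)
  cfg <- cohort_config(hc = hc_reference(n = 5), mci = mci_reference(n = 5),
                       calibration = "within_group",
                       stream = stream_config(sessions_mean = 8,
                                              sessions_dispersion = NA,
                                              presses_mean = 80,
                                              presses_dispersion = NA,
                                              within_participant_cv = 0.35,
                                              ht_outlier_rate = 0,
                                              ft_outlier_rate = 0))
  d <- withr::local_tempdir()
  res <- simulate_study(cfg, d, seed = 60)
  feats <- extract_features(parse_event_log(res$events))
  m <- merge(res$cohort, feats, by = "participant_id",
             suffixes = c("_latent", "_extracted"))
  n_ht <- m$n_keystrokes
  z_ht <- (m$mean_ht_ms_extracted - m$mean_ht_ms_latent) /
    (m$mean_ht_ms_latent * 0.35 / sqrt(n_ht))
  z_ft <- (m$mean_ft_ms_extracted - m$mean_ft_ms_latent) /
    (m$mean_ft_ms_latent * 0.35 / sqrt(n_ht - m$n_sessions_retained))
  z <- c(z_ht, z_ft)
  # individually ~N(0,1): all well-behaved, the bulk inside +-2 SE
  expect_true(all(abs(z) < 4))
  expect_gte(mean(abs(z) < 2), 0.8)
})

test_that("filters pull contaminated streams back toward the latent truth", {
  set.seed(61)
  st <- stream_config(sessions_mean = 10, sessions_dispersion = NA,
                      presses_mean = 80, presses_dispersion = NA,
                      ht_outlier_rate = 0.08, ft_outlier_rate = 0.08)
  ss <- generate_event_stream("p", 150, 600, st)
  filtered <- aggregate_participant(ss, min_presses = 1)
  raw <- aggregate_participant(ss, min_presses = 1,
                               ht_max_ms = 1e9, ft_max_ms = 1e9)
  expect_lt(abs(filtered$mean_ht_ms - 150), abs(raw$mean_ht_ms - 150))
  expect_lt(abs(filtered$mean_ft_ms - 600), abs(raw$mean_ft_ms - 600))
})
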
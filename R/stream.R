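#' Event-stream generation model
#'
#' Generative model for raw keystroke event streams around a
#' participant's latent mean HT and FT. Session and press counts are
#' negative-binomial (dispersion `d` means variance `mu (1 + d mu)`,
#' i.e. NB size `1/d`; dispersion 0 degenerates to Poisson).
#' Per-keystroke latencies are gamma around the participant mean with a
#' fixed coefficient of variation — positive and right-skewed, as typing
#' latencies are. A configurable fraction of keystrokes is replaced by
#' outliers beyond the preprocessing thresholds: HT uniform on
#' (700, 1400\] ms, FT uniform on (3000, 10000\] ms.
#'
#' Defaults: 32 sessions per participant (dispersion 0.3) and 120
#' presses per session with dispersion 0.7342, calibrated so that the
#' probability of a session exceeding 40 presses is 77.6%, the retention
#' rate the analysis pipeline is designed around; CV 0.35; outlier rates
#' 0.02.
#'
#' @param sessions_mean,sessions_dispersion negative-binomial session
#'   count per participant (`dispersion = NA` fixes the count at
#'   `round(mean)`, `0` gives Poisson).
#' @param presses_mean,presses_dispersion negative-binomial press count
#'   per session (same conventions).
#' @param within_participant_cv coefficient of variation of per-keystroke
#'   HT and FT around the participant mean.
#' @param ht_outlier_rate,ft_outlier_rate per-keystroke probabilities in
#'   \[0, 1) of substituting an out-of-range value.
#' @param ft_shift_ms shift of the FT gamma (a draw `G` with mean
#'   `mean_ft + ft_shift_ms` yields `FT = G - ft_shift_ms`), allowing a
#'   rollover (negative-FT) fraction; default 0 (no rollover generated).
#' @return Object of class `kd_stream_config`.
#' @export
stream_config <- function(sessions_mean = 32, sessions_dispersion = 0.3,
                          presses_mean = 120, presses_dispersion = 0.7342,
                          within_participant_cv = 0.35,
                          ht_outlier_rate = 0.02, ft_outlier_rate = 0.02,
                          ft_shift_ms = 0) {
  rates <- c(ht_outlier_rate, ft_outlier_rate)
  if (any(rates < 0) || any(rates >= 1))
    kd_validation_error("outlier rates must be in [0, 1)")
  if (sessions_mean < 0 || presses_mean < 0)
    kd_validation_error("counts must be >= 0")
  if (within_participant_cv < 0)
    kd_validation_error("within_participant_cv must be >= 0")
  structure(list(sessions_mean = sessions_mean,
                 sessions_dispersion = sessions_dispersion,
                 presses_mean = presses_mean,
                 presses_dispersion = presses_dispersion,
                 within_participant_cv = within_participant_cv,
                 ht_outlier_rate = ht_outlier_rate,
                 ft_outlier_rate = ft_outlier_rate,
                 ft_shift_ms = ft_shift_ms),
            class = "kd_stream_config")
}

draw_count <- function(n, mean, dispersion) {
  if (mean == 0) return(integer(n))
  if (is.na(dispersion)) return(rep(round(mean), n))  # degenerate: fixed count
  if (dispersion <= 0) stats::rpois(n, mean)
  else stats::rnbinom(n, size = 1 / dispersion, mu = mean)
}

# gamma with given mean and CV; CV 0 degenerates to the constant mean
rgamma_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, scale = mean / shape)
}

#' Generate raw keystroke event streams for one participant
#'
#' Builds typing sessions keystroke by keystroke: per session a press
#' count is drawn, per keystroke HT (and between keystrokes FT) is drawn
#' from the stream model around the participant's latent means, outliers
#' are injected, and timestamps are accumulated
#' (`press_{j+1} = release_j + FT_j`, `release_j = press_j + HT_j`,
#' rounded to integer ms). Press and release events are emitted
#' interleaved in time order. Sessions are spaced an hour apart so
#' timestamps never collide; flight times never span sessions.
#'
#' Draws are taken from the current RNG state; seed at the study level
#' (see [simulate_study()]) for reproducibility.
#'
#' @param participant_id token for the emitted sessions.
#' @param mean_ht_ms,mean_ft_ms latent participant means, ms (> 0).
#' @param stream a [stream_config].
#' @param n_sessions session count; drawn from the stream model when
#'   `NULL`.
#' @param start_time_ms epoch offset of the first session.
#' @return List of [typing_session] objects (possibly empty).
#' @export
generate_event_stream <- function(participant_id, mean_ht_ms, mean_ft_ms,
                                  stream = stream_config(),
                                  n_sessions = NULL, start_time_ms = 0) {
  stopifnot(inherits(stream, "kd_stream_config"))
  if (mean_ht_ms <= 0 || mean_ft_ms <= 0)
    kd_validation_error("latent means must be positive")
  if (is.null(n_sessions))
    n_sessions <- draw_count(1, stream$sessions_mean, stream$sessions_dispersion)
  cv <- stream$within_participant_cv
  shift <- stream$ft_shift_ms
  sessions <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    start <- start_time_ms + (s - 1) * 3.6e6
    np <- draw_count(1, stream$presses_mean, stream$presses_dispersion)
    if (np == 0) {
      sessions[[s]] <- typing_session(participant_id,
                                      sprintf("%s-s%04d", participant_id, s),
                                      empty_events())
      next
    }
    ht <- rgamma_mean_cv(np, mean_ht_ms, cv)
    if (stream$ht_outlier_rate > 0) {
      out <- stats::runif(np) < stream$ht_outlier_rate
      ht[out] <- stats::runif(sum(out), 700, 1400)
    }
    ft <- numeric(0)
    if (np > 1) {
      ft <- rgamma_mean_cv(np - 1, mean_ft_ms + shift, cv) - shift
      if (stream$ft_outlier_rate > 0) {
        out <- stats::runif(np - 1) < stream$ft_outlier_rate
        ft[out] <- stats::runif(sum(out), 3000, 10000)
      }
    }
    press <- start + c(0, cumsum(ht[-np] + ft))
    release <- press + ht
    events <- data.frame(
      t = round(c(rbind(press, release))),
      action = rep(c("down", "up"), np),
      key = rep(sprintf("k%02d", sample.int(30, np, replace = TRUE)), each = 2),
      stringsAsFactors = FALSE)
    events <- events[order(events$t), , drop = FALSE]
    sessions[[s]] <- typing_session(participant_id,
                                    sprintf("%s-s%04d", participant_id, s),
                                    events)
  }
  sessions
}

#' Simulate a full study: cohort, event streams and files
#'
#' Generates a cohort from `config`, a raw event stream per participant,
#' and writes three text artifacts to `dir`: the event log
#' (`events.json` or `events.ndjson`), the participant metadata table
#' (`metadata.csv`: demographics and cognitive scores, no keystroke
#' columns — those are the extractor's job), the latent truth table
#' (`latent_truth.csv`, for validation), and a `manifest.json` recording
#' the seed, an md5 hash of the configuration and row/session counts.
#' Identical config and seed produce byte-identical files.
#'
#' @param config a [cohort_config].
#' @param dir output directory (created if missing).
#' @param format `"json"` (single array) or `"ndjson"` (one session
#'   object per line).
#' @param seed overrides `config$seed`.
#' @return Invisibly, a list of the written paths plus the cohort and
#'   session count.
#' @export
simulate_study <- function(config, dir, format = c("json", "ndjson"),
                           seed = config$seed) {
  format <- match.arg(format)
  stopifnot(inherits(config, "kd_cohort_config"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    kd_validation_error(sprintf("cannot create output directory: %s", dir))
  config <- calibrate_cohort_config(config)
  cohort <- generate_cohort(config, seed = seed)  # seeds the RNG
  sessions <- list()
  for (i in seq_len(nrow(cohort))) {
    sessions <- c(sessions, generate_event_stream(
      cohort$participant_id[i], cohort$mean_ht_ms[i], cohort$mean_ft_ms[i],
      stream = config$stream))
  }
  ev_path <- file.path(dir, paste0("events.", if (format == "json") "json" else "ndjson"))
  write_event_log(sessions, ev_path, format = format)

  meta_cols <- c("participant_id", "group", "age", "sex", "education_years",
                 "mmse_k", "moca_k", "cbt_accuracy")
  meta_path <- file.path(dir, "metadata.csv")
  write.csv(cohort[, meta_cols], meta_path, row.names = FALSE, quote = FALSE)
  truth_path <- file.path(dir, "latent_truth.csv")
  write.csv(cohort[, c("participant_id", "group", "mean_ht_ms", "mean_ft_ms",
                       "latent_ht_ms", "latent_ft_ms")],
            truth_path, row.names = FALSE, quote = FALSE)

  cfg_json <- jsonlite::toJSON(config_as_list(config), auto_unbox = TRUE,
                               digits = NA)
  manifest <- list(seed = seed,
                   config_md5 = md5_of_string(as.character(cfg_json)),
                   package_version = as.character(utils::packageVersion("keydyn")),
                   n_participants = nrow(cohort),
                   n_sessions = length(sessions),
                   files = basename(c(ev_path, meta_path, truth_path)))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(events = ev_path, metadata = meta_path, truth = truth_path,
                 manifest = manifest_path, cohort = cohort,
                 n_sessions = length(sessions)))
}

config_as_list <- function(config) {
  list(hc = unclass(config$hc), mci = unclass(config$mci),
       target_spearman = config$target_spearman,
       calibration = config$calibration,
       stream = unclass(config$stream), seed = config$seed)
}

md5_of_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}
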
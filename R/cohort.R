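#' Group-level marginal parameters
#'
#' Per-group participant-level marginals for the variables the cohort
#' generator emulates. Defaults are supplied by [hc_reference()] and
#' [mci_reference()], which carry the published healthy-control and MCI
#' group summaries.
#'
#' @param n number of participants (>= 1).
#' @param means,sds named numeric vectors over `moca_k`, `cbt`, `ht`,
#'   `ft`, `mmse_k`, `age`, `education` (CBT is an accuracy proportion,
#'   HT/FT in ms, instruments in points, age/education in years).
#' @param sex_fraction_male proportion of male participants in \[0, 1\].
#' @return Object of class `kd_group_params`.
#' @export
group_params <- function(n, means, sds, sex_fraction_male) {
  vars <- c("moca_k", "cbt", "ht", "ft", "mmse_k", "age", "education")
  if (!all(vars %in% names(means)) || !all(vars %in% names(sds)))
    kd_validation_error(paste("means/sds must name:", paste(vars, collapse = ", ")))
  if (n < 1) kd_validation_error("n must be >= 1")
  if (any(sds[vars] < 0)) kd_validation_error("sds must be non-negative")
  if (sex_fraction_male < 0 || sex_fraction_male > 1)
    kd_validation_error("sex_fraction_male must be in [0, 1]")
  structure(list(n = as.integer(n), means = means[vars], sds = sds[vars],
                 sex_fraction_male = sex_fraction_male),
            class = "kd_group_params")
}

#' @rdname group_params
#' @export
hc_reference <- function(n = 64) {
  group_params(n,
    means = c(moca_k = 25.83, cbt = 0.773, ht = 108.77, ft = 622.925,
              mmse_k = 26.86, age = 75.52, education = 6.48),
    sds = c(moca_k = 2.11, cbt = 0.06, ht = 25.25, ft = 135.14,
            mmse_k = 1.39, age = 7.00, education = 4.41),
    sex_fraction_male = 30 / 64)
}

#' @rdname group_params
#' @export
mci_reference <- function(n = 47) {
  group_params(n,
    means = c(moca_k = 22.77, cbt = 0.687, ht = 184.85, ft = 1351.51,
              mmse_k = 26.55, age = 74.45, education = 6.34),
    sds = c(moca_k = 2.26, cbt = 0.07, ht = 25.24, ft = 242.75,
            mmse_k = 1.15, age = 6.98, education = 4.81),
    sex_fraction_male = 21 / 47)
}

#' Default pooled Spearman dependence targets
#'
#' The published pooled-sample rank-correlation structure of MoCA-K, CBT
#' accuracy, hold time and flight time (the Results-section values; the
#' FT-by-MoCA-K entry is -.491).
#'
#' @return Symmetric 4x4 matrix over `moca_k`, `cbt`, `ht`, `ft`.
#' @export
spearman_targets_default <- function() {
  v <- c("moca_k", "cbt", "ht", "ft")
  m <- diag(1, 4); dimnames(m) <- list(v, v)
  m["moca_k", "cbt"] <- m["cbt", "moca_k"] <- 0.302
  m["moca_k", "ht"] <- m["ht", "moca_k"] <- -0.468
  m["moca_k", "ft"] <- m["ft", "moca_k"] <- -0.491
  m["cbt", "ht"] <- m["ht", "cbt"] <- -0.487
  m["cbt", "ft"] <- m["ft", "cbt"] <- -0.492
  m["ht", "ft"] <- m["ft", "ht"] <- 0.733
  m
}

#' Full generative specification of a synthetic cohort
#'
#' Binds the two group marginals, the rank-correlation targets, the
#' event-stream model and a seed into one reproducible configuration:
#' identical config and seed give identical output.
#'
#' @param hc,mci [group_params] for the two groups.
#' @param target_spearman symmetric Spearman target matrix over
#'   `moca_k`, `cbt`, `ht`, `ft` (see [spearman_targets_default()]).
#' @param calibration `"pooled"` (default) calibrates the latent
#'   correlation so the pooled-sample Spearman matches the targets (what
#'   two-group study tables report); `"within_group"` applies the plain
#'   copula identity within each group instead.
#' @param stream a [stream_config] for raw event-stream generation.
#' @param seed integer seed.
#' @return Object of class `kd_cohort_config`.
#' @export
cohort_config <- function(hc = hc_reference(), mci = mci_reference(),
                          target_spearman = spearman_targets_default(),
                          calibration = c("pooled", "within_group"),
                          stream = stream_config(), seed = 1L) {
  calibration <- match.arg(calibration)
  stopifnot(inherits(hc, "kd_group_params"), inherits(mci, "kd_group_params"))
  if (!isSymmetric(unname(target_spearman)) || any(abs(target_spearman) > 1))
    kd_validation_error("target_spearman must be symmetric with |r| <= 1")
  structure(list(hc = hc, mci = mci, target_spearman = target_spearman,
                 calibration = calibration, stream = stream,
                 seed = as.integer(seed), latent_pearson = NULL),
            class = "kd_cohort_config")
}

#' Calibrate a cohort configuration
#'
#' Computes and caches the latent Pearson correlation matrix implied by
#' the configuration's Spearman targets (an O(seconds) step worth
#' sharing across replicate cohorts).
#'
#' @param config a [cohort_config].
#' @return The config with `latent_pearson` filled in.
#' @export
calibrate_cohort_config <- function(config) {
  stopifnot(inherits(config, "kd_cohort_config"))
  if (!is.null(config$latent_pearson)) return(config)
  vars <- colnames(config$target_spearman)
  config$latent_pearson <- if (config$calibration == "pooled") {
    w <- c(config$hc$n, config$mci$n)
    calibrate_pooled_copula(
      config$target_spearman,
      means = rbind(config$hc$means[vars], config$mci$means[vars]),
      sds = rbind(config$hc$sds[vars], config$mci$sds[vars]),
      weights = w / sum(w))
  } else {
    calibrate_copula(config$target_spearman)
  }
  config
}

#' Generate a synthetic participant cohort
#'
#' Draws, per group, latent standard-normal vectors with the calibrated
#' correlation, transforms each coordinate to its group marginal
#' (normal with the configured mean/SD), then applies instrument
#' realism: MoCA-K and MMSE-K are rounded to integers and clipped to
#' \[0, 30\] (instruments are integer-scored, so ties occur downstream),
#' CBT accuracy is clipped to \[0, 1\], HT/FT are truncated below at
#' 1 ms. Age, education and MMSE-K are drawn independently of the copula
#' block. Sex is assigned by the group's male fraction.
#'
#' @param config a [cohort_config] (calibrated on the fly if needed).
#' @param seed overrides `config$seed`.
#' @return data.frame, one row per participant (HC block first):
#'   `participant_id`, `group` (`"HC"`/`"MCI"`), `age`, `sex`,
#'   `education_years`, `mmse_k`, `moca_k`, `cbt_accuracy`,
#'   `mean_ht_ms`, `mean_ft_ms` plus the untruncated latent values
#'   `latent_ht_ms`, `latent_ft_ms`.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  config <- calibrate_cohort_config(config)
  set.seed(seed)
  vars <- colnames(config$target_spearman)
  L <- chol(config$latent_pearson)
  draw_group <- function(gp, label, id_offset) {
    n <- gp$n
    z <- matrix(stats::rnorm(n * length(vars)), n) %*% L
    colnames(z) <- vars
    lat <- sweep(sweep(z, 2, gp$sds[vars], "*"), 2, gp$means[vars], "+")
    data.frame(
      participant_id = sprintf("P%04d", id_offset + seq_len(n)),
      group = label,
      age = gp$means["age"] + gp$sds["age"] * stats::rnorm(n),
      sex = ifelse(stats::rbinom(n, 1, gp$sex_fraction_male) == 1, "M", "F"),
      education_years = gp$means["education"] + gp$sds["education"] * stats::rnorm(n),
      mmse_k = pmin(30, pmax(0, round(gp$means["mmse_k"] + gp$sds["mmse_k"] * stats::rnorm(n)))),
      moca_k = pmin(30, pmax(0, round(lat[, "moca_k"]))),
      cbt_accuracy = pmin(1, pmax(0, lat[, "cbt"])),
      mean_ht_ms = pmax(1, lat[, "ht"]),
      mean_ft_ms = pmax(1, lat[, "ft"]),
      latent_ht_ms = lat[, "ht"],
      latent_ft_ms = lat[, "ft"],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  rbind(draw_group(config$hc, "HC", 0L),
        draw_group(config$mci, "MCI", config$hc$n))
}
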
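#' Default marker panel
#'
#' The five-row panel of a keystroke-dynamics screening study: the
#' cognitive score alone (lower score calls MCI), hold time and flight
#' time alone (higher calls MCI), and each keystroke feature fused with
#' the cognitive score through a logistic predicted probability (higher
#' probability calls MCI).
#'
#' @return List of panel entries (`name`, `vars`, `direction`).
#' @export
default_panel <- function() {
  list(
    list(name = "MoCA-K", vars = "moca_k", direction = "lower_is_positive"),
    list(name = "HT (ms)", vars = "mean_ht_ms", direction = "higher_is_positive"),
    list(name = "FT (ms)", vars = "mean_ft_ms", direction = "higher_is_positive"),
    list(name = "MoCA-K + HT", vars = c("moca_k", "mean_ht_ms"),
         direction = "higher_is_positive"),
    list(name = "MoCA-K + FT", vars = c("moca_k", "mean_ft_ms"),
         direction = "higher_is_positive"))
}

#' Evaluate a panel of markers against the group label
#'
#' For each panel entry computes the empirical ROC, AUC with confidence
#' interval, and the Youden-optimal cutoff with its sensitivity and
#' specificity. Entries with more than one variable are first fused into
#' a single predicted probability via [fit_logistic_combiner()]; their
#' cutoff is then on the probability scale.
#'
#' @param records analysis data.frame with a `group` column and the
#'   marker columns named by the panel.
#' @param panel list of panel entries as in [default_panel()].
#' @param positive positive class label (default `"MCI"`).
#' @param ci_method,level passed to [auc_confidence_interval()].
#' @param ridge passed to [fit_logistic_combiner()] for fused entries.
#' @return data.frame of class `kd_panel`, one row per entry: `marker`,
#'   `auc`, `auc_ci_low`, `auc_ci_high`, `cutoff`, `sensitivity`,
#'   `specificity`, `youden_j`, `p_value` (normal test of AUC = 0.5 from
#'   the DeLong/bootstrap SE), `separation` (fused entries only).
#' @export
evaluate_marker_panel <- function(records, panel = default_panel(),
                                  positive = "MCI",
                                  ci_method = c("delong", "bootstrap"),
                                  level = 0.95, ridge = 0) {
  ci_method <- match.arg(ci_method)
  if (!"group" %in% names(records))
    kd_validation_error("records must have a 'group' column")
  rows <- lapply(panel, function(entry) {
    miss <- setdiff(entry$vars, names(records))
    if (length(miss))
      kd_validation_error(paste("panel variables missing:",
                                paste(miss, collapse = ", ")))
    sep <- NA
    if (length(entry$vars) > 1) {
      fit <- fit_logistic_combiner(records[, entry$vars], records$group,
                                   positive = positive, ridge = ridge)
      scores <- fit$probabilities
      sep <- fit$separation_flag
    } else {
      scores <- records[[entry$vars]]
      if (anyNA(scores)) kd_validation_error(
        sprintf("missing values in marker '%s'", entry$vars))
    }
    roc <- empirical_roc(scores, records$group, direction = entry$direction,
                         positive = positive)
    ci <- withCallingHandlers(
      auc_confidence_interval(roc, level = level, method = ci_method),
      warning = function(w) invokeRestart("muffleWarning"))
    cut <- youden_optimal_cutoff(roc)
    p_auc <- if (!is.null(ci$se) && !is.na(ci$se) && ci$se > 0)
      2 * stats::pnorm(-abs(roc$auc - 0.5) / ci$se) else NA_real_
    data.frame(marker = entry$name, auc = roc$auc,
               auc_ci_low = ci$low, auc_ci_high = ci$high,
               cutoff = cut$cutoff, sensitivity = cut$sensitivity,
               specificity = cut$specificity, youden_j = cut$youden_j,
               p_value = p_auc, separation = sep,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("kd_panel", "data.frame")
  out
}

#' @export
print.kd_panel <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
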
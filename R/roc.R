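#' Empirical ROC curve
#'
#' Builds the empirical receiver operating characteristic of a continuous
#' marker against binary class labels, with MCI as the positive class by
#' convention. Candidate thresholds are the midpoints between consecutive
#' distinct observed values plus sentinels below the minimum and above
#' the maximum, the style in which clinical cutoffs are usually printed.
#' The area under the curve is the trapezoidal area, which equals the
#' all-pairs concordance probability with ties counted 1/2.
#'
#' @param scores numeric per-subject marker values.
#' @param labels per-subject class labels; `positive` names the positive
#'   (disease) class, every other label is treated as control.
#' @param direction `"higher_is_positive"` if larger scores indicate the
#'   positive class (e.g. hold/flight time), `"lower_is_positive"` for
#'   markers where smaller values do (e.g. a cognitive test score).
#' @param positive label of the positive class (default `"MCI"`).
#' @return Object of class `kd_roc`: `thresholds` (marker units, aligned
#'   with) `sensitivities` and `specificities`, `auc`, `auc_ci_low`/
#'   `auc_ci_high` (`NA` until [auc_confidence_interval()] is applied),
#'   `direction`, `n_pos`, `n_neg`, `score_median`, plus the input
#'   `scores`/`labels` for variance estimation. Along the stored
#'   threshold order sensitivity is non-increasing and specificity
#'   non-decreasing.
#' @export
empirical_roc <- function(scores, labels,
                          direction = c("higher_is_positive", "lower_is_positive"),
                          positive = "MCI") {
  direction <- match.arg(direction)
  if (length(scores) != length(labels))
    kd_validation_error("scores and labels must have equal length")
  if (any(!is.finite(scores)))
    kd_validation_error("scores must be finite")
  pos <- labels == positive
  if (!any(pos) || all(pos))
    kd_degenerate_error("degenerate labels: need both classes non-empty")

  orient <- if (direction == "higher_is_positive") 1 else -1
  s <- orient * scores
  v <- sort(unique(s))
  if (length(v) == 1L)
    warning("all scores identical; ROC is uninformative (AUC 0.5)")
  thr <- c(v[1] - 1,
           if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
           v[length(v)] + 1)
  sp <- sort(s[pos]); sn <- sort(s[!pos])
  n_pos <- length(sp); n_neg <- length(sn)
  # positive call: oriented score > threshold (midpoints never tie data)
  sens <- (n_pos - findInterval(thr, sp)) / n_pos
  spec <- findInterval(thr, sn) / n_neg

  # trapezoid over (FPR, TPR) in increasing-FPR order; sentinels supply
  # the (0,0) and (1,1) endpoints
  fpr <- rev(1 - spec); tpr <- rev(sens)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)

  structure(list(thresholds = orient * thr,
                 sensitivities = sens,
                 specificities = spec,
                 auc = auc,
                 auc_ci_low = NA_real_, auc_ci_high = NA_real_,
                 direction = direction, positive = positive,
                 n_pos = n_pos, n_neg = n_neg,
                 score_median = stats::median(scores),
                 scores = scores, labels = labels),
            class = "kd_roc")
}

#' @export
print.kd_roc <- function(x, ...) {
  ci <- if (is.na(x$auc_ci_low)) "" else
    sprintf(" (95%% CI %.3f-%.3f)", x$auc_ci_low, x$auc_ci_high)
  cat(sprintf("<kd_roc: AUC %.3f%s, %d positives / %d negatives, %s>\n",
              x$auc, ci, x$n_pos, x$n_neg, x$direction))
  invisible(x)
}

delong_auc_se <- function(s_pos, s_neg) {
  m <- length(s_pos); n <- length(s_neg)
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(s_pos, function(x) mean(psi(x, s_neg)), numeric(1))
  v01 <- vapply(s_neg, function(y) mean(psi(s_pos, y)), numeric(1))
  sqrt(stats::var(v10) / m + stats::var(v01) / n)
}

#' Confidence interval for the ROC AUC
#'
#' Default method is DeLong's nonparametric variance estimate for the
#' concordance statistic with a normal-approximation interval truncated
#' to \[0, 1\]; a stratified nonparametric bootstrap (percentile
#' interval) is available as a fallback. A zero-variance AUC (e.g.
#' perfect separation) yields the degenerate interval `[auc, auc]` with
#' a warning.
#'
#' @param roc a `kd_roc` object from [empirical_roc()].
#' @param level confidence level (default 0.95); level 0 collapses the
#'   interval to `[auc, auc]`.
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap resamples (method `"bootstrap"`).
#' @return List with `auc`, `low`, `high`, `se` (`NA` for bootstrap),
#'   `level`, `method`.
#' @export
auc_confidence_interval <- function(roc, level = 0.95,
                                    method = c("delong", "bootstrap"),
                                    n_boot = 2000) {
  stopifnot(inherits(roc, "kd_roc"))
  method <- match.arg(method)
  if (level < 0 || level >= 1)
    kd_validation_error("level must be in [0, 1)")
  orient <- if (roc$direction == "higher_is_positive") 1 else -1
  s <- orient * roc$scores
  pos <- roc$labels == roc$positive
  if (sum(pos) < 2 || sum(!pos) < 2)
    kd_degenerate_error("need at least 2 subjects per class for a CI")
  if (method == "delong") {
    se <- delong_auc_se(s[pos], s[!pos])
    if (se == 0) {
      warning("zero DeLong variance (perfect separation); degenerate interval")
      return(list(auc = roc$auc, low = roc$auc, high = roc$auc, se = 0,
                  level = level, method = method))
    }
    z <- stats::qnorm(1 - (1 - level) / 2)
    list(auc = roc$auc,
         low = max(0, roc$auc - z * se), high = min(1, roc$auc + z * se),
         se = se, level = level, method = method)
  } else {
    sp <- s[pos]; sn <- s[!pos]
    aucs <- vapply(seq_len(n_boot), function(i) {
      bp <- sample(sp, replace = TRUE); bn <- sample(sn, replace = TRUE)
      concordance_auc(bp, bn)
    }, numeric(1))
    qs <- stats::quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE, type = 7)
    list(auc = roc$auc, low = qs[1], high = qs[2], se = stats::sd(aucs),
         level = level, method = method)
  }
}

# rank-based concordance AUC (ties 1/2); O(n log n)
concordance_auc <- function(s_pos, s_neg) {
  r <- rank(c(s_pos, s_neg), ties.method = "average")
  m <- length(s_pos)
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * length(s_neg))
}

#' Youden-optimal cutoff
#'
#' Selects the threshold maximizing the Youden index
#' `J = sensitivity + specificity - 1` over the ROC's candidate
#' thresholds. Ties on J are broken in favor of higher sensitivity (a
#' screening context favors catching cases), then the less extreme
#' cutoff, i.e. the one closest to the median score.
#'
#' @param roc a `kd_roc` object.
#' @return Object of class `kd_cutoff` with fields `cutoff` (marker
#'   units), `sensitivity`, `specificity`, `youden_j`.
#' @export
youden_optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "kd_roc"))
  if (!length(roc$thresholds))
    kd_validation_error("ROC has no thresholds")
  j <- roc$sensitivities + roc$specificities - 1
  cand <- which(j >= max(j) - 1e-12)
  cand <- cand[roc$sensitivities[cand] >= max(roc$sensitivities[cand]) - 1e-12]
  cand <- cand[order(abs(roc$thresholds[cand] - roc$score_median))]
  i <- cand[1]
  structure(list(cutoff = roc$thresholds[i],
                 sensitivity = roc$sensitivities[i],
                 specificity = roc$specificities[i],
                 youden_j = roc$sensitivities[i] + roc$specificities[i] - 1),
            class = "kd_cutoff")
}

#' @export
print.kd_cutoff <- function(x, ...) {
  cat(sprintf("<kd_cutoff: %.4g (sens %.3f, spec %.3f, J %.3f)>\n",
              x$cutoff, x$sensitivity, x$specificity, x$youden_j))
  invisible(x)
}
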
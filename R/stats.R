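#' Pooled two-sample t test from summary statistics
#'
#' Student's pooled-variance t test computed directly from printed group
#' summaries (mean, SD, n), the form identified by published degrees of
#' freedom `n1 + n2 - 2`. The pooled variance is
#' `sp^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2)` and
#' `t = (mean1 - mean2) / (sp * sqrt(1/n1 + 1/n2))`, with a two-tailed p
#' value from the t distribution.
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @return Object of class `kd_ttest`: `t`, `df`, `p`, `mean_diff`
#'   (`mean1 - mean2`), `pooled_sd`.
#' @export
pooled_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) kd_validation_error("need n >= 2 per group")
  if (sd1 < 0 || sd2 < 0) kd_validation_error("sds must be non-negative")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  diff <- mean1 - mean2
  if (sp == 0) {
    if (diff != 0) kd_degenerate_error("zero variance with unequal means")
    t <- 0
  } else {
    t <- diff / (sp * sqrt(1 / n1 + 1 / n2))
  }
  structure(list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
                 mean_diff = diff, pooled_sd = sp),
            class = "kd_ttest")
}

#' Pooled two-sample t test from raw data
#'
#' Convenience wrapper computing the group summaries and delegating to
#' [pooled_t_from_summary()], so raw-data and summary-based results are
#' identical by construction.
#'
#' @param x,y numeric samples for the two groups.
#' @return See [pooled_t_from_summary()].
#' @export
pooled_t_test <- function(x, y) {
  pooled_t_from_summary(mean(x), stats::sd(x), length(x),
                        mean(y), stats::sd(y), length(y))
}

#' @export
print.kd_ttest <- function(x, ...) {
  cat(sprintf("<kd_ttest: t = %.3f, df = %d, p = %.3g>\n", x$t, x$df, x$p))
  invisible(x)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) Pearson statistic
#' `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with 1 degree of
#' freedom, matching the form SPSS prints for group-by-sex tables.
#'
#' @param a,b,c,d cell counts, row-wise (`a`,`b` first row); `a` may also
#'   be a 2x2 matrix.
#' @return Object of class `kd_chisq`: `chi2`, `df` (always 1), `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  if (is.matrix(a)) {
    if (!all(dim(a) == 2)) kd_validation_error("table must be 2x2")
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  counts <- c(a, b, c, d)
  if (any(counts < 0)) kd_validation_error("counts must be non-negative")
  n <- sum(counts)
  if (n <= 0) kd_validation_error("empty table")
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) kd_degenerate_error("degenerate margin in 2x2 table")
  chi2 <- n * (a * d - b * c)^2 / prod(margins)
  structure(list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE)),
            class = "kd_chisq")
}

#' @export
print.kd_chisq <- function(x, ...) {
  cat(sprintf("<kd_chisq: chi2 = %.3f, df = 1, p = %.3g>\n", x$chi2, x$p))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Assigns average ranks to ties, takes the Pearson correlation of the
#' ranks, and tests it with the t approximation
#' `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom (two-tailed)
#' — adequate at the cohort sizes this package targets. For very small
#' samples (`n <= 8`) an exact permutation p value is available.
#'
#' @param x,y numeric vectors of equal length, at least 3.
#' @param p_method `"t_approx"` (default) or `"exact"` (full enumeration,
#'   `n <= 8` only).
#' @return Object of class `kd_spearman`: `r`, `p`, `n`.
#' @export
spearman_cor <- function(x, y, p_method = c("t_approx", "exact")) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) kd_validation_error("x and y lengths differ")
  n <- length(x)
  if (n < 3) kd_validation_error("need at least 3 observations")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    kd_degenerate_error("zero rank variance (constant input)")
  r <- stats::cor(rx, ry)
  p <- if (p_method == "t_approx") {
    if (abs(r) >= 1) 0 else {
      t <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(t), n - 2)
    }
  } else {
    if (n > 8) kd_validation_error("exact permutation p limited to n <= 8")
    perms <- permutations_of(n)
    robs <- abs(r) - 1e-12
    mean(apply(perms, 1, function(idx) abs(stats::cor(rx, ry[idx])) >= robs))
  }
  structure(list(r = r, p = p, n = n), class = "kd_spearman")
}

#' @export
print.kd_spearman <- function(x, ...) {
  cat(sprintf("<kd_spearman: r = %.3f, p = %.3g, n = %d>\n", x$r, x$p, x$n))
  invisible(x)
}

# all permutations of 1..n as a matrix (n! rows); test-scale only
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Spearman correlation matrix of analysis variables
#'
#' Pairwise rank correlations (complete cases across the selected
#' variables) of cognitive scores and keystroke features, in the layout
#' of a published correlation table: symmetric, unit diagonal.
#'
#' @param records analysis data.frame (one row per participant).
#' @param variables columns to correlate; defaults to the MoCA-K, CBT
#'   accuracy, mean HT and mean FT columns.
#' @return Object of class `kd_cormat`: `r` and `p` matrices, `n`
#'   (complete cases), `variables`.
#' @export
correlation_matrix <- function(records,
                               variables = c("moca_k", "cbt_accuracy",
                                             "mean_ht_ms", "mean_ft_ms")) {
  missing_vars <- setdiff(variables, names(records))
  if (length(missing_vars))
    kd_validation_error(paste("missing variables:",
                              paste(missing_vars, collapse = ", ")))
  dat <- records[stats::complete.cases(records[, variables]), variables]
  k <- length(variables)
  r <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- list(variables, variables)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    s <- spearman_cor(dat[[i]], dat[[j]])
    r[i, j] <- r[j, i] <- s$r
    p[i, j] <- p[j, i] <- s$p
  }
  structure(list(r = r, p = p, n = nrow(dat), variables = variables),
            class = "kd_cormat")
}

#' @export
print.kd_cormat <- function(x, ...) {
  cat(sprintf("<kd_cormat: n = %d>\n", x$n))
  print(round(x$r, 3))
  invisible(x)
}
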
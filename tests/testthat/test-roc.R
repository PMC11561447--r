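labels2 <- function(n_hc, n_mci) c(rep("HC", n_hc), rep("MCI", n_mci))

test_that("empirical ROC handles boundary cases", {
  r <- empirical_roc(c(1, 2, 3, 4, 5, 6), labels2(3, 3))
  expect_equal(r$auc, 1)

  expect_warning(r0 <- empirical_roc(rep(7, 6), labels2(3, 3)), "identical")
  expect_equal(r0$auc, 0.5)

  # 3 of 4 (mci, hc) pairs concordant
  r75 <- empirical_roc(c(2, 4, 3, 5), labels2(2, 2))
  expect_equal(r75$auc, 0.75)

  expect_error(empirical_roc(1:4, rep("MCI", 4)), class = "kd_degenerate_error")
})

test_that("sensitivity/specificity are monotone along the threshold axis", {
  set.seed(11)
  r <- empirical_roc(rnorm(60), sample(labels2(30, 30)))
  expect_true(all(diff(r$sensitivities) <= 0))
  expect_true(all(diff(r$specificities) >= 0))
  expect_equal(range(r$sensitivities), c(0, 1))
  expect_equal(range(r$specificities), c(0, 1))
})

test_that("trapezoid AUC equals all-pairs concordance on random instances", {
  for (seed in 1:20) {
    set.seed(seed)
    m <- sample(2:100, 1); n <- sample(2:100, 1)
    # rounding forces ties, exercising the 1/2 weighting
    pos <- round(rnorm(m, 1), 1); neg <- round(rnorm(n), 1)
    r <- empirical_roc(c(neg, pos), labels2(n, m))
    expect_equal(r$auc, bruteforce_auc(pos, neg), tolerance = 1e-12)
  }
})

test_that("ROC is invariant under strictly monotone transforms", {
  set.seed(3)
  scores <- rexp(40) + 0.1
  lab <- sample(labels2(22, 18))
  base <- empirical_roc(scores, lab)
  aff <- empirical_roc(3.5 * scores + 11, lab)
  logt <- empirical_roc(log(scores), lab)
  expect_equal(aff$auc, base$auc)
  expect_equal(logt$auc, base$auc)
  expect_equal(aff$sensitivities, base$sensitivities)
  expect_equal(logt$specificities, base$specificities)

  # affine transforms map the Youden cutoff exactly
  cb <- youden_optimal_cutoff(base); ca <- youden_optimal_cutoff(aff)
  expect_equal(ca$cutoff, 3.5 * cb$cutoff + 11)
  # nonlinear transforms induce the same partition of subjects
  cl <- youden_optimal_cutoff(logt)
  expect_equal(log(scores) > cl$cutoff, scores > cb$cutoff)
})

test_that("reversing direction maps AUC to 1 - AUC", {
  for (seed in 1:8) {
    set.seed(seed)
    scores <- round(rnorm(50), 1)
    lab <- sample(labels2(25, 25))
    hi <- empirical_roc(scores, lab, "higher_is_positive")
    lo <- empirical_roc(scores, lab, "lower_is_positive")
    expect_equal(lo$auc, 1 - hi$auc, tolerance = 1e-12)
  }
})

test_that("empirical AUC approaches the binormal value at large n", {
  set.seed(99)
  n <- 1e5
  hc <- rnorm(n, 25.83, 2.11); mci <- rnorm(n, 22.77, 2.26)
  r <- empirical_roc(c(hc, mci), labels2(n, n), "lower_is_positive")
  expect_equal(r$auc, pnorm((25.83 - 22.77) / sqrt(2.11^2 + 2.26^2)),
               tolerance = 0.005)
})

test_that("Youden search matches exhaustive enumeration", {
  pc <- youden_optimal_cutoff(empirical_roc(c(1, 2, 3, 4, 5, 6), labels2(3, 3)))
  expect_equal(pc$cutoff, 3.5)
  expect_equal(pc$youden_j, 1)

  # tie on J broken toward higher sensitivity
  tie <- youden_optimal_cutoff(empirical_roc(c(2, 4, 3, 5), labels2(2, 2)))
  expect_equal(tie$cutoff, 2.5)
  expect_equal(tie$sensitivity, 1)
  expect_equal(tie$specificity, 0.5)
  expect_equal(tie$youden_j, 0.5)

  for (seed in 1:20) {
    set.seed(seed)
    m <- sample(2:60, 1); n <- sample(2:60, 1)
    pos <- round(rnorm(m, 0.8), 1); neg <- round(rnorm(n), 1)
    cut <- youden_optimal_cutoff(empirical_roc(c(neg, pos), labels2(n, m)))
    expect_equal(cut$youden_j, bruteforce_youden(pos, neg), tolerance = 1e-12)
    expect_equal(cut$youden_j, cut$sensitivity + cut$specificity - 1)
  }
})

test_that("DeLong interval is sane and matches a hand-computed case", {
  # MCI {3,5}, HC {2,4}: placements give var = 0.125/2 + 0.125/2
  r <- empirical_roc(c(2, 4, 3, 5), labels2(2, 2))
  ci <- auc_confidence_interval(r)
  expect_equal(ci$se, sqrt(0.125), tolerance = 1e-12)
  expect_equal(ci$low, max(0, 0.75 - qnorm(0.975) * sqrt(0.125)))
  expect_equal(ci$high, 1)

  # degenerate: perfect separation
  rp <- empirical_roc(c(1, 2, 3, 4, 5, 6), labels2(3, 3))
  expect_warning(cip <- auc_confidence_interval(rp), "zero DeLong variance")
  expect_equal(c(cip$low, cip$high), c(1, 1))

  # level 0 collapses the interval
  set.seed(5)
  rn <- empirical_roc(rnorm(30, rep(c(0, 1), 15)), rep(c("HC", "MCI"), 15))
  ci0 <- auc_confidence_interval(rn, level = 0)
  expect_equal(ci0$low, ci0$high)
  expect_equal(ci0$low, rn$auc)
})

test_that("DeLong agrees with a bootstrap oracle at moderate n", {
  set.seed(17)
  scores <- c(rnorm(20), rnorm(20, 1.2))
  lab <- labels2(20, 20)
  r <- empirical_roc(scores, lab)
  dl <- auc_confidence_interval(r, method = "delong")
  set.seed(18)
  bs <- auc_confidence_interval(r, method = "bootstrap", n_boot = 10000)
  expect_equal(dl$low, bs$low, tolerance = 0.02)
  expect_equal(dl$high, bs$high, tolerance = 0.02)
})
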
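test_that("confusion tallies use an inclusive cutoff and validate input", {
  m <- confusion_from_scores(c(0.9, 0.1), c("MALIGNANT", "BENIGN"), 0.9)
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(1, 0, 0, 1))
  m2 <- confusion_from_scores(c(0.1, 0.2), c("MALIGNANT", "BENIGN"), 0.9)
  expect_equal(c(m2$tp, m2$fp), c(0, 0))
  # decimal-lattice tolerance: 0.2 + 0.5 counts as >= 0.7
  m3 <- confusion_from_scores(0.2 + 0.5, "MALIGNANT", 0.7)
  expect_equal(m3$tp, 1)
  expect_error(confusion_from_scores(c(1, 2), "MALIGNANT", 0.5),
               "differ in length")
  expect_error(confusion_from_scores(numeric(0), character(0), 0.5),
               "empty input")
})

test_that("Wilson interval matches the score-test inversion from prop.test", {
  # independent oracle: stats::prop.test without continuity correction
  # inverts the same score test
  cases <- rbind(c(22, 25), c(19, 36), c(18, 22), c(9, 11), c(1, 50),
                 c(49, 50), c(7, 7))
  for (i in seq_len(nrow(cases))) {
    k <- cases[i, 1]; n <- cases[i, 2]
    for (cl in c(0.90, 0.95, 0.99)) {
      ours <- wilson_ci(k, n, cl)
      oracle <- suppressWarnings(
        stats::prop.test(k, n, correct = FALSE, conf.level = cl)$conf.int
      )
      expect_equal(unname(ours), as.numeric(oracle), tolerance = 1e-10)
    }
  }
  # degenerate boundary: the score interval pins the endpoint exactly
  expect_equal(unname(wilson_ci(0, 10)[1]), 0)
  expect_equal(unname(wilson_ci(10, 10)[2]), 1)
  expect_error(wilson_ci(5, 0), "positive integer")
  expect_error(wilson_ci(11, 10), "between 0 and trials")
})

test_that("Wilson interval contains the estimate and reflects under k -> n-k", {
  set.seed(3)
  for (i in 1:50) {
    n <- sample(1:200, 1)
    k <- sample(0:n, 1)
    ci <- wilson_ci(k, n)
    expect_true(ci[1] <= k / n + 1e-12 && k / n <= ci[2] + 1e-12)
    expect_true(ci[1] >= 0 && ci[2] <= 1)
    refl <- wilson_ci(n - k, n)
    expect_equal(unname(refl), unname(1 - rev(ci)), tolerance = 1e-12)
  }
})

test_that("performance metrics and Wilson CIs reproduce the pilot tables", {
  # TRS table: (22, 3, 4, 18)
  p <- performance(confusion_matrix(22, 3, 4, 18))
  expect_equal(p$sensitivity, 22 / 26)
  expect_equal(p$specificity, 18 / 21)
  expect_equal(p$ppv, 0.88)
  expect_equal(p$npv, 18 / 22)
  expect_equal(round(100 * p$ci_ppv, 1), c(low = 70, high = 95.8))
  expect_equal(round(100 * p$ci_npv, 1), c(low = 61.5, high = 92.7))
  # X_US table: (9, 2, 17, 19)
  q <- performance(confusion_matrix(9, 2, 17, 19))
  expect_equal(round(100 * c(q$sensitivity, q$specificity, q$ppv, q$npv), 1),
               c(34.6, 90.5, 81.8, 52.8))
  expect_equal(round(100 * q$ci_npv, 0), c(low = 37, high = 68))
  # undefined metrics are explicit NA markers, never 0
  u <- performance(confusion_matrix(0, 0, 1, 1))
  expect_true(is.na(u$ppv))
  expect_true(all(is.na(u$ci_ppv)))
  expect_false(is.na(u$npv))
  expect_error(confusion_matrix(0, 0, 0, 0), "all zero")
})

test_that("balanced accuracy equals the single-threshold ROC AUC", {
  expect_equal(round(100 * balanced_accuracy(confusion_matrix(22, 3, 4, 18)), 1),
               85.2)
  expect_equal(round(100 * balanced_accuracy(confusion_matrix(9, 2, 17, 19)), 1),
               62.5)
  expect_equal(balanced_accuracy(confusion_matrix(5, 0, 0, 7)), 1)
  # independent oracle: trapezoidal AUC (pROC) of the dichotomized calls
  skip_if_not_installed("pROC")
  set.seed(5)
  for (i in 1:10) {
    n <- 60
    truth <- sample(c("MALIGNANT", "BENIGN"), n, replace = TRUE,
                    prob = c(0.55, 0.45))
    scores <- round(runif(n), 2)
    cutoff <- runif(1, 0.2, 0.8)
    if (length(unique(truth)) < 2) next
    m <- confusion_from_scores(scores, truth, cutoff)
    calls <- as.numeric(scores >= cutoff - 1e-9)
    auc <- suppressMessages(as.numeric(
      pROC::auc(response = as.integer(truth == "MALIGNANT"),
                predictor = calls, direction = "<")
    ))
    expect_equal(balanced_accuracy(m), auc, tolerance = 1e-12)
  }
})

test_that("odds ratio with Woolf interval reproduces the printed values", {
  or <- odds_ratio(confusion_matrix(9, 2, 17, 19))
  expect_equal(round(or$or_value, 2), 5.03)
  expect_equal(round(unname(or$ci), c(2, 1)), c(0.95, 26.6))
  expect_equal(odds_ratio(confusion_matrix(1, 1, 1, 1))$or_value, 1)
  # zero cell: Haldane-Anscombe correction keeps estimate and CI finite
  z <- odds_ratio(confusion_matrix(5, 0, 3, 7))
  expect_true(z$correction)
  expect_true(is.finite(z$or_value) && all(is.finite(z$ci)))
  expect_true(z$ci[1] <= z$or_value && z$or_value <= z$ci[2])
})

test_that("subgroup exclusion is cellwise subtraction with bounds", {
  m <- exclude_subgroup(confusion_matrix(22, 3, 4, 18), tp = 3)
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(19, 3, 4, 18))
  expect_equal(round(100 * m$tp / (m$tp + m$fn), 1), 82.6)
  same <- exclude_subgroup(confusion_matrix(22, 3, 4, 18))
  expect_equal(c(same$tp, same$fp, same$fn, same$tn), c(22, 3, 4, 18))
  expect_error(exclude_subgroup(confusion_matrix(2, 1, 1, 1), tp = 3),
               "exceeds")
})

test_that("proportion comparisons agree with their reference tests", {
  # pooled two-proportion z: hand-derived statistic, and chi-square identity
  cmp <- compare_proportions(9, 26, 22, 26, method = "two_prop_z")
  expect_equal(round(abs(cmp$statistic), 2), 3.67)
  expect_equal(cmp$p_value, 2.39e-4, tolerance = 0.01)
  oracle <- suppressWarnings(
    stats::prop.test(c(9, 22), c(26, 26), correct = FALSE)
  )
  expect_equal(cmp$p_value, oracle$p.value, tolerance = 1e-12)
  expect_equal(compare_proportions(5, 10, 10, 20)$p_value, 1)

  f <- compare_proportions(0, 10, 10, 10, method = "fisher")
  expect_equal(f$p_value,
               stats::fisher.test(matrix(c(0, 10, 10, 0), 2))$p.value)
  expect_lt(f$p_value, 1e-4)
  expect_error(compare_proportions(1, 0, 1, 2), "positive")
})

test_that("paired McNemar uses discordant pairs", {
  c1 <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  c2 <- c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  mc <- mcnemar_paired(c1, c2)
  expect_equal(c(mc$b, mc$c), c(1, 2))
  tab <- table(factor(c1, c(FALSE, TRUE)), factor(c2, c(FALSE, TRUE)))
  expect_equal(mc$p_value, stats::mcnemar.test(tab)$p.value)
  expect_equal(mcnemar_paired(c1, c1)$p_value, 1)
})
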
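test_that("reconstruction recovers the pilot tables uniquely", {
  sol <- reconstruct_matrix(
    list(sensitivity = c(34.6, 1), specificity = c(90, 0),
         ppv = c(81.8, 1), npv = c(52.8, 1)),
    n_total = 47
  )
  expect_length(sol, 1)
  m <- sol[[1]]
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(9, 2, 17, 19))

  sol2 <- reconstruct_matrix(
    list(sensitivity = c(84.6, 1), specificity = c(85.7, 1),
         ppv = c(88, 0), npv = c(81.8, 1)),
    n_total = 47
  )
  expect_length(sol2, 1)
  expect_equal(with(sol2[[1]], c(tp, fp, fn, tn)), c(22, 3, 4, 18))
})

test_that("a perfect printed quadruple yields the whole perfect-classifier family", {
  sol <- reconstruct_matrix(
    list(sensitivity = c(100, 0), specificity = c(100, 0),
         ppv = c(100, 0), npv = c(100, 0)),
    n_total = 4
  )
  cells <- t(vapply(sol, function(m) c(m$tp, m$fp, m$fn, m$tn), numeric(4)))
  expect_true(all(cells[, 2] == 0 & cells[, 3] == 0))
  # every split with both classes present (printed values force both margins)
  expect_equal(nrow(cells), 3)
  expect_setequal(cells[, 1], 1:3)
})

test_that("reconstruction is self-inverse for arbitrary tables", {
  set.seed(23)
  for (i in 1:8) {
    repeat {
      cells <- as.vector(stats::rmultinom(1, size = sample(10:30, 1),
                                          prob = rep(0.25, 4)))
      if (cells[1] + cells[3] > 0 && cells[2] + cells[4] > 0 &&
          cells[1] + cells[2] > 0 && cells[3] + cells[4] > 0) break
    }
    m <- confusion_matrix(cells[1], cells[2], cells[3], cells[4])
    n <- sum(cells)
    decimals <- sample(0:2, 1)
    printed <- list(
      sensitivity = c(round(100 * m$tp / (m$tp + m$fn), decimals), decimals),
      specificity = c(round(100 * m$tn / (m$tn + m$fp), decimals), decimals),
      ppv = c(round(100 * m$tp / (m$tp + m$fp), decimals), decimals),
      npv = c(round(100 * m$tn / (m$tn + m$fn), decimals), decimals)
    )
    sol <- reconstruct_matrix(printed, n, rounding = "either")
    found <- any(vapply(sol, function(s) {
      identical(c(s$tp, s$fp, s$fn, s$tn), c(m$tp, m$fp, m$fn, m$tn))
    }, logical(1)))
    expect_true(found)
  }
})

test_that("the printed X_GC quadruple admits no integer table at any n <= 47", {
  printed <- list(sensitivity = c(80.7, 1), specificity = c(94.7, 1),
                  ppv = c(92.3, 1), npv = c(80, 0))
  hits <- vapply(1:47, function(n) {
    length(reconstruct_matrix(printed, n, rounding = "either"))
  }, numeric(1))
  expect_true(all(hits == 0))
})

test_that("margin-wise reconstruction pins the X_GC fractions", {
  # 80.7 is a truncation of 21/26: nothing prints 80.7 under half-up
  expect_equal(nrow(reconstruct_proportion(80.7, 1, max_n = 47,
                                           rounding = "half_up")), 0)
  sens <- reconstruct_proportion(80.7, 1, max_n = 26, rounding = "either")
  expect_equal(nrow(sens), 1)
  expect_equal(c(sens$k, sens$n), c(21, 26))
  spec <- reconstruct_proportion(94.7, 1, max_n = 21)
  expect_equal(c(spec$k, spec$n), c(18, 19))
})

test_that("margin bounds restrict the solution set", {
  sol <- reconstruct_matrix(
    list(sensitivity = c(50, 0)), n_total = 8,
    margin_bounds = list(malignant = c(4, 4), benign = c(4, 4))
  )
  cells <- t(vapply(sol, function(m) c(m$tp, m$fp, m$fn, m$tn), numeric(4)))
  expect_true(all(cells[, 1] + cells[, 3] == 4))
  expect_true(all(cells[, 1] == 2))
})
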
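#' Comparing two proportions
#'
#' Two-sided comparison of two independent binomial proportions, either by
#' the pooled two-proportion z-test or by Fisher's exact test. For paired
#' designs (the same nodules called by two different scores),
#' [mcnemar_paired()] is the appropriate test instead.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @param method `"two_prop_z"` (pooled z statistic, no continuity
#'   correction) or `"fisher"` (exact).
#' @return a list with `p_value`, `method`, `estimate` (the two
#'   proportions) and, for the z-test, the `statistic`.
#' @examples
#' compare_proportions(9, 26, 22, 26)$p_value  # ~2.4e-4
#' @export
compare_proportions <- function(k1, n1, k2, n2,
                                method = c("two_prop_z", "fisher")) {
  method <- match.arg(method)
  if (n1 <= 0 || n2 <= 0) stop_input("both group sizes must be positive")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    stop_input("successes must lie within [0, n]")
  }
  p1 <- k1 / n1
  p2 <- k2 / n2
  if (method == "two_prop_z") {
    pool <- (k1 + k2) / (n1 + n2)
    se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
    if (se == 0) {
      # identical degenerate proportions (all success or all failure)
      return(list(p_value = 1, method = method, estimate = c(p1, p2),
                  statistic = 0))
    }
    z <- (p1 - p2) / se
    list(p_value = 2 * stats::pnorm(-abs(z)), method = method,
         estimate = c(p1, p2), statistic = z)
  } else {
    ft <- stats::fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2))
    list(p_value = ft$p.value, method = method, estimate = c(p1, p2))
  }
}

#' McNemar test for paired diagnostic calls
#'
#' Compares two tests applied to the same subjects (e.g. X_US-positive vs
#' TRS-positive calls on the same nodules) via the discordant pairs.
#'
#' @param calls1,calls2 logical vectors of test-positive calls, same length
#'   and subject order.
#' @param correct apply the continuity correction (default `TRUE`, as
#'   [stats::mcnemar.test()] does).
#' @return a list with `p_value`, `method` and the discordant counts `b`
#'   (positive only by test 1) and `c` (positive only by test 2).
#' @export
mcnemar_paired <- function(calls1, calls2, correct = TRUE) {
  if (length(calls1) != length(calls2)) stop_input("call vectors differ in length")
  calls1 <- as.logical(calls1)
  calls2 <- as.logical(calls2)
  b <- sum(calls1 & !calls2)
  cc <- sum(!calls1 & calls2)
  if (b + cc == 0) {
    return(list(p_value = 1, method = "mcnemar", b = b, c = cc))
  }
  tab <- table(factor(calls1, c(FALSE, TRUE)), factor(calls2, c(FALSE, TRUE)))
  mt <- stats::mcnemar.test(tab, correct = correct)
  list(p_value = mt$p.value, method = "mcnemar", b = b, c = cc)
}
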
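#' Confusion matrices and diagnostic performance
#'
#' Diagnostic performance of a dichotomized score against reference-standard
#' histology: sensitivity, specificity, predictive values with Wilson score
#' confidence intervals, balanced accuracy (the ROC AUC of a
#' single-threshold test), and the diagnostic odds ratio with a
#' log-normal (Woolf) interval.
#'
#' @name diagnostic_stats
NULL

#' Construct a 2x2 confusion matrix
#'
#' @param tp,fp,fn,tn non-negative integer cell counts (test positive /
#'   negative vs malignant / benign).
#' @return an object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop_input("confusion matrix cells must be non-negative integers")
  }
  if (sum(cells) == 0) stop_input("confusion matrix is all zero")
  structure(as.list(as.integer(cells)) |> stats::setNames(names(cells)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), nrow = 2, byrow = TRUE,
              dimnames = list(c("test+", "test-"), c("malignant", "benign")))
  print(m)
  invisible(x)
}

#' Tally a confusion matrix from scores and truth labels
#'
#' A nodule is test-positive when its score is at or above the cutoff
#' (inclusive, with the decimal-lattice tolerance used throughout).
#'
#' @param scores numeric vector.
#' @param truth character vector, `"MALIGNANT"`/`"BENIGN"` (same length).
#' @param cutoff positivity cutoff.
#' @return a [confusion_matrix()].
#' @export
confusion_from_scores <- function(scores, truth, cutoff) {
  if (!length(scores)) stop_input("empty input")
  if (length(scores) != length(truth)) {
    stop_input("scores and truths differ in length (%d vs %d)",
               length(scores), length(truth))
  }
  truth <- parse_truth(truth)
  if (anyNA(truth)) stop_input("missing truth labels")
  pos <- gte_tol(scores, cutoff)
  mal <- truth == "MALIGNANT"
  confusion_matrix(
    tp = sum(pos & mal), fp = sum(pos & !mal),
    fn = sum(!pos & mal), tn = sum(!pos & !mal)
  )
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Inverts the score test: for observed successes k of n at confidence
#' level 1 - alpha with z the standard normal quantile,
#' \deqn{\frac{\hat p + z^2/2n \pm z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}}{1 + z^2/n}.}
#' Endpoints always lie in \[0, 1\] and the interval always contains k/n.
#'
#' @param successes number of successes (0..trials).
#' @param trials number of trials (> 0).
#' @param conf_level confidence level, default 0.95.
#' @return numeric vector `c(low, high)`.
#' @examples
#' wilson_ci(22, 25)  # c(0.700, 0.958)
#' @export
wilson_ci <- function(successes, trials, conf_level = 0.95) {
  if (!is_scalar_number(trials) || trials <= 0 || trials != round(trials)) {
    stop_input("trials must be a positive integer")
  }
  if (successes < 0 || successes > trials) {
    stop_input("successes must be between 0 and trials")
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- successes / trials
  centre <- p + z^2 / (2 * trials)
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2))
  denom <- 1 + z^2 / trials
  c(low = max(0, (centre - half) / denom),
    high = min(1, (centre + half) / denom))
}

#' Balanced diagnostic accuracy
#'
#' `(sensitivity + specificity) / 2` — for a dichotomized (single-threshold)
#' test this equals the trapezoidal ROC AUC, and it is the "diagnostic
#' accuracy" figure used when comparing the three scores.
#'
#' @param m a [confusion_matrix()].
#' @return numeric in \[0, 1\].
#' @export
balanced_accuracy <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  if (m$tp + m$fn == 0 || m$fp + m$tn == 0) {
    stop_input("balanced accuracy undefined: a truth margin is zero")
  }
  (m$tp / (m$tp + m$fn) + m$tn / (m$tn + m$fp)) / 2
}

#' Full diagnostic performance of a confusion matrix
#'
#' Metrics whose denominator is zero (e.g. PPV when nothing is called
#' positive) are returned as `NA` — an explicit undefined marker, never
#' silently 0 — with `NA` confidence bounds.
#'
#' @param m a [confusion_matrix()].
#' @param conf_level confidence level for the Wilson intervals.
#' @return an object of class `diagnostic_performance`: a list with
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `balanced_accuracy`, the
#'   four `ci_*` (low, high) pairs, `conf_level` and the `matrix`.
#' @export
performance <- function(m, conf_level = 0.95) {
  stopifnot(inherits(m, "confusion_matrix"))
  metric <- function(k, n) {
    if (n == 0) {
      list(est = NA_real_, ci = c(low = NA_real_, high = NA_real_))
    } else {
      list(est = k / n, ci = wilson_ci(k, n, conf_level))
    }
  }
  sens <- metric(m$tp, m$tp + m$fn)
  spec <- metric(m$tn, m$tn + m$fp)
  ppv  <- metric(m$tp, m$tp + m$fp)
  npv  <- metric(m$tn, m$tn + m$fn)
  ba <- if (is.na(sens$est) || is.na(spec$est)) NA_real_ else
    (sens$est + spec$est) / 2
  structure(
    list(
      sensitivity = sens$est, specificity = spec$est,
      ppv = ppv$est, npv = npv$est,
      balanced_accuracy = ba,
      ci_sensitivity = sens$ci, ci_specificity = spec$ci,
      ci_ppv = ppv$ci, ci_npv = npv$ci,
      conf_level = conf_level,
      matrix = m
    ),
    class = "diagnostic_performance"
  )
}

#' @export
print.diagnostic_performance <- function(x, digits = 1, ...) {
  pct <- function(v) ifelse(is.na(v), "NA", sprintf("%.*f%%", digits, 100 * v))
  ci <- function(v) if (anyNA(v)) "" else
    sprintf(" (%s CI %s-%s)", sprintf("%.0f%%", 100 * x$conf_level),
            pct(v[1]), pct(v[2]))
  cat(sprintf("sensitivity %s%s\n", pct(x$sensitivity), ci(x$ci_sensitivity)))
  cat(sprintf("specificity %s%s\n", pct(x$specificity), ci(x$ci_specificity)))
  cat(sprintf("PPV         %s%s\n", pct(x$ppv), ci(x$ci_ppv)))
  cat(sprintf("NPV         %s%s\n", pct(x$npv), ci(x$ci_npv)))
  cat(sprintf("balanced accuracy %s\n", pct(x$balanced_accuracy)))
  invisible(x)
}

#' Diagnostic odds ratio with log-normal (Woolf) confidence interval
#'
#' `OR = (tp * tn) / (fp * fn)`; the interval is
#' `exp(log OR +/- z * sqrt(1/tp + 1/fp + 1/fn + 1/tn))`. When any cell is
#' zero the Haldane-Anscombe correction adds 0.5 to all four cells so the
#' estimator and interval stay defined.
#'
#' @param m a [confusion_matrix()].
#' @param conf_level confidence level, default 0.95.
#' @return a list with `or_value`, `ci` (low, high), `method` and
#'   `correction` (whether 0.5 was added).
#' @examples
#' odds_ratio(confusion_matrix(9, 2, 17, 19))  # OR 5.03, CI 0.95-26.6
#' @export
odds_ratio <- function(m, conf_level = 0.95) {
  stopifnot(inherits(m, "confusion_matrix"))
  cells <- c(m$tp, m$fp, m$fn, m$tn)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / cells))
  structure(
    list(
      or_value = or,
      ci = c(low = exp(log(or) - z * se), high = exp(log(or) + z * se)),
      method = "log-normal (Woolf)",
      correction = corrected,
      conf_level = conf_level
    ),
    class = "odds_ratio_result"
  )
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("OR %.2f, %.0f%% CI %.2f-%.1f [%s%s]\n",
              x$or_value, 100 * x$conf_level, x$ci[1], x$ci[2], x$method,
              if (x$correction) ", Haldane-Anscombe corrected" else ""))
  invisible(x)
}

#' Remove a subgroup from a confusion matrix
#'
#' Cell-wise subtraction, used for sub-analyses that exclude a histology
#' (e.g. recomputing TRS performance without the medullary carcinomas).
#'
#' @param m a [confusion_matrix()].
#' @param tp,fp,fn,tn counts to remove from each cell.
#' @return a [confusion_matrix()].
#' @export
exclude_subgroup <- function(m, tp = 0, fp = 0, fn = 0, tn = 0) {
  stopifnot(inherits(m, "confusion_matrix"))
  new <- c(m$tp - tp, m$fp - fp, m$fn - fn, m$tn - tn)
  if (any(new < 0)) {
    stop_input("subgroup removal exceeds a cell count")
  }
  confusion_matrix(new[1], new[2], new[3], new[4])
}
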
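#' Bayes-theorem projection of predictive values across prevalence
#'
#' Sensitivity and specificity are properties of the test; predictive values
#' depend on disease prevalence. Surgical cohorts of indeterminate thyroid
#' nodules carry referral and selection bias towards malignancy, so the
#' cohort-observed PPV/NPV are projected to other populations via Bayes'
#' theorem:
#' \deqn{PPV(\pi) = \frac{se\,\pi}{se\,\pi + (1-sp)(1-\pi)}, \qquad
#'       NPV(\pi) = \frac{sp\,(1-\pi)}{sp\,(1-\pi) + (1-se)\,\pi}.}
#'
#' @name prevalence_projection
NULL

#' Positive predictive value at a given prevalence
#'
#' @param sens test sensitivity in \[0, 1\].
#' @param spec test specificity in \[0, 1\].
#' @param prevalence disease prevalence in (0, 1); vectorized.
#' @return PPV in \[0, 1\]; `NA` when the positive-call probability is 0
#'   (sens = 0 and spec = 1).
#' @examples
#' bayes_ppv(22/26, 18/21, 0.28)  # 0.697
#' @export
bayes_ppv <- function(sens, spec, prevalence) {
  check_bayes_args(sens, spec, prevalence)
  num <- sens * prevalence
  den <- num + (1 - spec) * (1 - prevalence)
  ifelse(den == 0, NA_real_, num / den)
}

#' Negative predictive value at a given prevalence
#'
#' @inheritParams bayes_ppv
#' @return NPV in \[0, 1\]; `NA` when the negative-call probability is 0.
#' @examples
#' bayes_npv(22/26, 18/21, 0.06)  # 0.989
#' @export
bayes_npv <- function(sens, spec, prevalence) {
  check_bayes_args(sens, spec, prevalence)
  num <- spec * (1 - prevalence)
  den <- num + (1 - sens) * prevalence
  ifelse(den == 0, NA_real_, num / den)
}

check_bayes_args <- function(sens, spec, prevalence) {
  if (any(sens < 0 | sens > 1) || any(spec < 0 | spec > 1)) {
    stop_input("sens and spec must lie in [0, 1]")
  }
  if (any(prevalence <= 0 | prevalence >= 1)) {
    stop_input("prevalence must lie strictly inside (0, 1)")
  }
  invisible(NULL)
}

#' Predictive-value curve over a prevalence grid
#'
#' @inheritParams bayes_ppv
#' @param grid increasing prevalence grid in (0, 1); default 0.01 to 0.99 in
#'   steps of 0.01, which spans the 6-59% band typical of populations with
#'   cytologically indeterminate nodules (screening-like at the low end,
#'   surgical referral cohorts at the high end).
#' @return a data frame with columns `prevalence`, `ppv`, `npv`.
#' @export
prevalence_curve <- function(sens, spec, grid = seq(0.01, 0.99, by = 0.01)) {
  if (!length(grid)) stop_input("empty prevalence grid")
  if (is.unsorted(grid, strictly = TRUE)) {
    stop_input("prevalence grid must be strictly increasing")
  }
  data.frame(
    prevalence = grid,
    ppv = bayes_ppv(sens, spec, grid),
    npv = bayes_npv(sens, spec, grid)
  )
}
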
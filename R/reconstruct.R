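#' Reconstructing integer 2x2 tables from printed rounded metrics
#'
#' Published diagnostic-accuracy studies print sensitivity, specificity, PPV
#' and NPV as rounded percentages but rarely the underlying 2x2 table. With
#' the cohort size known, the table can be recovered by exhaustive search:
#' enumerate every `(tp, fp, fn, tn)` summing to the cohort size, compute
#' each metric, round it to the printed precision, and keep the tables that
#' reproduce every printed value. A unique survivor identifies the published
#' table exactly; asserting uniqueness is the caller's job.
#'
#' Printed values are matched under a rounding convention: `"half_up"`
#' (round half away from zero, the usual convention for clinical tables),
#' `"trunc"` (digits beyond the printed precision simply dropped — some
#' published values are truncations, recognizable when no integer table
#' matches under half-up), or `"either"`.
#'
#' @name reconstruction
NULL

#' @keywords internal
matches_printed <- function(pct, value, decimals,
                            rounding = c("half_up", "trunc", "either")) {
  rounding <- match.arg(rounding)
  p <- 10^decimals
  hu <- abs(round_half_up(pct, decimals) - value) < 1e-9
  if (rounding == "half_up") return(hu)
  tr <- abs(floor(pct * p + 1e-9) / p - value) < 1e-9
  if (rounding == "trunc") tr else (hu | tr)
}

#' Reconstruct 2x2 tables from printed rounded percentages
#'
#' @param printed a named list with any of `sensitivity`, `specificity`,
#'   `ppv`, `npv`; each entry is `c(value, decimals)` with the value on the
#'   percentage scale as printed (e.g. `c(84.6, 1)`, `c(88, 0)`). Metrics
#'   not listed are unconstrained.
#' @param n_total total cohort size (tp + fp + fn + tn).
#' @param margin_bounds optional list with `malignant = c(lo, hi)` and/or
#'   `benign = c(lo, hi)` restricting the truth margins.
#' @param rounding rounding convention for matching; see
#'   \link{reconstruction}.
#' @return a list of [confusion_matrix()] solutions (possibly empty — empty
#'   means the printed values are jointly inconsistent for this n).
#' @examples
#' reconstruct_matrix(
#'   list(sensitivity = c(84.6, 1), specificity = c(85.7, 1),
#'        ppv = c(88, 0), npv = c(81.8, 1)),
#'   n_total = 47
#' )
#' @export
reconstruct_matrix <- function(printed, n_total, margin_bounds = NULL,
                               rounding = c("half_up", "trunc", "either")) {
  rounding <- match.arg(rounding)
  if (!is_scalar_number(n_total) || n_total <= 0) {
    stop_input("n_total must be a positive integer")
  }
  known <- c("sensitivity", "specificity", "ppv", "npv")
  if (length(setdiff(names(printed), known))) {
    stop_input("printed metrics must be among %s", paste(known, collapse = ", "))
  }
  for (v in printed) {
    if (length(v) != 2L || v[1] < 0 || v[1] > 100 || v[2] < 0) {
      stop_input("each printed entry must be c(value in [0,100], decimals)")
    }
  }

  # enumerate all compositions of n_total into four cells, vectorized
  grid <- expand.grid(tp = 0:n_total, fp = 0:n_total, fn = 0:n_total)
  grid <- grid[grid$tp + grid$fp + grid$fn <= n_total, , drop = FALSE]
  grid$tn <- n_total - grid$tp - grid$fp - grid$fn

  mal <- grid$tp + grid$fn
  ben <- grid$fp + grid$tn
  keep <- rep(TRUE, nrow(grid))
  if (!is.null(margin_bounds$malignant)) {
    keep <- keep & mal >= margin_bounds$malignant[1] &
      mal <= margin_bounds$malignant[2]
  }
  if (!is.null(margin_bounds$benign)) {
    keep <- keep & ben >= margin_bounds$benign[1] &
      ben <= margin_bounds$benign[2]
  }

  check <- function(keep, num, den, entry) {
    if (is.null(entry)) return(keep)
    # a printed value constrains the metric to be defined (denominator > 0)
    ok <- den > 0
    pct <- ifelse(ok, 100 * num / den, NA_real_)
    keep & ok & matches_printed(pct, entry[1], entry[2], rounding)
  }
  keep <- check(keep, grid$tp, mal, printed$sensitivity)
  keep <- check(keep, grid$tn, ben, printed$specificity)
  keep <- check(keep, grid$tp, grid$tp + grid$fp, printed$ppv)
  keep <- check(keep, grid$tn, grid$tn + grid$fn, printed$npv)

  sol <- grid[keep, , drop = FALSE]
  lapply(seq_len(nrow(sol)), function(i) {
    confusion_matrix(sol$tp[i], sol$fp[i], sol$fn[i], sol$tn[i])
  })
}

#' Reconstruct a single proportion from its printed rounded value
#'
#' Finds all fractions k/n (n up to `max_n`) whose percentage prints as the
#' given value at the given precision — used to recover one margin of a
#' table (e.g. a sensitivity) when the full 2x2 is not jointly consistent.
#'
#' @param value printed percentage.
#' @param decimals printed decimal places.
#' @param max_n largest denominator to search.
#' @param min_n smallest denominator to search (default 1).
#' @param rounding rounding convention; see \link{reconstruction}.
#' @return a data frame with columns `k`, `n`, `pct`.
#' @export
reconstruct_proportion <- function(value, decimals, max_n, min_n = 1,
                                   rounding = c("half_up", "trunc", "either")) {
  rounding <- match.arg(rounding)
  out <- list()
  for (n in min_n:max_n) {
    k <- 0:n
    pct <- 100 * k / n
    hit <- matches_printed(pct, value, decimals, rounding)
    if (any(hit)) {
      out[[length(out) + 1L]] <- data.frame(k = k[hit], n = n, pct = pct[hit])
    }
  }
  if (!length(out)) {
    return(data.frame(k = integer(0), n = integer(0), pct = numeric(0)))
  }
  do.call(rbind, out)
}
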
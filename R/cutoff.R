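#' Cutoff selection on a dichotomized score
#'
#' Evaluates each candidate cutoff on the cohort, dichotomizing at
#' score >= cutoff, and selects the one with the highest balanced accuracy
#' (the single-threshold ROC AUC). Candidates whose balanced accuracy is
#' within `specificity_tiebreak_tol` of the maximum are treated as tied and
#' the tie is broken by the highest specificity — a more specific cutoff is
#' preferred when accuracy is statistically indistinguishable, because the
#' clinical cost of a false positive here is an unnecessary surgery. Exact
#' remaining ties go to the first-listed candidate.
#'
#' @param scores numeric score vector.
#' @param truth `"MALIGNANT"`/`"BENIGN"` labels.
#' @param candidates candidate cutoffs (non-empty).
#' @param specificity_tiebreak_tol balanced-accuracy band within which the
#'   specificity tie-break applies; default 0 (strict maximum).
#' @return a list with `cutoff` (the selected value) and `table`, a data
#'   frame of per-candidate `cutoff, tp, fp, fn, tn, sensitivity,
#'   specificity, balanced_accuracy`.
#' @export
select_cutoff <- function(scores, truth, candidates,
                          specificity_tiebreak_tol = 0) {
  if (!length(candidates)) stop_input("no candidate cutoffs")
  truth <- parse_truth(truth)
  if (length(unique(truth)) < 2L) {
    stop_input("degenerate truths: both classes are required for cutoff selection")
  }
  rows <- lapply(candidates, function(cut) {
    m <- confusion_from_scores(scores, truth, cut)
    data.frame(
      cutoff = cut, tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn,
      sensitivity = m$tp / (m$tp + m$fn),
      specificity = m$tn / (m$tn + m$fp),
      balanced_accuracy = balanced_accuracy(m)
    )
  })
  tab <- do.call(rbind, rows)
  best_ba <- max(tab$balanced_accuracy)
  in_band <- tab$balanced_accuracy >= best_ba - specificity_tiebreak_tol - SCORE_TOL
  band <- tab[in_band, , drop = FALSE]
  pick <- band$cutoff[which.max(band$specificity)]  # which.max: first on ties
  list(cutoff = pick, table = tab)
}
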
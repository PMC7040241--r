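#' Genomic classifier score X_GC
#'
#' The genomic classifier score of a nodule is the sum of the annotated
#' weights of all its alterations, grouped into three additive terms:
#'
#' \deqn{X_{GC} = \sum_{i=1}^{n} X_{SNV/INDEL,i} + X_{GF} + X_{CNV}}
#'
#' where the first term sums over the n detected SNVs and INDELs, and the
#' fusion and CNV terms sum their respective classes. The score is an
#' additive evidence model: it is not capped at 1 and grows with every
#' additional weighted alteration, so multi-hit nodules (e.g. Hürthle cell
#' carcinomas carrying NRAS + SLX4 + ATM) can exceed 1.
#'
#' @param alterations a list of [genomic_alteration()] objects (possibly
#'   empty).
#' @param wt a [weight_table()].
#' @param nodule_id optional nodule identifier carried into the result.
#' @param warn_unknown warn once per unknown alteration (see
#'   [annotate_alteration()]).
#' @return an object of class `genomic_profile`: a list with `nodule_id`,
#'   `alterations`, the component sums `x_snv_indel`, `x_gf`, `x_cnv`, the
#'   total `x_gc`, and `unknown_identifiers` (identifiers scored by
#'   fallback).
#' @examples
#' wt <- weight_table(c("BRAF:p.Val600Glu" = 0.95, "NRAS:p.Gln61Arg" = 0.5))
#' compute_xgc(list(genomic_alteration("BRAF", "SNV", "p.Val600Glu")), wt)$x_gc
#' @export
compute_xgc <- function(alterations, wt, nodule_id = NA_character_,
                        warn_unknown = TRUE) {
  stopifnot(is.list(alterations), inherits(wt, "weight_table"))
  x_snv_indel <- 0
  x_gf <- 0
  x_cnv <- 0
  unknown <- character(0)
  for (a in alterations) {
    if (!inherits(a, "genomic_alteration")) {
      stop_input("alterations must be genomic_alteration objects")
    }
    known <- a$identifier %in% names(wt$entries)
    if (!known) unknown <- c(unknown, a$identifier)
    w <- annotate_alteration(a, wt, warn_unknown = warn_unknown && !known)
    if (a$class %in% c("SNV", "INDEL")) {
      x_snv_indel <- x_snv_indel + w
    } else if (a$class == "GENE_FUSION") {
      x_gf <- x_gf + w
    } else {
      x_cnv <- x_cnv + w
    }
  }
  structure(
    list(
      nodule_id = nodule_id,
      alterations = alterations,
      x_snv_indel = x_snv_indel,
      x_gf = x_gf,
      x_cnv = x_cnv,
      x_gc = x_snv_indel + x_gf + x_cnv,
      unknown_identifiers = unknown
    ),
    class = "genomic_profile"
  )
}

#' @export
print.genomic_profile <- function(x, ...) {
  cat(sprintf(
    "<genomic_profile> %s: x_gc = %.3g (SNV/INDEL %.3g + fusion %.3g + CNV %.3g), %d alteration(s)\n",
    x$nodule_id, x$x_gc, x$x_snv_indel, x$x_gf, x$x_cnv, length(x$alterations)
  ))
  invisible(x)
}

#' Default alteration weight table
#'
#' A built-in, editable table of association weights for the alterations
#' recurrently observed in indeterminate thyroid nodules. Weights follow the
#' usual qualitative ordering from large somatic-mutation databases
#' (TCGA-THCA, COSMIC): BRAF p.Val600Glu and activating RET point mutations
#' near 1 (essentially diagnostic of papillary/medullary carcinoma), TERT
#' promoter mutations high, RAS hotspot mutations intermediate (~0.5; found
#' in both follicular-patterned carcinomas and adenomas), PAX8-PPARG fusion
#' intermediate, and alterations shared with clearly benign nodules (GNAS,
#' ESR1, TET2) low. The exact values are illustrative defaults for the
#' scoring scheme, not database-derived ground truth; analyses that depend on
#' specific weights should pass their own table.
#'
#' @return a [weight_table()] with fallback weight 0.
#' @export
default_weight_table <- function() {
  weight_table(
    c(
      "BRAF:p.Val600Glu"   = 0.95,
      "TERT:c.1-124C>T"    = 0.85,
      "TERT:c.1-146C>T"    = 0.85,
      "RET:p.Met918Thr"    = 0.95,
      "RET:p.Cys634Arg"    = 0.90,
      "RET:deletion"       = 0.85,
      "NRAS:p.Gln61Arg"    = 0.50,
      "NRAS:p.Gln61Lys"    = 0.50,
      "HRAS:p.Gln61Arg"    = 0.50,
      "KRAS:p.Gln61Arg"    = 0.50,
      "KRAS:p.Gly12Asp"    = 0.50,
      "PAX8:PAX8-PPARG"    = 0.55,
      "SLX4:pathogenic"    = 0.30,
      "ATM:pathogenic"     = 0.30,
      "GNAS:p.Arg201Cys"   = 0.20,
      "ESR1:pathogenic"    = 0.15,
      "TET2:pathogenic"    = 0.15
    ),
    fallback_weight = 0
  )
}
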
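# Shared fixture builders. Everything is generated in code at test time.

snv <- function(gene, detail) genomic_alteration(gene, "SNV", detail)

# a small weight table exercised throughout the unit tests
test_weights <- function(fallback = 0) {
  weight_table(
    c("BRAF:p.Val600Glu" = 0.95,
      "NRAS:p.Gln61Arg" = 0.5,
      "GNAS:p.Arg201Cys" = 0.3,
      "RET:deletion" = 0.25),
    fallback_weight = fallback
  )
}

write_tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_tmp_json <- function(text) {
  path <- withr::local_tempfile(fileext = ".json",
                                .local_envir = parent.frame())
  writeLines(text, path)
  path
}

# percentage rounded half-up to one decimal, as printed tables do
round_half_up_pct <- function(k, n) {
  thyrostrat:::round_half_up(100 * k / n, 1)
}

# build a score/truth cohort realizing an exact confusion matrix at a cutoff:
# positives score `hi`, negatives score `lo`
cohort_for_matrix <- function(tp, fp, fn, tn, hi = 1, lo = 0) {
  list(
    scores = c(rep(hi, tp), rep(hi, fp), rep(lo, fn), rep(lo, tn)),
    truth = c(rep("MALIGNANT", tp), rep("BENIGN", fp),
              rep("MALIGNANT", fn), rep("BENIGN", tn))
  )
}
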
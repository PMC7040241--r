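test_that("weight tables load from TSV and JSON and validate their entries", {
  tsv <- write_tmp_tsv(c(
    "# comment line",
    "identifier\tweight\tprovenance",
    "BRAF:p.Val600Glu\t0.95\tdriver of classic PTC",
    "NRAS:p.Gln61Arg\t0.5\tshared with adenomas"
  ))
  wt <- read_weight_table(tsv)
  expect_equal(unname(wt$entries["BRAF:p.Val600Glu"]), 0.95)
  expect_equal(length(wt$entries), 2L)

  js <- write_tmp_json('{"BRAF:p.Val600Glu": 0.95}')
  wj <- read_weight_table(js)
  expect_equal(unname(wj$entries["BRAF:p.Val600Glu"]), 0.95)
  expect_equal(length(wj$entries), 1L)

  fb <- write_tmp_json('{"BRAF:p.Val600Glu": 0.95, "_fallback": 0.1}')
  expect_equal(read_weight_table(fb)$fallback_weight, 0.1)

  expect_error(read_weight_table(write_tmp_json('{"X:1": 1.3}')),
               "out of range")
  expect_error(read_weight_table(write_tmp_tsv(c(
    "identifier\tweight", "A:1\t0.5", "A:1\t0.6"
  ))), "duplicate identifier")
  expect_error(read_weight_table(write_tmp_tsv(c(
    "identifier\tweight", "A:1\tnot_a_number"
  ))), "non-numeric")
  expect_error(read_weight_table(write_tmp_tsv(c(
    "identifier\tweight", "lonely_field"
  ))), "malformed row")
  expect_error(read_weight_table(file.path(tempdir(), "absent.tsv")),
               "not found")
})

test_that("identifiers are deterministic and case-normalized on the gene only", {
  expect_equal(alteration_id(" braf ", " p.Val600Glu "), "BRAF:p.Val600Glu")
  a <- genomic_alteration("braf", "snv", "p.Val600Glu")
  expect_equal(a$identifier, "BRAF:p.Val600Glu")
  expect_equal(a$class, "SNV")
  expect_error(genomic_alteration("BRAF", "hyperechoic", "x"),
               "unknown alteration class")
})

test_that("annotation returns table weights and falls back with a warning", {
  wt <- test_weights()
  expect_equal(annotate_alteration(snv("BRAF", "p.Val600Glu"), wt), 0.95)

  unknown <- snv("TP53", "p.Arg175His")
  expect_warning(w <- annotate_alteration(unknown, wt),
                 class = "thyrostrat_unknown_alteration")
  expect_equal(w, 0)
  wt10 <- test_weights(fallback = 0.1)
  expect_equal(suppressWarnings(annotate_alteration(unknown, wt10)), 0.1)
})

test_that("X_GC sums per-class components without a cap", {
  wt <- weight_table(c("A:1" = 0.5, "B:2" = 0.3, "C:cnv" = 0.25,
                       "D:f" = 0.4))
  expect_equal(compute_xgc(list(), wt)$x_gc, 0)

  one <- compute_xgc(list(snv("A", "1")), wt)
  expect_equal(one$x_gc, 0.5)

  p <- compute_xgc(list(snv("A", "1"), snv("B", "2"),
                        genomic_alteration("C", "CNV", "cnv")), wt)
  expect_equal(p$x_snv_indel, 0.8)
  expect_equal(p$x_gf, 0)
  expect_equal(p$x_cnv, 0.25)
  expect_equal(p$x_gc, 1.05)  # exceeds 1: additive evidence, no cap

  f <- compute_xgc(list(genomic_alteration("D", "GENE_FUSION", "f"),
                        genomic_alteration("B", "INDEL", "2")), wt)
  expect_equal(f$x_gf, 0.4)
  expect_equal(f$x_snv_indel, 0.3)
})

test_that("X_GC is additive, permutation-invariant and monotone", {
  set.seed(7)
  genes <- LETTERS[1:8]
  wt <- weight_table(stats::setNames(round(runif(8), 3),
                                     paste0(genes, ":v")))
  pool <- lapply(genes, function(g) snv(g, "v"))
  for (rep in 1:20) {
    k <- sample(0:8, 1)
    idx <- sample(8, k)
    a <- pool[idx]
    split_at <- sample(0:k, 1)
    left <- a[seq_len(split_at)]
    right <- a[setdiff(seq_len(k), seq_len(split_at))]
    total <- compute_xgc(a, wt)$x_gc
    # additivity over disjoint lists
    expect_equal(compute_xgc(left, wt)$x_gc + compute_xgc(right, wt)$x_gc,
                 total)
    # permutation invariance
    expect_equal(compute_xgc(a[sample(length(a))], wt)$x_gc, total)
    # adding a positive-weight alteration strictly increases the score
    rest <- setdiff(1:8, idx)
    if (length(rest)) {
      extra <- pool[[rest[sample.int(length(rest), 1)]]]
      if (wt$entries[[extra$identifier]] > 0) {
        expect_gt(compute_xgc(c(a, list(extra)), wt)$x_gc, total)
      }
    }
  }
  # no-association limit: all-zero weights score every profile 0
  wt0 <- weight_table(stats::setNames(rep(0, 8), paste0(genes, ":v")))
  expect_equal(compute_xgc(pool, wt0)$x_gc, 0)
})
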
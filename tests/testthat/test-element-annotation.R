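# Gene-effect classification, haploinsufficiency cutoffs, heart-expression
# filter, the candidate cascade, and lncRNA tiers.

test_that("gene effects split into full, partial and none", {
  genes <- mk_genes(c("g1", "g2", "g3"), "chr1",
                    c(100, 100, 1000), c(200, 200, 1200))
  genes$chrom <- c("chr1", "chr1", "chr2")
  cnvs <- mk_cnvs("chr1", 50, 300, "deletion")
  eff <- classify_gene_effects(cnvs, genes)
  expect_equal(nrow(eff), 2L)  # chr2 gene untouched
  expect_equal(eff$effect[eff$gene_id == "g1"], "full")
  expect_equal(eff$direction[eff$gene_id == "g1"], "deleted")

  dup <- mk_cnvs("chr1", 150, 300, "duplication")
  eff2 <- classify_gene_effects(dup, genes[1, , drop = FALSE])
  expect_equal(eff2$effect, "partial")
  expect_equal(eff2$direction, "duplicated")

  # the mosaic flag is carried, never dropped
  mos <- mk_cnvs("chr1", 50, 300, "deletion", mosaic = TRUE)
  expect_true(classify_gene_effects(mos, genes[1, , drop = FALSE])$mosaic)
})

test_that("effect classes partition the genes of a chromosome", {
  set.seed(17)
  gx <- rand_gi(30)
  genes <- mk_genes(sprintf("g%02d", 1:30), gx$chrom, gx$start, gx$end)
  cnv <- mk_cnvs("chrT", 2000, 7000, "duplication")
  eff <- classify_gene_effects(cnv, genes)
  for (i in seq_len(nrow(genes))) {
    overlap <- genes$start[i] <= 7000 && genes$end[i] >= 2000
    inside <- genes$start[i] >= 2000 && genes$end[i] <= 7000
    row <- eff[eff$gene_id == genes$gene_id[i], ]
    if (!overlap) {
      expect_equal(nrow(row), 0L)
    } else {
      expect_equal(row$effect, if (inside) "full" else "partial")
    }
  }
})

test_that("olfactory-receptor and keratin-associated families are marked excluded", {
  genes <- mk_genes(c("o1", "k1", "n1"), "chr1",
                    c(100, 400, 700), c(200, 500, 800),
                    symbol = c("OR13D1", "KRTAP4-5", "ORC1"))
  cnv <- mk_cnvs("chr1", 1, 1000, "duplication")
  eff <- classify_gene_effects(cnv, genes)
  expect_equal(eff$excluded_family[match(c("o1", "k1", "n1"), eff$gene_id)],
               c(TRUE, TRUE, FALSE))  # ORC1 is not an OR-family symbol
})

test_that("haploinsufficiency cutoffs are strict and absence is never positive", {
  expect_true(is_hi_sensitive(5, NA, NA))
  expect_true(is_hi_sensitive(NA, 0.95, NA))
  expect_true(is_hi_sensitive(NA, NA, 0.2))
  expect_false(is_hi_sensitive(50, 0.90, 0.35))  # boundaries excluded
  expect_false(is_hi_sensitive(10, NA, NA))
  expect_false(is_hi_sensitive(NA, NA, NA))
  expect_equal(is_hi_sensitive(c(5, 50), c(NA, NA), c(NA, NA)),
               c(TRUE, FALSE))
})

test_that("heart expression uses >= threshold over the stage window", {
  expect_true(is_heart_expressed(c(0, 2.0, 0), threshold_tpm = 2))
  expect_false(is_heart_expressed(c(0, 0, 0), threshold_tpm = 2))
  expect_false(is_heart_expressed(c(9.9, 1), threshold_tpm = 10))
  expect_warning(res <- is_heart_expressed(numeric(0)), "not expressed")
  expect_false(res)
  g <- mk_genes("g1", "chr1", 1, 10, max_tpm = 2)
  expect_true(is_heart_expressed(g))
  # stages outside the declared window are ignored
  g$tpm_extra_adult <- 100
  expect_false(is_heart_expressed(g, 10, stage_window = STAGES))
})

test_that("the candidate cascade equals the brute-force truth table", {
  lists <- list(chd_panel = "FLAGGED")
  combos <- expand.grid(excluded = c(FALSE, TRUE),
                        reducing = c(FALSE, TRUE),
                        hi = c(FALSE, TRUE),
                        expressed = c(FALSE, TRUE),
                        flagged = c(FALSE, TRUE))
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    genes <- mk_genes("g1", "chr1", 100, 200,
                      symbol = if (cb$excluded) "OR13D1" else
                        if (cb$flagged) "FLAGGED" else "PLAIN",
                      pct_hi = if (cb$hi) 3 else 60,
                      max_tpm = if (cb$expressed) 8 else 0.1)
    # flagged and excluded are driven by the symbol; an excluded symbol can
    # never also be flagged, so skip the contradictory combinations
    if (cb$excluded && cb$flagged) next
    cnv <- mk_cnvs("chr1", 50, if (cb$reducing) 300 else 300,
                   cn_class = if (cb$reducing) "deletion" else "duplication")
    eff <- classify_gene_effects(cnv, genes)
    got <- call_candidate_genes(eff, genes, lists)
    want <- !cb$excluded && cb$reducing && cb$hi && cb$expressed && cb$flagged
    expect_identical(got$candidate, want,
                     info = paste(unlist(cb), collapse = "/"))
  }
})

test_that("full gains never qualify but breakpoint-disrupted gains can", {
  lists <- list(chd_panel = "CANDG")
  genes <- mk_genes("g1", "chr1", 100, 200, symbol = "CANDG", pct_hi = 3,
                    max_tpm = 8)
  full_dup <- mk_cnvs("chr1", 50, 300, "duplication")
  expect_false(call_candidate_genes(classify_gene_effects(full_dup, genes),
                                    genes, lists)$candidate)
  part_dup <- mk_cnvs("chr1", 150, 300, "duplication")
  expect_true(call_candidate_genes(classify_gene_effects(part_dup, genes),
                                   genes, lists)$candidate)
  # the breakpoint-gain route is a configuration switch
  th <- annotation_thresholds(partial_gain_lof = FALSE)
  expect_false(call_candidate_genes(classify_gene_effects(part_dup, genes),
                                    genes, lists, th)$candidate)
  part_del <- mk_cnvs("chr1", 150, 300, "deletion")
  expect_true(call_candidate_genes(classify_gene_effects(part_del, genes),
                                   genes, lists, th)$candidate)
})

test_that("lncRNA content is tiered at 2 and 10 TPM per CNV", {
  lnc <- mk_genes(c("l1", "l2", "l3"), "chr1", c(100, 400, 700),
                  c(200, 500, 800), biotype = "lncRNA",
                  max_tpm = c(2.5, 0.5, 0.1))
  cnv <- mk_cnvs("chr1", 1, 1000, "duplication")
  res <- annotate_lncrnas(cnv, lnc)
  expect_equal(res$per_cnv$n_lncrna, 3L)
  expect_equal(res$per_cnv$n_tier_low, 1L)
  expect_equal(res$per_cnv$n_tier_high, 0L)

  none <- annotate_lncrnas(mk_cnvs("chr2", 1, 1000, "deletion"), lnc)
  expect_equal(none$per_cnv$n_lncrna, 0L)
})

test_that("recurrent lncRNAs count once per CNV but once in unique tallies", {
  lnc <- mk_genes("l1", "chr1", 400, 500, biotype = "lncRNA", max_tpm = 12)
  cnvs <- mk_cnvs("chr1", c(100, 350), c(600, 900),
                  cn_class = c("deletion", "duplication"))
  res <- annotate_lncrnas(cnvs, lnc)
  expect_equal(nrow(res$pairs), 2L)           # counted separately per CNV
  expect_equal(unname(res$unique_counts["total"]), 1L)
  expect_equal(unname(res$unique_counts["tier_high"]), 1L)
})

test_that("the 10 TPM tier is a subset of the 2 TPM tier", {
  set.seed(29)
  gx <- rand_gi(20)
  lnc <- mk_genes(sprintf("l%02d", 1:20), gx$chrom, gx$start, gx$end,
                  biotype = "lncRNA", max_tpm = runif(20, 0, 20))
  cx <- rand_gi(6, max_w = 5000)
  cnvs <- mk_cnvs(cx$chrom, cx$start, cx$end)
  res <- annotate_lncrnas(cnvs, lnc)
  expect_true(all(res$pairs$tier_low[res$pairs$tier_high]))
  expect_true(all(res$per_cnv$n_tier_high <= res$per_cnv$n_tier_low))
  expect_true(all(res$per_cnv$n_tier_low <= res$per_cnv$n_lncrna))
})
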
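# TAD classification and the three rewiring mechanisms, checked against an
# explicit post-CNV genome-reconstruction oracle on small per-base maps.

test_that("TAD maps reject overlapping TAD intervals", {
  expect_error(
    tad_map(data.frame(chrom = "chr1", start = c(1, 50), end = c(100, 150),
                       tad_id = c("T1", "T2")),
            data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0))),
    class = "chdcnv_validation_error")
  # abutting boundaries are fine
  expect_s3_class(toy_tadmap(3), "tad_map")
})

test_that("CNVs classify as intraTAD, interTAD or unassigned", {
  tm <- toy_tadmap(4)  # TADs T1..T4 of 100 bp, 10 bp boundaries
  intra <- assign_tad_class(gi("chrT", 120, 180), tm)
  expect_equal(intra$class, "intraTAD")
  expect_equal(intra$tad_ids, "T2")

  inter <- assign_tad_class(gi("chrT", 150, 250), tm)
  expect_equal(inter$class, "interTAD")
  expect_setequal(inter$tad_ids, c("T2", "T3"))
  expect_equal(inter$reason, "endpoints_in_different_tads")

  expect_equal(assign_tad_class(gi("chr9", 100, 200), tm)$class, "unassigned")
  # beyond the last TAD: unannotated terminal gap
  expect_equal(assign_tad_class(gi("chrT", 430, 600), tm)$class, "unassigned")
})

test_that("a CNV touching but not crossing a boundary stays intraTAD", {
  tm <- toy_tadmap(4)
  # T2 spans 111-210, boundary 211-220, T3 starts 221
  touch_right <- assign_tad_class(gi("chrT", 150, 215), tm)
  expect_equal(touch_right$class, "intraTAD")
  expect_equal(touch_right$tad_ids, "T2")
  touch_left <- assign_tad_class(gi("chrT", 215, 280), tm)
  expect_equal(touch_left$class, "intraTAD")
  expect_equal(touch_left$tad_ids, "T3")
  # fully containing the boundary is interTAD even when both endpoints
  # resolve to the same TAD
  span <- assign_tad_class(gi("chrT", 211, 230), tm)
  expect_equal(span$class, "interTAD")
  expect_equal(span$reason, "contains_boundary")
})

test_that("TAD classes partition every cohort", {
  fx <- generate_fixture(fixture_config(seed = 13))
  cls <- assign_tad_classes(fx$bundle$cnvs, fx$bundle$tads)
  expect_equal(nrow(cls), nrow(fx$bundle$cnvs))
  expect_true(all(cls$tad_class %in% c("intraTAD", "interTAD", "unassigned")))
  counts <- table(factor(cls$tad_class,
                         levels = c("intraTAD", "interTAD", "unassigned")))
  expect_equal(sum(counts), nrow(fx$bundle$cnvs))
})

test_that("intraTAD CNVs over an enhancer yield dosage events with TAD targets", {
  tm <- toy_tadmap(4)
  genes <- mk_genes("g1", "chrT", 190, 205, symbol = "TARG1")
  enh <- mk_enh("e1", "chrT", 130, 140)
  del <- mk_cnvs("chrT", 120, 160, "deletion")
  ev <- intra_tad_dosage_effects(del, tm, genes, enh,
                                 list(chd_panel = "TARG1"))
  expect_equal(ev$mechanism, "intra_dosage")
  expect_equal(ev$enhancers$status, "lost")
  expect_equal(ev$genes$symbol, "TARG1")
  expect_true(ev$chd_relevant)
  expect_false(ev$requires_tandem)

  # gains change dosage upward; unflagged targets are not CHD-relevant
  dup <- mk_cnvs("chrT", 120, 160, "duplication")
  ev2 <- intra_tad_dosage_effects(dup, tm, genes, enh, list())
  expect_equal(ev2$enhancers$status, "extra_copy")
  expect_false(ev2$chd_relevant)

  # no enhancer inside the CNV: no event
  expect_null(intra_tad_dosage_effects(mk_cnvs("chrT", 150, 160, "deletion"),
                                       tm, genes, enh, list()))
  # wrong TAD context is a contract error
  expect_error(intra_tad_dosage_effects(mk_cnvs("chrT", 150, 250, "deletion"),
                                        tm, genes, enh, list()),
               class = "chdcnv_contract_error")
})

test_that("deleting a boundary gains pairs across the fused remainders", {
  tm <- toy_tadmap(4)
  genes <- mk_genes("g1", "chrT", 120, 135, symbol = "LEFTG")   # early T2
  enh <- mk_enh("e1", "chrT", 290, 298)                         # late T3
  del <- mk_cnvs("chrT", 160, 260, "deletion")                  # removes T2/T3 boundary
  ev <- fuse_tads_for_deletion(del, tm, genes, enh, list(chd_panel = "LEFTG"))
  expect_equal(ev$mechanism, "fusion_neotad")
  expect_equal(pair_key(ev$pairs), "g1|e1")
  expect_true(ev$chd_relevant)

  # deleting the enhancer as well leaves nothing to pair
  del2 <- mk_cnvs("chrT", 160, 299, "deletion")
  expect_null(fuse_tads_for_deletion(del2, tm, genes, enh, list()))

  # same pre-TAD pairs are never novel
  enh_same <- mk_enh("e2", "chrT", 140, 148)
  expect_null(fuse_tads_for_deletion(del, tm, genes, enh_same, list()))

  expect_error(fuse_tads_for_deletion(mk_cnvs("chrT", 160, 260, "duplication"),
                                      tm, genes, enh, list()),
               class = "chdcnv_contract_error")
  expect_error(fuse_tads_for_deletion(mk_cnvs("chrT", 120, 150, "deletion"),
                                      tm, genes, enh, list()),
               class = "chdcnv_contract_error")
})

test_that("fusion events match the post-deletion reconstruction oracle", {
  set.seed(51)
  L <- 4 * 110  # 4 TADs of 100 bp + 10 bp boundaries
  tm <- toy_tadmap(4)
  for (rep in 1:25) {
    # elements strictly inside TADs; deletion endpoints strictly inside TADs
    tt <- tm$tads
    place <- function(n, w) {
      k <- sample.int(nrow(tt), n, replace = TRUE)
      s <- tt$start[k] + sample.int(100 - w, n, replace = TRUE) - 1
      list(start = s, end = s + w - 1)
    }
    gp <- place(3, 8); ep <- place(3, 5)
    genes <- mk_genes(sprintf("g%d", 1:3), "chrT", gp$start, gp$end)
    enh <- mk_enh(sprintf("e%d", 1:3), "chrT", ep$start, ep$end)
    k1 <- sample.int(3, 1)
    ks <- (k1 + 1):4
    k2 <- ks[sample.int(length(ks), 1)]
    s <- tt$start[k1] + sample.int(99, 1)
    e <- tt$start[k2] + sample.int(99, 1) - 1
    if (e <= s) next
    del <- mk_cnvs("chrT", s, e, "deletion")
    if (assign_tad_class(del, tm)$class != "interTAD") next
    ev <- fuse_tads_for_deletion(del, tm, genes, enh, list())
    got <- if (is.null(ev)) character(0) else pair_key(ev$pairs)
    want <- pair_key(oracle_fusion_pairs(tm, del, genes, enh, L))
    expect_identical(got, want)
  }
})

test_that("tandem duplications across one boundary gain pairs inside the copy", {
  tm <- toy_tadmap(4)
  genes <- mk_genes("g1", "chrT", 170, 185, symbol = "NEOG")  # late T2
  enh <- mk_enh("e1", "chrT", 230, 238)                       # early T3
  dup <- mk_cnvs("chrT", 160, 260, "duplication")
  ev <- neotad_for_tandem_duplication(dup, tm, genes, enh,
                                      list(transcription_factor = "NEOG"))
  expect_equal(ev$mechanism, "tandem_dup_neotad")
  expect_true(ev$requires_tandem)
  expect_equal(pair_key(ev$pairs), "g1|e1")
  expect_true(ev$chd_relevant)

  # enhancers outside the duplicated interval cannot join the neoTAD
  enh_out <- mk_enh("e2", "chrT", 290, 298)
  expect_null(neotad_for_tandem_duplication(dup, tm, genes, enh_out, list()))

  expect_error(neotad_for_tandem_duplication(
    mk_cnvs("chrT", 160, 260, "deletion"), tm, genes, enh, list()),
    class = "chdcnv_contract_error")
})

test_that("tandem neoTAD events match the reconstruction oracle on one-boundary spans", {
  set.seed(77)
  L <- 4 * 110
  tm <- toy_tadmap(4)
  tt <- tm$tads
  for (rep in 1:25) {
    place <- function(n, w) {
      k <- sample.int(nrow(tt), n, replace = TRUE)
      s <- tt$start[k] + sample.int(100 - w, n, replace = TRUE) - 1
      list(start = s, end = s + w - 1)
    }
    gp <- place(3, 8); ep <- place(3, 5)
    genes <- mk_genes(sprintf("g%d", 1:3), "chrT", gp$start, gp$end)
    enh <- mk_enh(sprintf("e%d", 1:3), "chrT", ep$start, ep$end)
    k1 <- sample.int(3, 1)  # span exactly one boundary: k1 -> k1+1
    s <- tt$start[k1] + sample.int(99, 1)
    e <- tt$start[k1 + 1] + sample.int(99, 1) - 1
    if (e <= s) next
    dup <- mk_cnvs("chrT", s, e, "duplication")
    if (assign_tad_class(dup, tm)$class != "interTAD") next
    ev <- neotad_for_tandem_duplication(dup, tm, genes, enh, list())
    got <- if (is.null(ev)) character(0) else pair_key(ev$pairs)
    want <- pair_key(oracle_tandem_pairs(tm, dup, genes, enh, L))
    expect_identical(got, want)
  }
})

test_that("no event ever pairs a gene and enhancer from the same pre-CNV TAD", {
  fx <- generate_fixture(fixture_config(seed = 19))
  events <- predict_rewiring(fx$bundle$cnvs, fx$bundle$tads, fx$bundle$genes,
                             fx$bundle$enhancers, fx$bundle$function_lists)
  tm <- fx$bundle$tads
  for (ev in events) {
    if (is.null(ev$pairs)) next  # intra-dosage events pair within one TAD by design
    for (i in seq_len(nrow(ev$pairs))) {
      g <- fx$bundle$genes[fx$bundle$genes$gene_id == ev$pairs$gene_id[i], ]
      e <- fx$bundle$enhancers[fx$bundle$enhancers$element_id ==
                                 ev$pairs$element_id[i], ]
      gt <- tm$tads$tad_id[tm$tads$chrom == g$chrom &
                             tm$tads$start <= g$end & tm$tads$end >= g$start]
      et <- tm$tads$tad_id[tm$tads$chrom == e$chrom &
                             tm$tads$start <= e$end & tm$tads$end >= e$start]
      expect_length(intersect(gt, et), 0)
    }
  }
})
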
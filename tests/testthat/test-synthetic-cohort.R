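# Fixture generator: determinism, planted ground truth, degradation modes.

test_that("identical seed and config give byte-identical fixture files", {
  cfg <- fixture_config(seed = 7, n_patients = 15, n_genes = 25,
                        n_lncrnas = 10, n_enhancers = 6)
  fx1 <- generate_fixture(cfg)
  fx2 <- generate_fixture(cfg)
  expect_identical(fx1, fx2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_bundle(fx1$bundle, d1)
  write_bundle(fx2$bundle, d2)
  files <- list.files(d1)
  expect_identical(files, list.files(d2))
  expect_identical(unname(tools::md5sum(file.path(d1, files))),
                   unname(tools::md5sum(file.path(d2, files))))
  # a different seed changes the cohort
  fx3 <- generate_fixture(fixture_config(seed = 8, n_patients = 15,
                                         n_genes = 25, n_lncrnas = 10,
                                         n_enhancers = 6))
  expect_false(identical(fx1$bundle$cnvs, fx3$bundle$cnvs))
})

test_that("a planted recurrent pair forces its ground-truth SRO", {
  cfg <- fixture_config(seed = 1, cnv_rate_per_patient = 0,
                        planted = planted_default(
                          recurrent_pair = c(1000, 5000, 3000, 8000),
                          candidate_gene = FALSE, fusion_deletion = FALSE,
                          tandem_duplication = FALSE, intra_enhancer = FALSE,
                          known_region_cnv = FALSE, lncrna_cnv = FALSE))
  fx <- generate_fixture(cfg)
  expect_equal(nrow(fx$bundle$cnvs), 2L)
  expect_equal(fx$truth$recurrent_groups[[1]]$sro, gi("chr1", 3000, 5000))
  groups <- group_recurrent(fx$bundle$cnvs)
  expect_length(groups, 1L)
  expect_equal(groups[[1]]$sro, gi("chr1", 3000, 5000))
})

test_that("zero CNV rate with no planting yields an empty cohort", {
  fx <- generate_fixture(fixture_config(seed = 2, cnv_rate_per_patient = 0,
                                        planted = planted_none()))
  expect_equal(nrow(fx$bundle$cnvs), 0L)
  expect_length(fx$truth$recurrent_groups, 0L)
  expect_equal(nrow(fx$truth$candidate_genes), 0L)
  expect_equal(nrow(fx$truth$rewiring), 0L)
  res <- annotate_cohort(fx$bundle)
  expect_equal(res$summary$n_cnvs, 0L)
  expect_true(is.na(res$summary$pct_gains))
})

test_that("infeasible planted geometry is a config error", {
  expect_error(
    generate_fixture(fixture_config(seed = 1, chrom_length = 3000,
                                    tad_size_mean = 500,
                                    boundary_width = 50)),
    class = "chdcnv_validation_error")
  expect_error(fixture_config(n_patients = -1),
               class = "chdcnv_validation_error")
  expect_error(fixture_config(loss_fraction = 1.4),
               class = "chdcnv_validation_error")
})

test_that("degradation modes inject the advertised pathologies", {
  fx <- generate_fixture(fixture_config(seed = 5, n_patients = 12,
                                        n_genes = 20, n_lncrnas = 10,
                                        n_enhancers = 6))
  d1 <- degrade_fixture(fx$bundle, "drop_pli")
  expect_true(all(is.na(d1$genes$pli)))

  d2 <- degrade_fixture(fx$bundle, "shuffle_chrom_case")
  expect_true(any(grepl("^CHR", d2$cnvs$chrom)))
  # dialect normalization makes annotation invariant to label case
  r0 <- annotate_cohort(fx$bundle)
  r2 <- annotate_cohort(d2)
  expect_equal(r2$cnvs$interest_flags, r0$cnvs$interest_flags)
  expect_equal(r2$cnvs$tad_class, r0$cnvs$tad_class)

  d3 <- degrade_fixture(fx$bundle, "zero_length")
  expect_error(validate_bundle(d3), class = "chdcnv_validation_error")

  d4 <- degrade_fixture(fx$bundle, "unknown_chrom")
  r4 <- annotate_cohort(d4)
  expect_equal(r4$cnvs$tad_class[1], "unassigned")

  expect_error(degrade_fixture(fx$bundle, "not_a_mode"),
               class = "chdcnv_validation_error")
})

test_that("cohort gain:loss ratio converges to the configured fraction", {
  cfg <- fixture_config(seed = 11, n_chromosomes = 40, n_patients = 250,
                        cnv_rate_per_patient = 1, planted = planted_none(),
                        n_genes = 20, n_lncrnas = 10, n_enhancers = 5)
  fx <- generate_fixture(cfg)
  n <- nrow(fx$bundle$cnvs)
  expect_gt(n, 150)
  p_hat <- mean(is_loss(fx$bundle$cnvs$cn_class))
  ci <- stats::binom.test(round(p_hat * n), n)$conf.int
  expect_true(cfg$loss_fraction >= ci[1] && cfg$loss_fraction <= ci[2])
  # CNV lengths stay inside the configured log-uniform range
  w <- gi_width(fx$bundle$cnvs)
  expect_true(all(w >= cfg$size_range[1] & w <= cfg$size_range[2]))
})

test_that("planted scenarios are recovered exactly by the full pipeline", {
  fx <- generate_fixture(fixture_config(seed = 3))
  res <- annotate_cohort(fx$bundle)
  # recurrent groups
  expect_length(res$groups, length(fx$truth$recurrent_groups))
  expect_setequal(res$groups[[1]]$member_ids,
                  fx$truth$recurrent_groups[[1]]$member_ids)
  expect_equal(res$groups[[1]]$sro, fx$truth$recurrent_groups[[1]]$sro)
  expect_true(res$group_table$candidate[1])
  # candidate genes: exact set equality = precision and recall 1
  called <- unique(res$gene_evidence[res$gene_evidence$candidate,
                                     c("cnv_id", "gene_id")])
  expect_equal(called[order(called$cnv_id), ],
               fx$truth$candidate_genes[order(fx$truth$candidate_genes$cnv_id),
                                        c("cnv_id", "gene_id")],
               ignore_attr = TRUE)
  # TAD classes for every CNV
  m <- merge(res$tad_classes, fx$truth$tad_classes, by = "cnv_id")
  expect_equal(m$tad_class.x, m$tad_class.y)
  # rewiring events
  got <- res$rewiring_table[order(res$rewiring_table$cnv_id),
                            c("cnv_id", "mechanism", "genes", "elements",
                              "requires_tandem", "chd_relevant")]
  want <- fx$truth$rewiring[order(fx$truth$rewiring$cnv_id), ]
  expect_equal(got, want, ignore_attr = TRUE)
  # interest flags
  mi <- merge(res$cnvs[, c("cnv_id", "of_interest")], fx$truth$interest,
              by = "cnv_id")
  expect_equal(mi$of_interest.x, mi$of_interest.y)
  # per-CNV lncRNA tiers
  lc <- res$lncrna$per_cnv
  for (i in seq_len(nrow(fx$truth$lncrna))) {
    row <- lc[lc$cnv_id == fx$truth$lncrna$cnv_id[i], ]
    expect_equal(row$n_lncrna, fx$truth$lncrna$n_lncrna[i])
    expect_equal(row$n_tier_low, fx$truth$lncrna$n_tier_low[i])
    expect_equal(row$n_tier_high, fx$truth$lncrna$n_tier_high[i])
  }
})
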
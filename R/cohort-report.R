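# Cohort descriptives, the final "CNV of interest" call, and report
# generation.

#' Round half-up
#'
#' Cohort percentages are conventionally printed rounded half-up to one
#' decimal (e.g. 17/87 -> 19.5%), unlike R's default round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Percentage of a count pair, rounded half-up to one decimal
#'
#' @param num,den Numerator and denominator counts.
#' @param digits Decimal places.
#' @return Numeric percentage, or `NA` when the denominator is zero
#'   (percentages of an empty cohort are undefined, not zero).
#' @export
percent_half_up <- function(num, den, digits = 1) {
  ifelse(den == 0, NA_real_, round_half_up(100 * num / den, digits))
}

#' Final interest call for an annotated CNV
#'
#' A CNV is "of interest" iff any of the four evidence routes fired:
#' membership in a candidate-SRO recurrent group, at least one candidate
#' gene, at least one developing-heart-expressed lncRNA, or at least one
#' CHD-relevant rewiring event. Bare overlap with a known dosage-sensitive
#' region does not confer interest (those CNVs are reported separately),
#' unless `include_known_region` is switched on.
#'
#' @param candidate_region,candidate_gene,heart_lncrna,tad_rewiring Logical
#'   vectors of per-CNV evidence flags.
#' @param known_region_overlap Logical vector; only consulted when
#'   `include_known_region = TRUE`.
#' @param include_known_region Should known-region overlap alone confer
#'   interest?
#' @return Logical vector.
#' @export
call_of_interest <- function(candidate_region, candidate_gene, heart_lncrna,
                             tad_rewiring, known_region_overlap = FALSE,
                             include_known_region = FALSE) {
  out <- candidate_region | candidate_gene | heart_lncrna | tad_rewiring
  if (include_known_region) out <- out | known_region_overlap
  out
}

#' Annotate a whole cohort
#'
#' Runs the full reassessment on a track bundle: known-region annotation,
#' recurrence grouping with candidate-SRO calls, the candidate-gene
#' cascade, two-tier lncRNA scoring, TAD classification and rewiring
#' prediction, and the final per-CNV interest call. X-linked CNVs in female
#' patients are flagged with a skewed-X-inactivation caveat, never
#' filtered.
#'
#' @param bundle A [track_bundle()] (validated on entry).
#' @param thresholds From [annotation_thresholds()].
#' @param min_fraction Minimum region fraction for known-region hits.
#' @param min_reciprocal Reciprocal-overlap threshold for the
#'   population-track comparison.
#' @param include_known_region Forwarded to [call_of_interest()].
#' @param par PAR equivalence windows.
#' @return A `chd_annotation` list: `cnvs` (one row per CNV with all
#'   evidence flags), `region_hits`, `groups`, `group_table`,
#'   `gene_evidence`, `lncrna`, `tad_classes`, `rewiring_events`,
#'   `rewiring_table`, `summary`, `patients`, `thresholds`.
#' @export
annotate_cohort <- function(bundle, thresholds = annotation_thresholds(),
                            min_fraction = 0, min_reciprocal = 0.5,
                            include_known_region = FALSE,
                            par = par_regions()) {
  bundle <- validate_bundle(bundle)
  cnvs <- bundle$cnvs
  region_hits <- annotate_known_regions(cnvs, bundle$known_regions,
                                        min_fraction, par)
  groups <- group_recurrent(cnvs, bundle$genes, par)
  group_table <- recurrent_group_table(groups, bundle$population,
                                       bundle$known_regions, min_reciprocal,
                                       par)
  effects <- classify_gene_effects(cnvs, bundle$genes, par,
                                   thresholds$excluded_family_patterns)
  gene_evidence <- call_candidate_genes(effects, bundle$genes,
                                        bundle$function_lists, thresholds)
  lnc <- annotate_lncrnas(cnvs, bundle$lncrnas, thresholds, par)
  tad_classes <- assign_tad_classes(cnvs, bundle$tads)
  events <- predict_rewiring(cnvs, bundle$tads, bundle$genes,
                             bundle$enhancers, bundle$function_lists)
  ev_tbl <- rewiring_table(events)

  ann <- cnvs
  ann$length_bp <- gi_width(cnvs)
  ann$tad_class <- tad_classes$tad_class[match(ann$cnv_id, tad_classes$cnv_id)]
  ann$known_region_overlap <- ann$cnv_id %in% region_hits$cnv_id
  ann$group_id <- rep(NA_character_, nrow(ann))
  ann$candidate_region <- rep(FALSE, nrow(ann))
  for (g in groups) {
    i <- ann$cnv_id %in% g$member_ids
    ann$group_id[i] <- g$group_id
    cand <- group_table$candidate[group_table$group_id == g$group_id]
    ann$candidate_region[i] <- isTRUE(cand)
  }
  cand_by_cnv <- gene_evidence[gene_evidence$candidate, , drop = FALSE]
  ann$n_candidate_genes <- vapply(ann$cnv_id, function(id) {
    length(unique(cand_by_cnv$gene_id[cand_by_cnv$cnv_id == id]))
  }, integer(1))
  ann$candidate_genes <- vapply(ann$cnv_id, function(id) {
    paste(unique(cand_by_cnv$symbol[cand_by_cnv$cnv_id == id]), collapse = ",")
  }, character(1))
  ann$candidate_gene <- ann$n_candidate_genes > 0L
  pc <- lnc$per_cnv
  m <- match(ann$cnv_id, pc$cnv_id)
  ann$n_lncrna <- pc$n_lncrna[m]
  ann$n_lncrna_tier_low <- pc$n_tier_low[m]
  ann$n_lncrna_tier_high <- pc$n_tier_high[m]
  ann$heart_lncrna <- ann$n_lncrna_tier_low > 0L
  chd_ev <- ev_tbl[ev_tbl$chd_relevant, , drop = FALSE]
  ann$tad_rewiring <- ann$cnv_id %in% chd_ev$cnv_id
  ann$x_inactivation_caveat <- ann$chrom == "chrX" & ann$sex == "F"
  ann$of_interest <- call_of_interest(ann$candidate_region, ann$candidate_gene,
                                      ann$heart_lncrna, ann$tad_rewiring,
                                      ann$known_region_overlap,
                                      include_known_region)
  flag_cols <- c("candidate_region", "candidate_gene", "heart_lncrna",
                 "tad_rewiring", "known_region_overlap")
  ann$interest_flags <- vapply(seq_len(nrow(ann)), function(i) {
    paste(flag_cols[unlist(ann[i, flag_cols])], collapse = ";")
  }, character(1))

  out <- structure(list(cnvs = ann, region_hits = region_hits,
                        groups = groups, group_table = group_table,
                        gene_evidence = gene_evidence, lncrna = lnc,
                        tad_classes = tad_classes, rewiring_events = events,
                        rewiring_table = ev_tbl, patients = bundle$patients,
                        thresholds = thresholds),
                   class = "chd_annotation")
  out$summary <- summarize_cohort(out, bundle$patients)
  out
}

#' Cohort summary statistics
#'
#' Deterministic descriptive statistics over an annotated cohort: CNV
#' class and loss/gain tallies with percentages (half-up, one decimal),
#' size statistics in kb, inheritance tallies, per-patient CNV counts, TAD
#' class tallies, and interest tallies per phenotype group. An empty
#' cohort yields zero counts with absent (`NA`) percentages.
#'
#' @param annotated A `chd_annotation` (or a list with an annotated `cnvs`
#'   data.frame).
#' @param patients data.frame with `patient_id`, `phenotype_group`.
#' @return A named list of counts, percentages and size statistics.
#' @export
summarize_cohort <- function(annotated, patients) {
  ann <- annotated$cnvs
  n <- nrow(ann)
  n_losses <- sum(is_loss(ann$cn_class))
  n_gains <- sum(is_gain(ann$cn_class))
  kb <- function(x) round_half_up(x / 1000, 2)
  size_stats <- function(bp) {
    if (length(bp) == 0L) {
      return(list(mean_kb = NA_real_, min_kb = NA_real_, max_kb = NA_real_,
                  median_kb = NA_real_))
    }
    list(mean_kb = kb(mean(bp)), min_kb = kb(min(bp)), max_kb = kb(max(bp)),
         median_kb = kb(stats::median(bp)))
  }
  per_patient <- table(factor(ann$patient_id,
                              levels = unique(ann$patient_id)))
  pp <- if (length(per_patient)) as.integer(per_patient) else integer(0)
  groups <- list()
  for (ph in PHENOTYPE_GROUPS) {
    sub <- ann[ann$phenotype_group == ph, , drop = FALSE]
    n_pat <- sum(patients$phenotype_group == ph)
    cases <- unique(sub$patient_id[sub$of_interest])
    groups[[ph]] <- list(
      n_patients = n_pat,
      n_cnvs = nrow(sub),
      n_losses = sum(is_loss(sub$cn_class)),
      n_gains = sum(is_gain(sub$cn_class)),
      pct_losses = percent_half_up(sum(is_loss(sub$cn_class)), nrow(sub)),
      pct_gains = percent_half_up(sum(is_gain(sub$cn_class)), nrow(sub)),
      size = size_stats(sub$length_bp),
      n_of_interest = sum(sub$of_interest),
      n_cases_of_interest = length(cases),
      pct_cases_of_interest = percent_half_up(length(cases), n_pat))
  }
  list(
    n_patients = nrow(patients),
    n_cnvs = n,
    n_losses = n_losses,
    n_gains = n_gains,
    pct_losses = percent_half_up(n_losses, n),
    pct_gains = percent_half_up(n_gains, n),
    n_deletions = sum(ann$cn_class == "deletion"),
    n_duplications = sum(ann$cn_class == "duplication"),
    n_triplications = sum(ann$cn_class == "triplication"),
    n_mosaic = sum(ann$mosaic),
    size = size_stats(ann$length_bp),
    size_gains = size_stats(ann$length_bp[is_gain(ann$cn_class)]),
    size_losses = size_stats(ann$length_bp[is_loss(ann$cn_class)]),
    inheritance = list(
      n_inherited = sum(ann$inheritance == "inherited"),
      n_de_novo = sum(ann$inheritance == "de_novo"),
      n_unknown = sum(ann$inheritance == "unknown"),
      pct_inherited = percent_half_up(sum(ann$inheritance == "inherited"), n),
      pct_de_novo = percent_half_up(sum(ann$inheritance == "de_novo"), n),
      pct_unknown = percent_half_up(sum(ann$inheritance == "unknown"), n)),
    per_patient_cnvs = list(
      n_patients_with_cnv = length(pp),
      min = if (length(pp)) min(pp) else NA_integer_,
      max = if (length(pp)) max(pp) else NA_integer_,
      median = if (length(pp)) stats::median(pp) else NA_real_),
    tad = list(
      n_intra = sum(ann$tad_class == "intraTAD"),
      n_inter = sum(ann$tad_class == "interTAD"),
      n_unassigned = sum(ann$tad_class == "unassigned")),
    interest = list(
      n_of_interest = sum(ann$of_interest),
      n_candidate_region = sum(ann$candidate_region),
      n_candidate_gene_cnvs = sum(ann$candidate_gene),
      n_heart_lncrna_cnvs = sum(ann$heart_lncrna),
      n_tad_rewiring_cnvs = sum(ann$tad_rewiring),
      n_known_region_cnvs = sum(ann$known_region_overlap)),
    by_phenotype = groups)
}

#' Write the per-CNV and per-gene evidence report
#'
#' `format = "tsv"` writes `cnv_annotations.tsv` (one row per CNV with all
#' evidence flags, deterministic column order) and `gene_evidence.tsv`;
#' `format = "json"` writes the same content as one `report.json`.
#'
#' @param result A `chd_annotation` from [annotate_cohort()].
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` or `"json"`.
#' @return The paths written, invisibly.
#' @export
write_report <- function(result, dir, format = c("tsv", "json")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- result$cnvs[order(result$cnvs$cnv_id), , drop = FALSE]
  ge <- result$gene_evidence[order(result$gene_evidence$cnv_id,
                                   result$gene_evidence$gene_id), , drop = FALSE]
  if (format == "tsv") {
    paths <- file.path(dir, c("cnv_annotations.tsv", "gene_evidence.tsv"))
    a <- ann
    a$start <- fmt_num(a$start); a$end <- fmt_num(a$end)
    a$length_bp <- fmt_num(a$length_bp)
    utils::write.table(a, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ge, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    paths <- file.path(dir, "report.json")
    jsonlite::write_json(list(cnvs = ann, gene_evidence = ge,
                              summary = result$summary),
                         paths, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(paths)
}

#' Render the full report set for a cohort
#'
#' Writes, deterministically: `known_region_hits.tsv` (known-region overlap
#' table), `recurrent_groups.tsv` (one row per recurrent group with SRO and
#' candidate call), `cnv_annotations.tsv` and `gene_evidence.tsv` (via
#' [write_report()]), `lncrna_pairs.tsv`, `rewiring_events.tsv`,
#' `chromosome_map.tsv` (per-chromosome CNV map with interest marks), and
#' `flow_counts.json` with the cohort flow tallies.
#'
#' @param result A `chd_annotation` from [annotate_cohort()].
#' @param outdir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
render_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  hits <- result$region_hits[order(result$region_hits$cnv_id,
                                   result$region_hits$region), , drop = FALSE]
  p1 <- wt(hits, "known_region_hits.tsv")
  gt <- result$group_table
  gt$sro_start <- fmt_num(gt$sro_start)
  gt$sro_end <- fmt_num(gt$sro_end)
  p2 <- wt(gt, "recurrent_groups.tsv")
  p34 <- write_report(result, outdir, format = "tsv")
  lp <- result$lncrna$pairs
  p5 <- wt(lp[order(lp$cnv_id, lp$gene_id), , drop = FALSE], "lncrna_pairs.tsv")
  p6 <- wt(result$rewiring_table, "rewiring_events.tsv")
  ann <- result$cnvs[order(result$cnvs$chrom, result$cnvs$start), , drop = FALSE]
  cmap <- data.frame(chrom = ann$chrom, start = fmt_num(ann$start),
                     end = fmt_num(ann$end), cn_class = ann$cn_class,
                     cnv_id = ann$cnv_id, interest_flags = ann$interest_flags,
                     of_interest = ann$of_interest)
  p7 <- wt(cmap, "chromosome_map.tsv")
  p8 <- file.path(outdir, "flow_counts.json")
  s <- result$summary
  flow <- list(
    patients = list(total = s$n_patients,
                    SCHD = s$by_phenotype$SCHD$n_patients,
                    ICHD = s$by_phenotype$ICHD$n_patients),
    cnvs = list(total = s$n_cnvs, losses = s$n_losses, gains = s$n_gains,
                SCHD = s$by_phenotype$SCHD$n_cnvs,
                ICHD = s$by_phenotype$ICHD$n_cnvs),
    tad = s$tad,
    evidence = s$interest)
  jsonlite::write_json(flow, p8, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(p1, p2, p34, p5, p6, p7, p8))
}
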
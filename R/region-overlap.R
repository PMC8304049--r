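# CNV overlap with known dosage-sensitive regions, cohort recurrence, and
# candidate-region calls on the smallest region of overlap.

#' Annotate CNVs against known pathogenic/dosage-sensitive regions
#'
#' Reports one hit per (CNV, region) pair with any overlap at least
#' `min_fraction` of the region (default 0, i.e. any overlap: clinically
#' meaningful hits occur down to fractions of a percent of large regions).
#' Losses are matched against the region's haploinsufficiency evidence
#' score, gains against its triplosensitivity score.
#'
#' @param cnvs A CNV table.
#' @param regions Known regions: `chrom`, `start`, `end`, `name`,
#'   `hi_score`, `ts_score` (and optionally `chd_link`).
#' @param min_fraction Minimum covered fraction of the region in `[0, 1]`.
#' @param par PAR equivalence windows.
#' @return data.frame with `cnv_id`, `region`, `fraction`, `pct_label`
#'   (half-up to one decimal, as conventionally printed), `matched_score`
#'   and `score_type` (`HI`/`TS`).
#' @export
annotate_known_regions <- function(cnvs, regions, min_fraction = 0,
                                   par = par_regions()) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  empty <- data.frame(cnv_id = character(0), region = character(0),
                      fraction = numeric(0), pct_label = character(0),
                      score_type = character(0), matched_score = numeric(0))
  if (nrow(cnvs) == 0L || nrow(regions) == 0L) return(empty)
  cn <- par_normalize(cnvs, par)
  rg <- par_normalize(regions, par)
  hits <- find_hits(cn, rg)
  if (length(hits) == 0L) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(cn$end[qi], rg$end[si]) - pmax(cn$start[qi], rg$start[si]) + 1
  fraction <- ov / (rg$end[si] - rg$start[si] + 1)
  loss <- is_loss(cnvs$cn_class[qi])
  out <- data.frame(cnv_id = cnvs$cnv_id[qi],
                    region = regions$name[si],
                    fraction = fraction,
                    pct_label = sprintf("%.1f%%", round_half_up(100 * fraction, 1)),
                    score_type = ifelse(loss, "HI", "TS"),
                    matched_score = ifelse(loss, regions$hi_score[si],
                                           regions$ts_score[si]))
  out[out$fraction >= min_fraction & out$fraction > 0, , drop = FALSE]
}

#' Group recurrent CNVs across the cohort
#'
#' Single-linkage grouping on at least one base pair of overlap (after PAR
#' equivalence mapping): the maximal connected components of the interval
#' overlap graph, retained when they have two or more members. Copy-number
#' class is deliberately not required to match — recurrent regions mix
#' deletions and duplications. Each group's SRO is the fold of
#' [gi_intersect()] over its members; single-linkage chains need not share
#' a common core, so groups with an empty SRO are retained and flagged.
#'
#' @param cnvs A CNV table.
#' @param genes Optional protein-coding gene table used to list the genes
#'   overlapping each SRO.
#' @param par PAR equivalence windows.
#' @return A list of recurrent groups; each group is a list with
#'   `group_id`, `member_ids`, `members` (CNV rows), `sro` (interval table,
#'   possibly empty), `sro_empty`, `sro_label` (mixed-chromosome SROs are
#'   labelled e.g. `"chrX/Y"`), and `genes_in_sro`.
#' @export
group_recurrent <- function(cnvs, genes = NULL, par = par_regions()) {
  if (nrow(cnvs) < 2L) return(list())
  cn <- par_normalize(cnvs, par)
  gr <- as_granges(cn)
  # reduce with min.gapwidth = 0 merges only on >=1 bp overlap (not
  # adjacency); membership in a reduced range = single-linkage component
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  comp <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(gr, red))
  groups <- list()
  for (k in sort(unique(comp))) {
    idx <- which(comp == k)
    if (length(idx) < 2L) next
    members <- cnvs[idx, , drop = FALSE]
    sro <- gi_sro(members[, c("chrom", "start", "end")], par = par)
    chroms <- unique(members$chrom)
    label <- if (length(chroms) > 1L) {
      paste0("chr", paste(sub("^chr", "", sort(chroms)), collapse = "/"))
    } else {
      chroms
    }
    genes_in_sro <- character(0)
    if (!is.null(genes) && !gi_is_empty(sro) && nrow(genes)) {
      gn <- par_normalize(genes, par)
      genes_in_sro <- genes$symbol[overlaps_iv(gn, sro)]
    }
    groups[[length(groups) + 1L]] <-
      list(group_id = sprintf("rg_%02d", length(groups) + 1L),
           member_ids = members$cnv_id, members = members, sro = sro,
           sro_empty = gi_is_empty(sro), sro_label = label,
           genes_in_sro = genes_in_sro)
  }
  groups
}

#' Is a recurrent group's SRO a candidate region?
#'
#' TRUE iff (i) the SRO is non-empty, (ii) it does not overlap any known
#' dosage-sensitive region, and (iii) no population-track CNV reaches the
#' reciprocal-overlap threshold with it (the reproducible stand-in for a
#' manual "comparable CNV in population databases" lookup). The rationale
#' string records the first criterion that failed.
#'
#' @param group A recurrent group from [group_recurrent()].
#' @param population_cnvs Interval table of population/benign CNVs.
#' @param known_regions Known-region table (see
#'   [annotate_known_regions()]).
#' @param min_reciprocal Reciprocal-overlap threshold in `(0, 1]`.
#' @param par PAR equivalence windows.
#' @return A list with `candidate` (logical) and `rationale` (character).
#' @export
candidate_sro <- function(group, population_cnvs, known_regions,
                          min_reciprocal = 0.5, par = par_regions()) {
  if (is.null(group) || length(group$member_ids %||% character(0)) == 0L) {
    stop_validation("candidate_sro() requires a non-empty recurrent group")
  }
  stopifnot(min_reciprocal > 0, min_reciprocal <= 1)
  sro <- group$sro
  if (gi_is_empty(sro)) {
    return(list(candidate = FALSE, rationale = "empty SRO (single-linkage chain without common core)"))
  }
  if (nrow(known_regions)) {
    kn <- par_normalize(known_regions, par)
    hit <- overlaps_iv(kn, par_normalize(sro, par))
    if (any(hit)) {
      return(list(candidate = FALSE,
                  rationale = sprintf("SRO overlaps known dosage-sensitive region %s",
                                      known_regions$name[which(hit)[1]])))
    }
  }
  if (nrow(population_cnvs)) {
    ro <- vapply(seq_len(nrow(population_cnvs)), function(i) {
      reciprocal_overlap(sro, population_cnvs[i, , drop = FALSE], par = par)
    }, numeric(1))
    if (any(ro >= min_reciprocal)) {
      return(list(candidate = FALSE,
                  rationale = sprintf("comparable population CNV (reciprocal overlap %.2f >= %.2f)",
                                      max(ro), min_reciprocal)))
    }
  }
  list(candidate = TRUE,
       rationale = "non-empty SRO, no known-region overlap, no comparable population CNV")
}

#' Summarize recurrent groups as a table
#'
#' One row per group, in the layout of a recurrent-region report: members,
#' SRO coordinates, protein-coding genes in the SRO, candidate flag and
#' rationale.
#'
#' @param groups List from [group_recurrent()].
#' @param population_cnvs,known_regions,min_reciprocal,par Passed to
#'   [candidate_sro()].
#' @return data.frame with one row per recurrent group.
#' @export
recurrent_group_table <- function(groups, population_cnvs, known_regions,
                                  min_reciprocal = 0.5, par = par_regions()) {
  if (length(groups) == 0L) {
    return(data.frame(group_id = character(0), n_members = integer(0),
                      member_ids = character(0), sro_label = character(0),
                      sro_start = numeric(0), sro_end = numeric(0),
                      sro_empty = logical(0), genes_in_sro = character(0),
                      candidate = logical(0), rationale = character(0)))
  }
  do.call(rbind, lapply(groups, function(g) {
    cs <- candidate_sro(g, population_cnvs, known_regions, min_reciprocal, par)
    data.frame(group_id = g$group_id, n_members = length(g$member_ids),
               member_ids = paste(g$member_ids, collapse = ","),
               sro_label = g$sro_label,
               sro_start = if (g$sro_empty) NA_real_ else g$sro$start,
               sro_end = if (g$sro_empty) NA_real_ else g$sro$end,
               sro_empty = g$sro_empty,
               genes_in_sro = paste(g$genes_in_sro, collapse = ","),
               candidate = cs$candidate, rationale = cs$rationale)
  }))
}
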
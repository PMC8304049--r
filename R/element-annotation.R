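# The candidate-gene cascade: per-gene CNV effect, dosage-sensitivity
# cutoffs, developing-heart expression, gene-function membership; plus
# two-tier lncRNA scoring.

#' Default annotation thresholds
#'
#' The three haploinsufficiency cutoffs are positive arguments with strict
#' comparisons: %HI < 10, pLI > 0.90, o/e upper bound < 0.35. Expression is
#' compared with `>=` (a threshold *of* 2 TPM reached in at least one
#' developmental stage of the heart window). `lncrna_tiers` gives the two
#' lncRNA expression tiers in TPM.
#'
#' @param pct_hi,pli,oe_upper Haploinsufficiency cutoffs.
#' @param tpm Protein-coding heart-expression threshold (TPM).
#' @param lncrna_tiers Two lncRNA expression tiers (TPM).
#' @param partial_gain_lof Should partial duplications/triplications count as
#'   potentially loss-of-function (breakpoint disruption)? Full gains never
#'   qualify via the haploinsufficiency route.
#' @param stage_window Character vector of stage labels forming the
#'   developing-heart window, or `NULL` to use every `tpm_` column of the
#'   gene table (the tables emitted by this package only carry the window
#'   stages).
#' @param excluded_family_patterns Regexes of gene-family symbols excluded
#'   from candidate evaluation (olfactory receptor and keratin-associated
#'   protein families by default).
#' @return A named list of thresholds.
#' @export
annotation_thresholds <- function(pct_hi = 10, pli = 0.90, oe_upper = 0.35,
                                  tpm = 2, lncrna_tiers = c(2, 10),
                                  partial_gain_lof = TRUE,
                                  stage_window = NULL,
                                  excluded_family_patterns = c("^OR[0-9]", "^KRTAP")) {
  list(pct_hi = pct_hi, pli = pli, oe_upper = oe_upper, tpm = tpm,
       lncrna_tiers = sort(lncrna_tiers), partial_gain_lof = partial_gain_lof,
       stage_window = stage_window,
       excluded_family_patterns = excluded_family_patterns)
}

is_excluded_family <- function(symbol, patterns = c("^OR[0-9]", "^KRTAP")) {
  Reduce(`|`, lapply(patterns, grepl, x = symbol), rep(FALSE, length(symbol)))
}

direction_of <- function(cn_class) {
  c(deletion = "deleted", duplication = "duplicated",
    triplication = "triplicated")[cn_class]
}

#' Classify the effect of each CNV on each overlapped gene
#'
#' A gene fully contained in a CNV is affected in full; a gene overlapped
#' but not contained is disrupted by a breakpoint (partial). Disjoint pairs
#' yield no row. The mosaic flag is copied from the CNV; members of excluded
#' gene families (OR*/KRTAP*) are marked so downstream candidate evaluation
#' can disregard them.
#'
#' @param cnvs A CNV table.
#' @param genes A gene table (any biotype).
#' @param par PAR equivalence windows (see [par_normalize()]).
#' @param excluded_family_patterns Symbol regexes of disregarded families.
#' @return data.frame with one row per overlapping (CNV, gene) pair:
#'   `cnv_id`, `gene_id`, `symbol`, `effect` (`full`/`partial`), `direction`
#'   (`deleted`/`duplicated`/`triplicated`), `mosaic`, `excluded_family`.
#' @importFrom S4Vectors queryHits subjectHits
#' @export
classify_gene_effects <- function(cnvs, genes, par = par_regions(),
                                  excluded_family_patterns = c("^OR[0-9]", "^KRTAP")) {
  empty <- data.frame(cnv_id = character(0), gene_id = character(0),
                      symbol = character(0), effect = character(0),
                      direction = character(0), mosaic = logical(0),
                      excluded_family = logical(0))
  if (nrow(cnvs) == 0L || nrow(genes) == 0L) return(empty)
  cn <- par_normalize(cnvs, par)
  gn <- par_normalize(genes, par)
  hits <- find_hits(cn, gn)
  if (length(hits) == 0L) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  full <- cn$start[qi] <= gn$start[si] & gn$end[si] <= cn$end[qi]
  data.frame(cnv_id = cnvs$cnv_id[qi],
             gene_id = genes$gene_id[si],
             symbol = genes$symbol[si],
             effect = ifelse(full, "full", "partial"),
             direction = unname(direction_of(cnvs$cn_class[qi])),
             mosaic = cnvs$mosaic[qi],
             excluded_family = is_excluded_family(genes$symbol[si],
                                                  excluded_family_patterns))
}

#' Haploinsufficiency sensitivity from dosage scores
#'
#' TRUE iff any present score passes its cutoff: `%HI < 10`, `pLI > 0.90`,
#' or o/e upper bound `< 0.35` (strict comparisons; defaults from
#' [annotation_thresholds()]). Absent scores never satisfy a criterion —
#' absence of evidence is not evidence.
#'
#' @param pct_hi,pli,oe_upper Numeric vectors of scores (`NA` = absent).
#' @param thresholds Cutoffs, as from [annotation_thresholds()].
#' @return Logical vector.
#' @export
is_hi_sensitive <- function(pct_hi, pli, oe_upper,
                            thresholds = annotation_thresholds()) {
  (!is.na(pct_hi) & pct_hi < thresholds$pct_hi) |
    (!is.na(pli) & pli > thresholds$pli) |
    (!is.na(oe_upper) & oe_upper < thresholds$oe_upper)
}

stage_cols <- function(genes, stage_window = NULL) {
  cols <- grep("^tpm_", names(genes), value = TRUE)
  if (!is.null(stage_window)) {
    cols <- intersect(paste0("tpm_", stage_window), cols)
  }
  cols
}

max_tpm <- function(genes, stage_window = NULL) {
  cols <- stage_cols(genes, stage_window)
  if (length(cols) == 0L || nrow(genes) == 0L) {
    return(rep(NA_real_, nrow(genes)))
  }
  m <- as.matrix(genes[, cols, drop = FALSE])
  apply(m, 1L, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
}

#' Expression in the developing heart window
#'
#' TRUE iff the maximum TPM over the developmental stages of the heart
#' window (four weeks post conception through neonate) reaches the
#' threshold (`>=`). Genes with an empty/all-missing profile are FALSE,
#' with a warning.
#'
#' @param genes A gene table with `tpm_<stage>` columns, or a numeric
#'   vector of per-stage TPM values for a single gene.
#' @param threshold_tpm Expression threshold in TPM.
#' @param stage_window Optional stage labels restricting the window.
#' @return Logical vector (one element per gene).
#' @export
is_heart_expressed <- function(genes, threshold_tpm = 2, stage_window = NULL) {
  if (is.numeric(genes)) {
    if (length(genes) == 0L || all(is.na(genes))) {
      warning("empty expression profile treated as not expressed", call. = FALSE)
      return(FALSE)
    }
    return(max(genes, na.rm = TRUE) >= threshold_tpm)
  }
  mt <- max_tpm(genes, stage_window)
  if (anyNA(mt)) {
    warning(sprintf("%d gene(s) with empty expression profile treated as not expressed",
                    sum(is.na(mt))), call. = FALSE)
  }
  !is.na(mt) & mt >= threshold_tpm
}

#' Call candidate CHD genes from classified effects
#'
#' A (CNV, gene) effect nominates a candidate gene iff all five predicates
#' hold: (i) the gene is not in an excluded family; (ii) the effect
#' plausibly reduces dosage or function — a full deletion, or any
#' breakpoint disruption (partial deletion always; partial
#' duplication/triplication when `partial_gain_lof` is on); full
#' duplications/triplications never qualify via the haploinsufficiency
#' route; (iii) the gene is haploinsufficiency-sensitive
#' ([is_hi_sensitive()]); (iv) it is expressed in the developing heart at
#' the TPM threshold ([is_heart_expressed()]); (v) it appears in at least
#' one gene-function list. The returned evidence trail records every
#' predicate per effect.
#'
#' @param effects Output of [classify_gene_effects()] (protein-coding rows).
#' @param genes Protein-coding gene table.
#' @param function_lists Named list of gene-symbol vectors.
#' @param thresholds From [annotation_thresholds()].
#' @return data.frame: one row per effect with logical columns
#'   `not_excluded`, `dosage_reducing`, `hi_sensitive`, `heart_expressed`,
#'   `function_flagged`, the matched `function_flags`, and `candidate`.
#' @export
call_candidate_genes <- function(effects, genes, function_lists = list(),
                                 thresholds = annotation_thresholds()) {
  if (nrow(effects) == 0L) {
    out <- effects
    for (col in c("not_excluded", "dosage_reducing", "hi_sensitive",
                  "heart_expressed", "function_flagged", "candidate")) {
      out[[col]] <- logical(0)
    }
    out$function_flags <- character(0)
    return(out)
  }
  gi_idx <- match(effects$gene_id, genes$gene_id)
  if (anyNA(gi_idx)) {
    stop_validation("effects reference gene_ids absent from the gene table")
  }
  g <- genes[gi_idx, , drop = FALSE]
  hi <- is_hi_sensitive(g$pct_hi, g$pli, g$oe_upper, thresholds)
  expr <- suppressWarnings(
    is_heart_expressed(g, thresholds$tpm, thresholds$stage_window))
  flags <- vapply(g$symbol, function(s) {
    paste(names(function_lists)[vapply(function_lists, function(l) s %in% l,
                                       logical(1))], collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  dosage_reducing <-
    (effects$effect == "full" & effects$direction == "deleted") |
    (effects$effect == "partial" &
       (effects$direction == "deleted" | thresholds$partial_gain_lof))
  out <- effects
  out$not_excluded <- !effects$excluded_family
  out$dosage_reducing <- dosage_reducing
  out$hi_sensitive <- hi
  out$heart_expressed <- expr
  out$function_flagged <- nzchar(flags)
  out$function_flags <- flags
  out$candidate <- out$not_excluded & out$dosage_reducing & out$hi_sensitive &
    out$heart_expressed & out$function_flagged
  out
}

#' Per-CNV lncRNA content at two expression tiers
#'
#' Counts every lncRNA gene fully contained in or disrupted by each CNV
#' (any overlap), and the subsets reaching the two developing-heart
#' expression tiers (default 2 and 10 TPM). A lncRNA inside several CNVs is
#' counted once per CNV; cohort-unique tallies are also reported.
#'
#' @param cnvs A CNV table.
#' @param lncrnas A lncRNA gene table with `tpm_<stage>` columns.
#' @param thresholds From [annotation_thresholds()] (`lncrna_tiers`,
#'   `stage_window`).
#' @param par PAR equivalence windows.
#' @return A list with `pairs` (one row per CNV-lncRNA overlap with
#'   `max_tpm`, `tier_low`, `tier_high`), `per_cnv` (counts per CNV), and
#'   `unique_counts` (cohort-level unique gene tallies).
#' @export
annotate_lncrnas <- function(cnvs, lncrnas, thresholds = annotation_thresholds(),
                             par = par_regions()) {
  tiers <- thresholds$lncrna_tiers
  empty_pairs <- data.frame(cnv_id = character(0), gene_id = character(0),
                            symbol = character(0), max_tpm = numeric(0),
                            tier_low = logical(0), tier_high = logical(0))
  per_cnv_of <- function(pairs) {
    n <- vapply(cnvs$cnv_id, function(id) sum(pairs$cnv_id == id), integer(1))
    n2 <- vapply(cnvs$cnv_id, function(id) sum(pairs$cnv_id == id & pairs$tier_low),
                 integer(1))
    n10 <- vapply(cnvs$cnv_id, function(id) sum(pairs$cnv_id == id & pairs$tier_high),
                  integer(1))
    data.frame(cnv_id = cnvs$cnv_id, n_lncrna = n, n_tier_low = n2,
               n_tier_high = n10)
  }
  if (nrow(cnvs) == 0L || nrow(lncrnas) == 0L) {
    return(list(pairs = empty_pairs, per_cnv = per_cnv_of(empty_pairs),
                unique_counts = c(total = 0L, tier_low = 0L, tier_high = 0L)))
  }
  cn <- par_normalize(cnvs, par)
  ln <- par_normalize(lncrnas, par)
  hits <- find_hits(cn, ln)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  mt <- max_tpm(lncrnas, thresholds$stage_window)
  pairs <- data.frame(cnv_id = cnvs$cnv_id[qi],
                      gene_id = lncrnas$gene_id[si],
                      symbol = lncrnas$symbol[si],
                      max_tpm = mt[si])
  pairs$tier_low <- !is.na(pairs$max_tpm) & pairs$max_tpm >= tiers[1]
  pairs$tier_high <- !is.na(pairs$max_tpm) & pairs$max_tpm >= tiers[2]
  list(pairs = pairs,
       per_cnv = per_cnv_of(pairs),
       unique_counts = c(total = length(unique(pairs$gene_id)),
                         tier_low = length(unique(pairs$gene_id[pairs$tier_low])),
                         tier_high = length(unique(pairs$gene_id[pairs$tier_high]))))
}
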
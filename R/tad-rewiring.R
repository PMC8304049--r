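# TAD context of CNVs and predicted gene-enhancer rewiring.
#
# Three mechanisms are modelled: dosage change of an enhancer inside an
# intact TAD (intraTAD CNVs), fusion of the flanking TAD remainders when a
# deletion removes a boundary (interTAD deletions), and neoTAD formation by
# a duplicated boundary when an interTAD duplication occurred in tandem.
# Orientation/insertion site is unknowable from array or shallow-WGS calls,
# so tandem is an assumption, always reported as `requires_tandem = TRUE`.

#' Construct/validate a TAD map
#'
#' Per chromosome the TADs must be sorted and non-overlapping; boundary
#' intervals separate (or flank) them and may abut TADs but not overlap
#' other boundaries ambiguously. Bases covered by neither a TAD nor a
#' boundary (e.g. telomeric gaps, chromosomes without calls) are
#' unannotated.
#'
#' @param tads data.frame with `chrom`, `start`, `end`, `tad_id`.
#' @param boundaries data.frame with `chrom`, `start`, `end`.
#' @return A `tad_map` object.
#' @export
tad_map <- function(tads, boundaries) {
  tads$chrom <- norm_chrom(tads$chrom)
  boundaries$chrom <- norm_chrom(boundaries$chrom)
  validate_gi(tads, "TAD")
  validate_gi(boundaries, "TAD boundary")
  if (is.null(tads$tad_id)) {
    stop_validation("TAD table requires a tad_id column")
  }
  ord <- order(tads$chrom, tads$start)
  tads <- tads[ord, , drop = FALSE]
  rownames(tads) <- NULL
  for (chr in unique(tads$chrom)) {
    tt <- tads[tads$chrom == chr, , drop = FALSE]
    if (nrow(tt) > 1L && any(tt$start[-1] <= tt$end[-nrow(tt)])) {
      stop_validation(sprintf("overlapping TAD intervals on %s: TADs must tile without overlap", chr))
    }
  }
  boundaries <- boundaries[order(boundaries$chrom, boundaries$start), , drop = FALSE]
  rownames(boundaries) <- NULL
  structure(list(tads = tads, boundaries = boundaries), class = "tad_map")
}

# locate a single base: list(kind = "tad"|"boundary"|"unannotated", tad_id)
locate_point <- function(tm, chrom, pos) {
  tt <- tm$tads[tm$tads$chrom == chrom, , drop = FALSE]
  hit <- which(tt$start <= pos & pos <= tt$end)
  if (length(hit)) {
    return(list(kind = "tad", tad_id = tt$tad_id[hit[1]]))
  }
  bb <- tm$boundaries[tm$boundaries$chrom == chrom, , drop = FALSE]
  if (nrow(bb) && any(bb$start <= pos & pos <= bb$end)) {
    return(list(kind = "boundary", tad_id = NA_character_))
  }
  list(kind = "unannotated", tad_id = NA_character_)
}

# endpoint inside a boundary is assigned the flanking TAD on the interior
# side (toward the CNV body): a CNV touching but not crossing a boundary
# stays intraTAD
resolve_endpoint <- function(tm, chrom, pos, side = c("start", "end")) {
  side <- match.arg(side)
  loc <- locate_point(tm, chrom, pos)
  if (loc$kind != "boundary") return(loc)
  tt <- tm$tads[tm$tads$chrom == chrom, , drop = FALSE]
  if (side == "start") {
    nxt <- which(tt$start > pos) # interior side is rightward
    if (length(nxt)) {
      return(list(kind = "tad", tad_id = tt$tad_id[nxt[1]], via_boundary = TRUE))
    }
  } else {
    prv <- which(tt$end < pos) # interior side is leftward
    if (length(prv)) {
      return(list(kind = "tad", tad_id = tt$tad_id[prv[length(prv)]],
                  via_boundary = TRUE))
    }
  }
  list(kind = "unannotated", tad_id = NA_character_)
}

#' Classify a CNV by TAD context
#'
#' A CNV is `intraTAD` when both endpoints resolve to the same TAD,
#' `interTAD` when they resolve to different TADs or the CNV fully contains
#' at least one boundary interval, and `unassigned` when either endpoint
#' lies in an unannotated region (telomeric gap or a chromosome without TAD
#' calls). An endpoint inside a boundary interval is assigned the flanking
#' TAD on the interior side, so a CNV touching but not crossing a boundary
#' stays intraTAD.
#'
#' @param cnv Single-row CNV (or interval) table.
#' @param tm A [tad_map()].
#' @return A list with `class` (`"intraTAD"`, `"interTAD"`, `"unassigned"`),
#'   `tad_ids` (involved TADs, outermost first), and `reason` (which
#'   condition triggered an interTAD call).
#' @export
assign_tad_class <- function(cnv, tm) {
  stopifnot(nrow(cnv) == 1L)
  l <- resolve_endpoint(tm, cnv$chrom, cnv$start, "start")
  r <- resolve_endpoint(tm, cnv$chrom, cnv$end, "end")
  if (l$kind == "unannotated" || r$kind == "unannotated") {
    return(list(class = "unassigned", tad_ids = character(0), reason = "unannotated_endpoint"))
  }
  bb <- tm$boundaries[tm$boundaries$chrom == cnv$chrom, , drop = FALSE]
  contains_boundary <- nrow(bb) > 0L &&
    any(cnv$start <= bb$start & bb$end <= cnv$end)
  tt <- tm$tads[tm$tads$chrom == cnv$chrom, , drop = FALSE]
  involved <- tt$tad_id[tt$tad_id %in% c(l$tad_id, r$tad_id) |
                          (tt$start >= cnv$start & tt$end <= cnv$end)]
  if (l$tad_id == r$tad_id && !contains_boundary) {
    return(list(class = "intraTAD", tad_ids = l$tad_id, reason = "same_tad"))
  }
  reason <- if (l$tad_id != r$tad_id) "endpoints_in_different_tads" else "contains_boundary"
  list(class = "interTAD", tad_ids = involved, reason = reason)
}

#' Classify every CNV in a table by TAD context
#'
#' @param cnvs A CNV table.
#' @param tm A [tad_map()].
#' @return data.frame with `cnv_id`, `tad_class`, `tad_ids`
#'   (comma-separated), `reason`.
#' @export
assign_tad_classes <- function(cnvs, tm) {
  if (nrow(cnvs) == 0L) {
    return(data.frame(cnv_id = character(0), tad_class = character(0),
                      tad_ids = character(0), reason = character(0)))
  }
  res <- lapply(seq_len(nrow(cnvs)), function(i) {
    a <- assign_tad_class(cnvs[i, , drop = FALSE], tm)
    data.frame(cnv_id = cnvs$cnv_id[i], tad_class = a$class,
               tad_ids = paste(a$tad_ids, collapse = ","), reason = a$reason)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

# elements (gene or enhancer rows) overlapping / contained in an interval
overlaps_iv <- function(x, iv) {
  x$chrom == iv$chrom & x$start <= iv$end & x$end >= iv$start
}

contained_iv <- function(x, iv) {
  x$chrom == iv$chrom & x$start >= iv$start & x$end <= iv$end
}

# pre-CNV TAD ids overlapped by each element row, as a list of character
origin_tads <- function(x, tm) {
  lapply(seq_len(nrow(x)), function(i) {
    tt <- tm$tads[tm$tads$chrom == x$chrom[i], , drop = FALSE]
    tt$tad_id[tt$start <= x$end[i] & tt$end >= x$start[i]]
  })
}

flagged_symbols <- function(function_lists) {
  unique(unlist(function_lists, use.names = FALSE))
}

rewiring_event <- function(cnv_id, mechanism, enhancers, genes,
                           requires_tandem, chd_relevant) {
  structure(list(cnv_id = cnv_id, mechanism = mechanism,
                 enhancers = enhancers, genes = genes,
                 requires_tandem = requires_tandem,
                 chd_relevant = chd_relevant),
            class = "rewiring_event")
}

#' Dosage effects of an intraTAD CNV on enhancers within its TAD
#'
#' An intraTAD CNV that covers an enhancer changes the enhancer's dosage
#' (lost for deletions, extra copies for gains); candidate target genes are
#' the genes of the same TAD outside the CNV, whose regulatory input — not
#' dosage — changes. The event is CHD-relevant when any such gene carries a
#' function-list flag.
#'
#' @param cnv Single-row CNV table.
#' @param tm A [tad_map()].
#' @param genes Protein-coding gene table.
#' @param enhancers Enhancer table (`element_id`, `heart_positive`).
#' @param function_lists Named list of gene symbol vectors.
#' @return A `rewiring_event`, or `NULL` when no enhancer overlaps the CNV.
#' @export
intra_tad_dosage_effects <- function(cnv, tm, genes, enhancers,
                                     function_lists = list()) {
  a <- assign_tad_class(cnv, tm)
  if (a$class != "intraTAD") {
    stop_contract("intra_tad_dosage_effects() requires an intraTAD CNV")
  }
  hit <- enhancers[overlaps_iv(enhancers, cnv), , drop = FALSE]
  if (nrow(hit) == 0L) return(NULL)
  tad <- tm$tads[tm$tads$tad_id == a$tad_ids[1], , drop = FALSE]
  targ <- genes[overlaps_iv(genes, tad) & !overlaps_iv(genes, cnv), , drop = FALSE]
  status <- if (is_loss(cnv$cn_class)) "lost" else "extra_copy"
  flg <- flagged_symbols(function_lists)
  enh_df <- data.frame(element_id = hit$element_id, status = status,
                       heart_positive = hit$heart_positive)
  gene_df <- data.frame(gene_id = targ$gene_id, symbol = targ$symbol,
                        status = "regulatory_input_changed",
                        flagged = targ$symbol %in% flg)
  rewiring_event(cnv$cnv_id %||% NA_character_, "intra_dosage", enh_df,
                 gene_df, requires_tandem = FALSE,
                 chd_relevant = any(gene_df$flagged))
}

#' Gene-enhancer pairs gained by TAD fusion after an interTAD deletion
#'
#' Deleting a boundary fuses the remainder of the leftmost involved TAD
#' (left of the deletion) with the remainder of the rightmost involved TAD
#' (right of the deletion). Gained pairs are gene-enhancer pairs that both
#' survive the deletion, lie in the fused domain, and originated in
#' different pre-CNV TADs. Interior TADs of a multi-TAD deletion contribute
#' only elements surviving in the outer remainders.
#'
#' @inheritParams intra_tad_dosage_effects
#' @return A `rewiring_event` whose `pairs` element lists gained
#'   gene-enhancer pairs, or `NULL` when no pair is gained.
#' @export
fuse_tads_for_deletion <- function(cnv, tm, genes, enhancers,
                                   function_lists = list()) {
  if (!is_loss(cnv$cn_class)) {
    stop_contract("fuse_tads_for_deletion() requires a deletion")
  }
  a <- assign_tad_class(cnv, tm)
  if (a$class != "interTAD") {
    stop_contract("fuse_tads_for_deletion() requires an interTAD CNV")
  }
  tt <- tm$tads[tm$tads$tad_id %in% a$tad_ids, , drop = FALSE]
  ltad <- tt[which.min(tt$start), , drop = FALSE]
  rtad <- tt[which.max(tt$end), , drop = FALSE]
  remainders <- gi_empty()
  if (ltad$start <= cnv$start - 1) {
    remainders <- rbind(remainders,
                        data.frame(chrom = cnv$chrom, start = ltad$start,
                                   end = cnv$start - 1))
  }
  if (cnv$end + 1 <= rtad$end) {
    remainders <- rbind(remainders,
                        data.frame(chrom = cnv$chrom, start = cnv$end + 1,
                                   end = rtad$end))
  }
  in_domain <- function(x) {
    if (nrow(remainders) == 0L) return(rep(FALSE, nrow(x)))
    Reduce(`|`, lapply(seq_len(nrow(remainders)), function(i) {
      overlaps_iv(x, remainders[i, , drop = FALSE])
    }))
  }
  g <- genes[!overlaps_iv(genes, cnv) & in_domain(genes), , drop = FALSE]
  e <- enhancers[!overlaps_iv(enhancers, cnv) & in_domain(enhancers), , drop = FALSE]
  build_gained_pairs(cnv, "fusion_neotad", g, e, tm, function_lists,
                     requires_tandem = FALSE)
}

#' Gene-enhancer pairs inside the neoTAD of a tandem duplication
#'
#' An interTAD duplication that occurred in tandem duplicates the boundary,
#' creating a neoTAD whose content is exactly the duplicated copy of the
#' CNV interval. Gained pairs are gene-enhancer pairs both fully inside the
#' duplicated interval that originated in different pre-CNV TADs. Because
#' array/shallow-WGS calls cannot establish orientation, events always carry
#' `requires_tandem = TRUE`.
#'
#' @inheritParams intra_tad_dosage_effects
#' @return A `rewiring_event`, or `NULL` when no pair is gained.
#' @export
neotad_for_tandem_duplication <- function(cnv, tm, genes, enhancers,
                                          function_lists = list()) {
  if (!is_gain(cnv$cn_class)) {
    stop_contract("neotad_for_tandem_duplication() requires a duplication or triplication")
  }
  a <- assign_tad_class(cnv, tm)
  if (a$class != "interTAD") {
    stop_contract("neotad_for_tandem_duplication() requires an interTAD CNV")
  }
  g <- genes[contained_iv(genes, cnv), , drop = FALSE]
  e <- enhancers[contained_iv(enhancers, cnv), , drop = FALSE]
  build_gained_pairs(cnv, "tandem_dup_neotad", g, e, tm, function_lists,
                     requires_tandem = TRUE)
}

# pairs whose pre-CNV TAD sets are disjoint (novelty requirement)
build_gained_pairs <- function(cnv, mechanism, g, e, tm, function_lists,
                               requires_tandem) {
  if (nrow(g) == 0L || nrow(e) == 0L) return(NULL)
  gt <- origin_tads(g, tm)
  et <- origin_tads(e, tm)
  flg <- flagged_symbols(function_lists)
  pairs <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    keep <- vapply(seq_len(nrow(e)),
                   function(j) length(intersect(gt[[i]], et[[j]])) == 0L,
                   logical(1))
    if (!any(keep)) return(NULL)
    data.frame(gene_id = g$gene_id[i], symbol = g$symbol[i],
               element_id = e$element_id[keep],
               heart_positive = e$heart_positive[keep],
               gene_flagged = g$symbol[i] %in% flg)
  }))
  if (is.null(pairs) || nrow(pairs) == 0L) return(NULL)
  ev <- rewiring_event(
    cnv$cnv_id %||% NA_character_, mechanism,
    enhancers = unique(data.frame(element_id = pairs$element_id,
                                  status = "gained",
                                  heart_positive = pairs$heart_positive)),
    genes = unique(data.frame(gene_id = pairs$gene_id, symbol = pairs$symbol,
                              status = "exposed_to_novel_enhancer",
                              flagged = pairs$gene_flagged)),
    requires_tandem = requires_tandem,
    chd_relevant = any(pairs$gene_flagged))
  ev$pairs <- pairs
  ev
}

#' Predict rewiring events for a whole cohort
#'
#' Dispatches each CNV by TAD class and copy-number class: intraTAD CNVs to
#' [intra_tad_dosage_effects()], interTAD deletions to
#' [fuse_tads_for_deletion()], interTAD gains to
#' [neotad_for_tandem_duplication()]. Unassigned CNVs yield no event.
#'
#' @param cnvs A CNV table.
#' @param tm A [tad_map()].
#' @param genes,enhancers,function_lists See [intra_tad_dosage_effects()].
#' @return A list of `rewiring_event` objects (possibly empty).
#' @export
predict_rewiring <- function(cnvs, tm, genes, enhancers,
                             function_lists = list()) {
  events <- list()
  for (i in seq_len(nrow(cnvs))) {
    cnv <- cnvs[i, , drop = FALSE]
    a <- assign_tad_class(cnv, tm)
    ev <- if (a$class == "intraTAD") {
      intra_tad_dosage_effects(cnv, tm, genes, enhancers, function_lists)
    } else if (a$class == "interTAD" && is_loss(cnv$cn_class)) {
      fuse_tads_for_deletion(cnv, tm, genes, enhancers, function_lists)
    } else if (a$class == "interTAD") {
      neotad_for_tandem_duplication(cnv, tm, genes, enhancers, function_lists)
    } else {
      NULL
    }
    if (!is.null(ev)) events[[length(events) + 1L]] <- ev
  }
  events
}

#' Flatten rewiring events to a table
#'
#' @param events List of `rewiring_event` objects.
#' @return data.frame with one row per event-level record.
#' @export
rewiring_table <- function(events) {
  if (length(events) == 0L) {
    return(data.frame(cnv_id = character(0), mechanism = character(0),
                      n_enhancers = integer(0), n_genes = integer(0),
                      genes = character(0), elements = character(0),
                      requires_tandem = logical(0), chd_relevant = logical(0)))
  }
  do.call(rbind, lapply(events, function(ev) {
    data.frame(cnv_id = ev$cnv_id, mechanism = ev$mechanism,
               n_enhancers = nrow(ev$enhancers), n_genes = nrow(ev$genes),
               genes = paste(ev$genes$symbol, collapse = ","),
               elements = paste(ev$enhancers$element_id, collapse = ","),
               requires_tandem = ev$requires_tandem,
               chd_relevant = ev$chd_relevant)
  }))
}
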
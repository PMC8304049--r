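# Independent brute-force oracles and small fixture builders. Oracles work
# per base on toy chromosomes (<= a few kb) and never share code with the
# interval algebra or the TAD module they check.

# --- per-base interval oracles -------------------------------------------

bf_intersect <- function(a, b, L = 10000) {
  if (a$chrom != b$chrom) return(gi_empty())
  base <- seq_len(L)
  hit <- base >= a$start & base <= a$end & base >= b$start & base <= b$end
  if (!any(hit)) return(gi_empty())
  gi(a$chrom, min(base[hit]), max(base[hit]))
}

bf_sro <- function(x, L = 10000) {
  if (length(unique(x$chrom)) > 1) return(gi_empty())
  base <- seq_len(L)
  hit <- rep(TRUE, L)
  for (i in seq_len(nrow(x))) {
    hit <- hit & base >= x$start[i] & base <= x$end[i]
  }
  if (!any(hit)) return(gi_empty())
  gi(x$chrom[1], min(base[hit]), max(base[hit]))
}

bf_coverage <- function(region, cnv, L = 10000) {
  if (region$chrom != cnv$chrom) return(0)
  base <- region$start:region$end
  mean(base >= cnv$start & base <= cnv$end)
}

# random intervals on a toy chromosome
rand_gi <- function(n, chrom = "chrT", L = 10000, max_w = 4000) {
  s <- sample.int(L - 10, n, replace = TRUE)
  w <- sample.int(max_w, n, replace = TRUE)
  gi(chrom, s, pmin(s + w - 1, L))
}

# --- cohort/table builders ------------------------------------------------

mk_cnvs <- function(chrom, start, end, cn_class = "deletion",
                    mosaic = FALSE, inheritance = "unknown",
                    patient_id = NULL, phenotype_group = "ICHD", sex = "M",
                    cnv_id = NULL) {
  n <- length(start)
  df <- data.frame(chrom = chrom, start = start, end = end,
                   cn_class = rep_len(cn_class, n),
                   mosaic = rep_len(mosaic, n),
                   inheritance = rep_len(inheritance, n),
                   patient_id = patient_id %||% sprintf("P%02d", seq_len(n)),
                   phenotype_group = rep_len(phenotype_group, n),
                   sex = rep_len(sex, n))
  if (!is.null(cnv_id)) df$cnv_id <- cnv_id
  cnv_table(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

STAGES <- c("wpc4", "wpc5", "wpc8", "neonate")

mk_genes <- function(gene_id, chrom, start, end, symbol = gene_id,
                     biotype = "protein_coding", pct_hi = NA_real_,
                     pli = NA_real_, oe_upper = NA_real_, max_tpm = 0) {
  n <- length(start)
  g <- data.frame(gene_id = gene_id, symbol = symbol, chrom = chrom,
                  start = start, end = end, strand = "+",
                  biotype = rep_len(biotype, n),
                  pct_hi = rep_len(pct_hi, n), pli = rep_len(pli, n),
                  oe_upper = rep_len(oe_upper, n))
  for (s in STAGES) g[[paste0("tpm_", s)]] <- 0
  g$tpm_wpc8 <- rep_len(max_tpm, n)
  g
}

mk_enh <- function(element_id, chrom, start, end, heart_positive = FALSE) {
  data.frame(chrom = chrom, start = start, end = end,
             element_id = element_id,
             heart_positive = rep_len(heart_positive, length(start)))
}

# evenly tiled toy TAD map: n TADs of `tw` bp separated by `bw` bp boundaries
toy_tadmap <- function(n = 4, tw = 100, bw = 10, chrom = "chrT") {
  starts <- (seq_len(n) - 1) * (tw + bw) + 1
  tad_map(data.frame(chrom = chrom, start = starts, end = starts + tw - 1,
                     tad_id = sprintf("T%d", seq_len(n))),
          data.frame(chrom = chrom, start = starts[-n] + tw,
                     end = starts[-n] + tw + bw - 1))
}

# --- post-CNV genome reconstruction oracles ------------------------------

# per-base domain label: tad_id, "b" (boundary) or "gap"
domain_labels <- function(tm, chrom, L) {
  lab <- rep("gap", L)
  tt <- tm$tads[tm$tads$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(tt))) lab[tt$start[i]:tt$end[i]] <- tt$tad_id[i]
  bb <- tm$boundaries[tm$boundaries$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(bb))) lab[bb$start[i]:bb$end[i]] <- "b"
  lab
}

# contiguous unblocked runs -> post-CNV domain ids (NA on boundary/gap bases)
post_domains <- function(lab) {
  blocked <- lab %in% c("b", "gap")
  dom <- rep(NA_integer_, length(lab))
  cur <- 0L
  for (i in seq_along(lab)) {
    if (blocked[i]) next
    if (i == 1L || blocked[i - 1L]) cur <- cur + 1L
    dom[i] <- cur
  }
  dom
}

# pre-CNV TAD ids overlapping an element
pre_tads_of <- function(lab, s, e) {
  setdiff(unique(lab[s:e]), c("b", "gap"))
}

# gained gene-enhancer pairs after a deletion: pairs whose surviving bases
# share a post-deletion domain but shared no pre-deletion TAD
oracle_fusion_pairs <- function(tm, del, genes, enhancers, L) {
  lab <- domain_labels(tm, del$chrom, L)
  keep <- setdiff(seq_len(L), del$start:del$end)
  dom <- post_domains(lab[keep])
  dom_of <- function(s, e) {
    idx <- which(keep >= s & keep <= e)
    if (length(idx) != e - s + 1) return(integer(0))  # partially deleted
    unique(stats::na.omit(dom[idx]))
  }
  out <- NULL
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(enhancers))) {
      gd <- dom_of(genes$start[i], genes$end[i])
      ed <- dom_of(enhancers$start[j], enhancers$end[j])
      share_post <- length(intersect(gd, ed)) > 0
      share_pre <- length(intersect(pre_tads_of(lab, genes$start[i], genes$end[i]),
                                    pre_tads_of(lab, enhancers$start[j],
                                                enhancers$end[j]))) > 0
      if (share_post && !share_pre) {
        out <- rbind(out, data.frame(gene_id = genes$gene_id[i],
                                     element_id = enhancers$element_id[j]))
      }
    }
  }
  out %||% data.frame(gene_id = character(0), element_id = character(0))
}

# gained pairs after a tandem duplication: rebuild the post-duplication base
# sequence explicitly ([1..end][start..end][end+1..L]) and test whether full
# copies of both elements share a post domain they did not share pre-CNV
oracle_tandem_pairs <- function(tm, dup, genes, enhancers, L) {
  lab <- domain_labels(tm, dup$chrom, L)
  orig <- c(seq_len(dup$end), dup$start:dup$end,
            if (dup$end < L) (dup$end + 1):L)
  dom <- post_domains(lab[orig])
  copies_of <- function(s, e) {
    w <- e - s + 1
    hits <- which(orig >= s & orig <= e)
    runs <- split(hits, cumsum(c(1, diff(hits) != 1)))
    doms <- integer(0)
    for (r in runs) {
      if (length(r) == w) {  # a complete copy
        d <- unique(stats::na.omit(dom[r]))
        if (length(d) == 1) doms <- c(doms, d)
      }
    }
    doms
  }
  out <- NULL
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(enhancers))) {
      share_post <- length(intersect(copies_of(genes$start[i], genes$end[i]),
                                     copies_of(enhancers$start[j],
                                               enhancers$end[j]))) > 0
      share_pre <- length(intersect(pre_tads_of(lab, genes$start[i], genes$end[i]),
                                    pre_tads_of(lab, enhancers$start[j],
                                                enhancers$end[j]))) > 0
      if (share_post && !share_pre) {
        out <- rbind(out, data.frame(gene_id = genes$gene_id[i],
                                     element_id = enhancers$element_id[j]))
      }
    }
  }
  out %||% data.frame(gene_id = character(0), element_id = character(0))
}

pair_key <- function(df) {
  sort(paste(df$gene_id, df$element_id, sep = "|"))
}
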
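# Synthetic fixture bundles: a toy genome with TAD tiling, gene/lncRNA/
# enhancer tracks, a known-region track, a population track, and a CNV
# cohort with planted ground-truth scenarios, so the whole cascade is
# testable without external downloads.
#
# Planted scenarios occupy dedicated chromosomes (chr1..chr7); chr8 carries
# the background lncRNAs, enhancers and the population track but no CNVs;
# chr9 onwards carry background CNVs in disjoint per-CNV slots, so planted
# ground truth cannot be contaminated by accidental background recurrence
# or rewiring.

STAGE_LABELS <- c("wpc4", "wpc5", "wpc6", "wpc7", "wpc8", "wpc9", "wpc10",
                  "wpc11", "wpc12", "wpc13", "wpc16", "wpc18", "wpc20",
                  "neonate")

#' Planted-scenario switches for the fixture generator
#'
#' Each switch plants one ground-truth scenario: a recurrent CNV pair with
#' a known SRO, a fully deleted candidate gene, an interTAD deletion
#' removing one boundary (fusion), an interTAD tandem duplication (neoTAD),
#' an intraTAD deletion covering one enhancer, a CNV inside a known
#' dosage-sensitive region, and a CNV containing lncRNAs at both expression
#' tiers.
#'
#' @param recurrent_pair `TRUE` for the default pair, or a numeric vector
#'   `c(start1, end1, start2, end2)` of coordinates on the first chromosome.
#' @param candidate_gene,fusion_deletion,tandem_duplication,intra_enhancer,known_region_cnv,lncrna_cnv
#'   Logical switches.
#' @return Named list of switches.
#' @export
planted_default <- function(recurrent_pair = TRUE, candidate_gene = TRUE,
                            fusion_deletion = TRUE, tandem_duplication = TRUE,
                            intra_enhancer = TRUE, known_region_cnv = TRUE,
                            lncrna_cnv = TRUE) {
  list(recurrent_pair = recurrent_pair, candidate_gene = candidate_gene,
       fusion_deletion = fusion_deletion,
       tandem_duplication = tandem_duplication,
       intra_enhancer = intra_enhancer, known_region_cnv = known_region_cnv,
       lncrna_cnv = lncrna_cnv)
}

#' @rdname planted_default
#' @export
planted_none <- function() {
  planted_default(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
}

#' Configuration for the synthetic fixture generator
#'
#' Defaults emulate the shape of a reported clinical CNV-US cohort: CNV
#' lengths log-uniform between 6.66 kb and 5.08 Mb, losses about 30% of
#' calls with gains split ~15:1 between duplications and triplications,
#' inheritance shown for ~59% of calls with ~4% de novo, about a third of
#' patients syndromic, and TADs of ~880 kb separated by 40 kb boundary
#' bins. Identical seed and config produce byte-identical output.
#'
#' @param n_chromosomes Number of toy chromosomes (at least 9: seven planted
#'   scenario chromosomes, one element chromosome, and background).
#' @param chrom_length Length of each chromosome in bp.
#' @param tad_size_mean TAD size in bp (deterministic tiling).
#' @param boundary_width Boundary interval width in bp.
#' @param n_genes Background protein-coding genes.
#' @param n_lncrnas Background lncRNA genes.
#' @param n_enhancers Background enhancer elements.
#' @param heart_enhancer_fraction Fraction of background enhancers flagged
#'   heart-positive.
#' @param n_patients Cohort size.
#' @param cnv_rate_per_patient Mean background CNVs per patient (Poisson).
#' @param hi_pass_fraction Fraction of background genes passing the
#'   haploinsufficiency cutoffs.
#' @param expressed_fraction Fraction of background genes/lncRNAs reaching
#'   2 TPM in at least one heart-window stage.
#' @param loss_fraction Probability a background CNV is a deletion.
#' @param triplication_fraction Probability a gain is a triplication.
#' @param mosaic_fraction Probability a deletion/duplication is mosaic.
#' @param inheritance_probs Named probabilities for `inherited`, `de_novo`,
#'   `unknown`.
#' @param schd_fraction Fraction of syndromic patients.
#' @param male_fraction Fraction of male patients.
#' @param size_range CNV length range in bp (log-uniform).
#' @param planted Scenario switches from [planted_default()].
#' @param seed Integer seed; the single source of randomness.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_chromosomes = 16, chrom_length = 6e7,
                           tad_size_mean = 880e3, boundary_width = 40e3,
                           n_genes = 160, n_lncrnas = 80, n_enhancers = 25,
                           heart_enhancer_fraction = 0.1, n_patients = 60,
                           cnv_rate_per_patient = 0.5,
                           hi_pass_fraction = 0.3, expressed_fraction = 0.6,
                           loss_fraction = 0.304,
                           triplication_fraction = 6 / 96,
                           mosaic_fraction = 0.015,
                           inheritance_probs = c(inherited = 0.587,
                                                 de_novo = 0.043,
                                                 unknown = 0.37),
                           schd_fraction = 0.322, male_fraction = 0.585,
                           size_range = c(6660, 5.08e6),
                           planted = planted_default(), seed = 1L) {
  cfg <- list(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
              tad_size_mean = tad_size_mean, boundary_width = boundary_width,
              n_genes = n_genes, n_lncrnas = n_lncrnas,
              n_enhancers = n_enhancers,
              heart_enhancer_fraction = heart_enhancer_fraction,
              n_patients = n_patients,
              cnv_rate_per_patient = cnv_rate_per_patient,
              hi_pass_fraction = hi_pass_fraction,
              expressed_fraction = expressed_fraction,
              loss_fraction = loss_fraction,
              triplication_fraction = triplication_fraction,
              mosaic_fraction = mosaic_fraction,
              inheritance_probs = inheritance_probs,
              schd_fraction = schd_fraction, male_fraction = male_fraction,
              size_range = size_range, planted = planted, seed = seed)
  counts <- c(n_chromosomes, n_genes, n_lncrnas, n_enhancers, n_patients)
  if (any(counts < 0)) stop_validation("fixture counts must be >= 0")
  fr <- c(heart_enhancer_fraction, hi_pass_fraction, expressed_fraction,
          loss_fraction, triplication_fraction, mosaic_fraction,
          schd_fraction, male_fraction)
  if (any(fr < 0 | fr > 1)) stop_validation("fixture fractions must lie in [0, 1]")
  if (cnv_rate_per_patient < 0) stop_validation("cnv_rate_per_patient must be >= 0")
  structure(cfg, class = "fixture_config")
}

# deterministic TAD tiling with a terminal unannotated gap
tile_tads <- function(chrom, len, tad_size, bwidth) {
  period <- tad_size + bwidth
  n <- floor((len - tad_size) / period) + 1
  if (n < 1) {
    return(list(tads = data.frame(chrom = character(0), start = numeric(0),
                                  end = numeric(0), tad_id = character(0)),
                boundaries = gi_empty()))
  }
  starts <- (seq_len(n) - 1) * period + 1
  tads <- data.frame(chrom = chrom, start = starts,
                     end = starts + tad_size - 1,
                     tad_id = sprintf("%s_tad_%03d", chrom, seq_len(n)))
  bstarts <- tads$end[-n] + 1
  boundaries <- data.frame(chrom = chrom, start = bstarts,
                           end = bstarts + bwidth - 1)
  list(tads = tads, boundaries = boundaries)
}

# construction-side TAD classification (same convention as the analysis
# module, recomputed independently from the tiling arithmetic)
truth_tad_class <- function(tads, boundaries, chrom, s, e) {
  tt <- tads[tads$chrom == chrom, , drop = FALSE]
  bb <- boundaries[boundaries$chrom == chrom, , drop = FALSE]
  res <- function(pos, side) {
    in_tad <- which(tt$start <= pos & pos <= tt$end)
    if (length(in_tad)) return(tt$tad_id[in_tad[1]])
    in_b <- nrow(bb) && any(bb$start <= pos & pos <= bb$end)
    if (!in_b) return(NA_character_)
    if (side == "start") {
      nxt <- which(tt$start > pos)
      if (length(nxt)) return(tt$tad_id[nxt[1]])
    } else {
      prv <- which(tt$end < pos)
      if (length(prv)) return(tt$tad_id[prv[length(prv)]])
    }
    NA_character_
  }
  l <- res(s, "start"); r <- res(e, "end")
  if (is.na(l) || is.na(r)) return("unassigned")
  contains_b <- nrow(bb) > 0 && any(s <= bb$start & bb$end <= e)
  if (l == r && !contains_b) "intraTAD" else "interTAD"
}

blank_expr <- function(n) {
  m <- as.data.frame(matrix(0.1, nrow = n, ncol = length(STAGE_LABELS)))
  names(m) <- paste0("tpm_", STAGE_LABELS)
  m
}

mk_gene <- function(gene_id, symbol, chrom, start, end, biotype,
                    pct_hi = NA_real_, pli = NA_real_, oe_upper = NA_real_,
                    tpm = NULL) {
  g <- data.frame(gene_id = gene_id, symbol = symbol, chrom = chrom,
                  start = start, end = end, strand = "+", biotype = biotype,
                  pct_hi = pct_hi, pli = pli, oe_upper = oe_upper)
  expr <- blank_expr(1)
  if (!is.null(tpm)) expr[1, paste0("tpm_", names(tpm))] <- unname(tpm)
  cbind(g, expr)
}

#' Generate a synthetic track bundle with planted ground truth
#'
#' Builds the toy genome (deterministic TAD tiling with a terminal
#' unannotated gap per chromosome), all annotation tracks, a patient
#' cohort, planted scenario CNVs and a background CNV cohort, and the
#' ground truth that downstream modules must recover exactly.
#'
#' @param config A [fixture_config()].
#' @return A list with `bundle` (a [track_bundle()]) and `truth`, a list
#'   with `recurrent_groups`, `candidate_genes`, `tad_classes` (per-CNV),
#'   `rewiring` (expected events), `lncrna` (expected per-CNV tier counts)
#'   and `interest` (expected per-CNV interest flags).
#' @export
generate_fixture <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  len <- config$chrom_length
  S <- config$tad_size_mean
  B <- config$boundary_width
  period <- S + B
  any_planted <- any(vapply(config$planted, function(x) !identical(x, FALSE),
                            logical(1)))
  if (any_planted && config$n_chromosomes < 9) {
    stop_validation("planted scenarios require at least 9 chromosomes")
  }
  if (config$n_chromosomes < 1) stop_validation("need at least one chromosome")
  chroms <- paste0("chr", seq_len(config$n_chromosomes))

  tads_l <- list(); bnds_l <- list()
  for (chr in chroms) {
    t <- tile_tads(chr, len, S, B)
    tads_l[[chr]] <- t$tads; bnds_l[[chr]] <- t$boundaries
  }
  tads <- do.call(rbind, tads_l); rownames(tads) <- NULL
  boundaries <- do.call(rbind, bnds_l); rownames(boundaries) <- NULL
  tad_start <- function(k) (k - 1) * period + 1
  n_tads_per_chrom <- floor((len - S) / period) + 1
  if (any_planted && n_tads_per_chrom < 4) {
    stop_validation("planted TAD scenarios need at least 4 TADs per chromosome")
  }

  # ---- patients -----------------------------------------------------------
  n_pat <- max(config$n_patients, if (any_planted) 7L else 0L)
  patients <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n_pat)),
    phenotype_group = ifelse(stats::runif(n_pat) < config$schd_fraction,
                             "SCHD", "ICHD"),
    sex = ifelse(stats::runif(n_pat) < config$male_fraction, "M", "F"))

  genes <- list(); lncs <- list(); enh <- list()
  cnvs <- list()
  truth <- list(recurrent_groups = list(),
                candidate_genes = data.frame(cnv_id = character(0),
                                             gene_id = character(0),
                                             symbol = character(0)),
                rewiring = data.frame(cnv_id = character(0),
                                      mechanism = character(0),
                                      genes = character(0),
                                      elements = character(0),
                                      requires_tandem = logical(0),
                                      chd_relevant = logical(0)),
                lncrna = data.frame(cnv_id = character(0),
                                    n_lncrna = integer(0),
                                    n_tier_low = integer(0),
                                    n_tier_high = integer(0)))
  interest <- list()  # cnv_id -> character vector of flags
  pl_cnv <- function(chrom, start, end, cn_class, patient_i,
                     inheritance = "unknown", id) {
    if (start < 1 || end > len || end < start) {
      stop_validation(sprintf("planted CNV %s:%d-%d infeasible for chromosome length %d",
                              chrom, start, end, len))
    }
    data.frame(chrom = chrom, start = start, end = end, cn_class = cn_class,
               mosaic = FALSE, inheritance = inheritance,
               patient_id = patients$patient_id[patient_i],
               phenotype_group = patients$phenotype_group[patient_i],
               sex = patients$sex[patient_i], cnv_id = id)
  }
  p <- config$planted

  # chr1: recurrent duplication pair with known SRO
  if (!identical(p$recurrent_pair, FALSE)) {
    co <- if (is.numeric(p$recurrent_pair)) {
      p$recurrent_pair
    } else {
      w <- min(4e5, floor(len / 10))
      base <- floor(0.2 * len)
      c(base + 1, base + w, base + floor(w / 2) + 1, base + w + floor(w / 2))
    }
    cnvs$recA <- pl_cnv("chr1", co[1], co[2], "duplication", 1L, id = "cnv_recA")
    cnvs$recB <- pl_cnv("chr1", co[3], co[4], "duplication", 2L, id = "cnv_recB")
    sro <- gi_sro(gi(c("chr1", "chr1"), c(co[1], co[3]), c(co[2], co[4])))
    if (gi_is_empty(sro)) {
      stop_validation("planted recurrent pair does not overlap")
    }
    genes$sro <- mk_gene("g_sro", "SROG1", "chr1",
                         sro$start + floor(gi_width(sro) / 4),
                         min(sro$end, sro$start + floor(gi_width(sro) / 4) + 4999),
                         "protein_coding")
    truth$recurrent_groups[[1]] <- list(member_ids = c("cnv_recA", "cnv_recB"),
                                        sro = sro, candidate_region = TRUE)
    interest$cnv_recA <- "candidate_region"
    interest$cnv_recB <- "candidate_region"
  }

  # chr2: fully deleted candidate gene (all five predicates hold)
  if (isTRUE(p$candidate_gene)) {
    gs <- floor(0.3 * len) + 1
    genes$cand <- mk_gene("g_cand", "CAND1", "chr2", gs, gs + 49999,
                          "protein_coding", pct_hi = 3, pli = 0.99,
                          oe_upper = 0.2, tpm = c(wpc5 = 8))
    cnvs$cand <- pl_cnv("chr2", gs - 50000, gs + 99999, "deletion", 3L,
                        inheritance = "de_novo", id = "cnv_cand")
    truth$candidate_genes <- rbind(truth$candidate_genes,
                                   data.frame(cnv_id = "cnv_cand",
                                              gene_id = "g_cand",
                                              symbol = "CAND1"))
    interest$cnv_cand <- "candidate_gene"
  }

  # chr3: interTAD deletion spanning exactly one boundary -> TAD fusion
  if (isTRUE(p$fusion_deletion)) {
    t2 <- tad_start(2); t3 <- tad_start(3)
    del <- c(t2 + floor(S / 2), t3 + floor(S / 2))
    cnvs$fus <- pl_cnv("chr3", del[1], del[2], "deletion", 4L, id = "cnv_fus")
    genes$fus <- mk_gene("g_fus", "FUSG1", "chr3", t2 + floor(S / 10),
                         t2 + floor(S / 10) + 19999, "protein_coding",
                         tpm = c(wpc8 = 4))
    enh$fus <- data.frame(chrom = "chr3", start = t3 + floor(0.8 * S),
                          end = t3 + floor(0.8 * S) + 1999,
                          element_id = "element_fus", heart_positive = TRUE)
    truth$rewiring <- rbind(truth$rewiring,
                            data.frame(cnv_id = "cnv_fus",
                                       mechanism = "fusion_neotad",
                                       genes = "FUSG1",
                                       elements = "element_fus",
                                       requires_tandem = FALSE,
                                       chd_relevant = TRUE))
    interest$cnv_fus <- "tad_rewiring"
  }

  # chr4: interTAD tandem duplication -> neoTAD
  if (isTRUE(p$tandem_duplication)) {
    t2 <- tad_start(2); t3 <- tad_start(3)
    dup <- c(t2 + floor(S / 2), t3 + floor(S / 2))
    cnvs$neo <- pl_cnv("chr4", dup[1], dup[2], "duplication", 5L, id = "cnv_neo")
    genes$neo <- mk_gene("g_neo", "NEOG1", "chr4", t2 + floor(0.7 * S),
                         t2 + floor(0.7 * S) + 19999, "protein_coding",
                         tpm = c(wpc6 = 3))
    enh$neo <- data.frame(chrom = "chr4", start = t3 + floor(0.2 * S),
                          end = t3 + floor(0.2 * S) + 1999,
                          element_id = "element_neo", heart_positive = FALSE)
    truth$rewiring <- rbind(truth$rewiring,
                            data.frame(cnv_id = "cnv_neo",
                                       mechanism = "tandem_dup_neotad",
                                       genes = "NEOG1",
                                       elements = "element_neo",
                                       requires_tandem = TRUE,
                                       chd_relevant = TRUE))
    interest$cnv_neo <- "tad_rewiring"
  }

  # chr5: intraTAD deletion covering one enhancer; flagged gene in the TAD
  if (isTRUE(p$intra_enhancer)) {
    t2 <- tad_start(2)
    cnvs$intra <- pl_cnv("chr5", t2 + floor(0.3 * S), t2 + floor(0.5 * S),
                         "deletion", 6L, id = "cnv_intra")
    enh$intra <- data.frame(chrom = "chr5", start = t2 + floor(0.35 * S),
                            end = t2 + floor(0.35 * S) + 1999,
                            element_id = "element_intra",
                            heart_positive = FALSE)
    genes$intra <- mk_gene("g_intra", "INTG1", "chr5", t2 + floor(0.7 * S),
                           t2 + floor(0.7 * S) + 19999, "protein_coding",
                           tpm = c(wpc10 = 6))
    truth$rewiring <- rbind(truth$rewiring,
                            data.frame(cnv_id = "cnv_intra",
                                       mechanism = "intra_dosage",
                                       genes = "INTG1",
                                       elements = "element_intra",
                                       requires_tandem = FALSE,
                                       chd_relevant = TRUE))
    interest$cnv_intra <- "tad_rewiring"
  }

  # chr6: CNV inside a known dosage-sensitive region
  known_regions <- data.frame(chrom = character(0), start = numeric(0),
                              end = numeric(0), name = character(0),
                              hi_score = numeric(0), ts_score = numeric(0),
                              chd_link = character(0))
  if (isTRUE(p$known_region_cnv)) {
    rw <- min(3e6, floor(len / 4))
    rs <- floor(0.1 * len) + 1
    known_regions <- data.frame(chrom = "chr6", start = rs, end = rs + rw - 1,
                                name = "SYN-REGION-1", hi_score = 2,
                                ts_score = 1, chd_link = "debated")
    cnvs$known <- pl_cnv("chr6", rs + floor(rw / 3), rs + floor(rw / 2),
                         "duplication", 7L, id = "cnv_known")
    interest$cnv_known <- character(0)  # known-region overlap alone: not of interest
  }

  # chr7: CNV containing lncRNAs at both expression tiers
  if (isTRUE(p$lncrna_cnv)) {
    cs <- floor(0.2 * len) + 1
    cnvs$lnc <- pl_cnv("chr7", cs, cs + 499999, "duplication", 2L, id = "cnv_lnc")
    lncs$planted <- rbind(
      mk_gene("l_t2", "LNC-T2", "chr7", cs + 10000, cs + 14999, "lncRNA",
              tpm = c(wpc8 = 5)),
      mk_gene("l_t10", "LNC-T10", "chr7", cs + 100000, cs + 104999, "lncRNA",
              tpm = c(wpc10 = 12)),
      mk_gene("l_low", "LNC-LOW", "chr7", cs + 200000, cs + 204999, "lncRNA",
              tpm = c(wpc12 = 0.5)))
    truth$lncrna <- rbind(truth$lncrna,
                          data.frame(cnv_id = "cnv_lnc", n_lncrna = 3L,
                                     n_tier_low = 2L, n_tier_high = 1L))
    interest$cnv_lnc <- "heart_lncrna"
  }

  # ---- background tracks (chr8 elements, chr9+ CNVs/genes) ---------------
  bg_chroms <- chroms[seq_len(config$n_chromosomes) > 8]
  draw_expr <- function(n, expressed) {
    m <- matrix(stats::runif(n * length(STAGE_LABELS), 0, 1.5),
                nrow = n)
    hot <- sample.int(length(STAGE_LABELS), n, replace = TRUE)
    m[cbind(which(expressed), hot[expressed])] <-
      stats::runif(sum(expressed), 2.5, 50)
    m <- as.data.frame(m)
    names(m) <- paste0("tpm_", STAGE_LABELS)
    m
  }
  if (config$n_genes > 0) {
    ng <- config$n_genes
    gene_chroms <- if (length(bg_chroms)) bg_chroms else chroms[min(8, length(chroms))]
    chrom <- sample(gene_chroms, ng, replace = TRUE)
    width <- floor(stats::runif(ng, 5e3, 2e5))
    start <- floor(stats::runif(ng, 1, len - width))
    pass <- stats::runif(ng) < config$hi_pass_fraction
    pct_hi <- ifelse(pass, stats::runif(ng, 0, 9.9), stats::runif(ng, 15, 95))
    pli <- ifelse(pass, stats::runif(ng, 0.91, 0.999), stats::runif(ng, 0, 0.85))
    oe <- ifelse(pass, stats::runif(ng, 0.05, 0.34), stats::runif(ng, 0.4, 1.5))
    # mask scores to "absent" at random, keeping one passing score for passers
    keep <- matrix(stats::runif(3 * ng) < 0.7, ncol = 3)
    keep[cbind(seq_len(ng), sample.int(3, ng, replace = TRUE))] <- TRUE
    pct_hi[!keep[, 1]] <- NA; pli[!keep[, 2]] <- NA; oe[!keep[, 3]] <- NA
    # a passer must retain at least one passing score
    need <- pass & is.na(pct_hi) & is.na(pli) & is.na(oe)
    pct_hi[need] <- stats::runif(sum(need), 0, 9.9)
    expressed <- stats::runif(ng) < config$expressed_fraction
    bg <- data.frame(gene_id = sprintf("g_bg%04d", seq_len(ng)),
                     symbol = sprintf("BGG%04d", seq_len(ng)),
                     chrom = chrom, start = start, end = start + width - 1,
                     strand = "+", biotype = "protein_coding",
                     pct_hi = pct_hi, pli = pli, oe_upper = oe)
    genes$bg <- cbind(bg, draw_expr(ng, expressed))
  }
  if (config$n_lncrnas > 0 && length(chroms) >= 8) {
    nl <- config$n_lncrnas
    width <- floor(stats::runif(nl, 2e3, 5e4))
    start <- floor(stats::runif(nl, 1, len - width))
    expressed <- stats::runif(nl) < config$expressed_fraction
    bg <- data.frame(gene_id = sprintf("l_bg%04d", seq_len(nl)),
                     symbol = sprintf("BGL%04d", seq_len(nl)),
                     chrom = "chr8", start = start, end = start + width - 1,
                     strand = "+", biotype = "lncRNA",
                     pct_hi = NA_real_, pli = NA_real_, oe_upper = NA_real_)
    lncs$bg <- cbind(bg, draw_expr(nl, expressed))
  }
  if (config$n_enhancers > 0 && length(chroms) >= 8) {
    ne <- config$n_enhancers
    start <- floor(stats::runif(ne, 1, len - 2000))
    enh$bg <- data.frame(chrom = "chr8", start = start, end = start + 1499,
                         element_id = sprintf("element_%04d", seq_len(ne)),
                         heart_positive = stats::runif(ne) < config$heart_enhancer_fraction)
  }
  population <- if (length(chroms) >= 8) {
    ps <- floor(seq(0.1, 0.9, length.out = 5) * len)
    data.frame(chrom = "chr8", start = ps + 1, end = ps + 150000)
  } else {
    gi_empty()
  }

  # background CNVs in disjoint slots so no accidental recurrence arises
  n_bg <- stats::rpois(n_pat, config$cnv_rate_per_patient)
  total_bg <- sum(n_bg)
  if (total_bg > 0) {
    slot_w <- ceiling(config$size_range[2] * 1.15)
    per_chrom <- floor(len / slot_w)
    if (length(bg_chroms) == 0L || per_chrom < 1L ||
        total_bg > length(bg_chroms) * per_chrom) {
      stop_validation(sprintf(
        "cannot place %d background CNVs in disjoint slots: increase n_chromosomes or chrom_length",
        total_bg))
    }
    slot <- seq_len(total_bg)
    chrom <- bg_chroms[(slot - 1) %/% per_chrom + 1]
    offset <- ((slot - 1) %% per_chrom) * slot_w
    width <- floor(exp(stats::runif(total_bg, log(config$size_range[1]),
                                    log(config$size_range[2]))))
    start <- offset + 1 + floor(stats::runif(total_bg) * (slot_w - width - 1))
    loss <- stats::runif(total_bg) < config$loss_fraction
    trip <- !loss & stats::runif(total_bg) < config$triplication_fraction
    cn_class <- ifelse(loss, "deletion", ifelse(trip, "triplication",
                                                "duplication"))
    mosaic <- stats::runif(total_bg) < config$mosaic_fraction &
      cn_class != "triplication"
    inh <- sample(names(config$inheritance_probs), total_bg, replace = TRUE,
                  prob = config$inheritance_probs)
    pat_i <- rep(seq_len(n_pat), n_bg)
    cnvs$bg <- data.frame(chrom = chrom, start = start,
                          end = start + width - 1, cn_class = cn_class,
                          mosaic = mosaic, inheritance = inh,
                          patient_id = patients$patient_id[pat_i],
                          phenotype_group = patients$phenotype_group[pat_i],
                          sex = patients$sex[pat_i],
                          cnv_id = sprintf("cnv_bg%04d", seq_len(total_bg)))
  }

  cnv_tbl <- if (length(cnvs)) {
    cnv_table(do.call(rbind, c(cnvs, list(make.row.names = FALSE))))
  } else {
    cnv_table(data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0), cn_class = character(0),
                         mosaic = logical(0), inheritance = character(0),
                         patient_id = character(0),
                         phenotype_group = character(0), sex = character(0)))
  }
  empty_genes <- cbind(data.frame(gene_id = character(0), symbol = character(0),
                                  chrom = character(0), start = numeric(0),
                                  end = numeric(0), strand = character(0),
                                  biotype = character(0), pct_hi = numeric(0),
                                  pli = numeric(0), oe_upper = numeric(0)),
                       blank_expr(0))
  gene_tbl <- if (length(genes)) do.call(rbind, c(genes, list(make.row.names = FALSE))) else empty_genes
  lnc_tbl <- if (length(lncs)) do.call(rbind, c(lncs, list(make.row.names = FALSE))) else empty_genes
  enh_tbl <- if (length(enh)) {
    do.call(rbind, c(enh, list(make.row.names = FALSE)))
  } else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               element_id = character(0), heart_positive = logical(0))
  }
  rownames(gene_tbl) <- NULL; rownames(lnc_tbl) <- NULL

  function_lists <- list(
    chd_panel = intersect(c("CAND1", "FUSG1", "INTG1"), gene_tbl$symbol),
    transcription_factor = intersect("NEOG1", gene_tbl$symbol),
    go_chd_term = intersect(c("INTG1", "CAND1"), gene_tbl$symbol))
  function_lists <- function_lists[vapply(function_lists, length, 1L) > 0]

  bundle <- track_bundle(cnv_tbl, patients, known_regions, gene_tbl, lnc_tbl,
                         enh_tbl, tad_map(tads, boundaries), population,
                         function_lists)

  # expected TAD class for every emitted CNV, from the tiling arithmetic
  truth$tad_classes <- data.frame(
    cnv_id = cnv_tbl$cnv_id,
    tad_class = vapply(seq_len(nrow(cnv_tbl)), function(i) {
      truth_tad_class(tads, boundaries, cnv_tbl$chrom[i], cnv_tbl$start[i],
                      cnv_tbl$end[i])
    }, character(1)))
  truth$interest <- data.frame(
    cnv_id = cnv_tbl$cnv_id,
    flags = vapply(cnv_tbl$cnv_id, function(id) {
      paste(interest[[id]] %||% character(0), collapse = ";")
    }, character(1), USE.NAMES = FALSE))
  truth$interest$of_interest <- nzchar(truth$interest$flags)

  list(bundle = bundle, truth = truth)
}

DEGRADE_MODES <- c("drop_pli", "shuffle_chrom_case", "zero_length",
                   "unknown_chrom")

#' Inject controlled pathologies into a bundle
#'
#' Negative-path fixtures: `"drop_pli"` blanks every pLI score,
#' `"shuffle_chrom_case"` rewrites chromosome labels in mixed case (a
#' dialect the validators must normalize away), `"zero_length"` corrupts
#' one enhancer into a zero-length feature (rejected by
#' [validate_bundle()] and by the BED reader), `"unknown_chrom"` moves one
#' CNV to an unplaced-contig label (annotated as TAD-unassigned, never
#' dropped).
#'
#' @param bundle A [track_bundle()].
#' @param mode One of `r paste(DEGRADE_MODES, collapse = ", ")`.
#' @return The degraded bundle (not revalidated).
#' @export
degrade_fixture <- function(bundle, mode) {
  if (!mode %in% DEGRADE_MODES) {
    stop_validation(sprintf("unknown degrade mode '%s'", mode))
  }
  if (mode == "drop_pli") {
    bundle$genes$pli <- NA_real_
    bundle$lncrnas$pli <- NA_real_
  } else if (mode == "shuffle_chrom_case") {
    shuffle <- function(x) {
      pre <- rep_len(c("Chr", "CHR", "chr"), length(x))
      paste0(pre, sub("^chr", "", x))
    }
    for (part in c("cnvs", "genes", "lncrnas", "enhancers", "known_regions",
                   "population")) {
      bundle[[part]]$chrom <- shuffle(bundle[[part]]$chrom)
    }
    bundle$tads$tads$chrom <- shuffle(bundle$tads$tads$chrom)
    bundle$tads$boundaries$chrom <- shuffle(bundle$tads$boundaries$chrom)
  } else if (mode == "zero_length") {
    if (nrow(bundle$enhancers) == 0L) {
      stop_validation("zero_length mode needs at least one enhancer")
    }
    bundle$enhancers$end[1] <- bundle$enhancers$start[1] - 1
  } else if (mode == "unknown_chrom") {
    if (nrow(bundle$cnvs) == 0L) {
      stop_validation("unknown_chrom mode needs at least one CNV")
    }
    bundle$cnvs$chrom[1] <- "chrUn_gl000220"
  }
  bundle
}
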
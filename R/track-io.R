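# Readers and writers for the cohort CNV table and every annotation track.
# Internal coordinates are 1-based inclusive; BED files are 0-based
# half-open, converted at this boundary layer only (via rtracklayer).

`%||%` <- function(a, b) if (is.null(a)) b else a

# coordinates must never be written in scientific notation
fmt_num <- function(x) {
  ifelse(is.na(x), "", format(x, scientific = FALSE, trim = TRUE, digits = 15))
}

read_tsv_strict <- function(path) {
  utils::read.delim(path, colClasses = "character", check.names = FALSE,
                    na.strings = NULL, quote = "")
}

parse_int_col <- function(x, col, rows = seq_along(x)) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & (is.na(out) | out != floor(out)))
  if (length(bad)) {
    stop_schema(sprintf("row %d, column '%s': non-integer value '%s'",
                        rows[bad[1]], col, x[bad[1]]))
  }
  miss <- which(is.na(x) | x == "")
  if (length(miss)) {
    stop_schema(sprintf("row %d, column '%s': missing coordinate",
                        rows[miss[1]], col))
  }
  out
}

parse_num_col <- function(x, col) {
  out <- suppressWarnings(as.numeric(x))
  out[x == ""] <- NA_real_
  bad <- which(x != "" & is.na(out))
  if (length(bad)) {
    stop_schema(sprintf("row %d, column '%s': non-numeric value '%s'",
                        bad[1], col, x[bad[1]]))
  }
  out
}

parse_bool_col <- function(x, col) {
  lo <- tolower(x)
  bad <- which(!(lo %in% c("true", "false")))
  if (length(bad)) {
    stop_schema(sprintf("row %d, column '%s': expected true/false, got '%s'",
                        bad[1], col, x[bad[1]]))
  }
  lo == "true"
}

#' Read a cohort CNV table
#'
#' Tab-separated with header columns `chrom`, `start`, `end`, `cn_class`,
#' `mosaic`, `inheritance`, `patient_id`, `phenotype_group`, `sex`
#' (optionally `cnv_id`). Coordinates are 1-based inclusive as printed in
#' clinical reports. Schema violations are reported naming the offending row
#' and column.
#'
#' @param path Path to the TSV file.
#' @return A validated CNV table (see [cnv_table()]).
#' @export
read_cnv_table <- function(path) {
  df <- read_tsv_strict(path)
  need <- c("chrom", "start", "end", "cn_class", "mosaic", "inheritance",
            "patient_id", "phenotype_group", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_schema(sprintf("CNV table %s is missing column(s): %s",
                        path, paste(miss, collapse = ", ")))
  }
  if (nrow(df) == 0L) {
    return(cnv_table(data.frame(chrom = character(0), start = numeric(0),
                                end = numeric(0), cn_class = character(0),
                                mosaic = logical(0), inheritance = character(0),
                                patient_id = character(0),
                                phenotype_group = character(0),
                                sex = character(0))))
  }
  df$start <- parse_int_col(df$start, "start")
  df$end <- parse_int_col(df$end, "end")
  df$mosaic <- parse_bool_col(df$mosaic, "mosaic")
  cnv_table(df)
}

#' Write a cohort CNV table
#'
#' @param cnvs A CNV table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnv_table <- function(cnvs, path) {
  out <- cnvs
  out$start <- fmt_num(out$start)
  out$end <- fmt_num(out$end)
  out$mosaic <- ifelse(out$mosaic, "true", "false")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED track into 1-based inclusive coordinates
#'
#' BED3/BED4/BED6, optionally with declared extra columns (e.g. a tissue
#' column on an enhancer track). Zero-length features are rejected.
#'
#' @param path Path to the BED file.
#' @param extra_cols Named character vector of extra column types appended
#'   after the standard BED fields (passed to [rtracklayer::import()]), or
#'   `NULL`.
#' @return A data.frame with columns `chrom`, `start`, `end` plus any
#'   `name`/`score`/extra columns present.
#' @export
read_bed_track <- function(path, extra_cols = NULL) {
  gr <- rtracklayer::import(path, format = "BED",
                            extraCols = extra_cols %||% character())
  out <- data.frame(chrom = norm_chrom(as.character(GenomicRanges::seqnames(gr))),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr))
  mc <- as.data.frame(S4Vectors::mcols(gr))
  for (col in names(mc)) {
    if (!all(is.na(mc[[col]]))) out[[col]] <- mc[[col]]
  }
  bad <- which(out$end < out$start)
  if (length(bad)) {
    stop_validation(sprintf("zero-length BED feature at record %d of %s",
                            bad[1], path))
  }
  validate_gi(out, context = sprintf("BED track %s", basename(path)))
}

#' Write a BED track from 1-based inclusive coordinates
#'
#' @param x An interval table; optional `name`, `score` and extra columns are
#'   emitted after the three coordinate fields, in the order given by
#'   `cols`.
#' @param path Output path.
#' @param cols Character vector of column names to append after
#'   chrom/start/end (default: `name` then `score` when present).
#' @return `path`, invisibly.
#' @export
write_bed_track <- function(x, path, cols = intersect(c("name", "score"), names(x))) {
  validate_gi(x, "BED track")
  out <- data.frame(chrom = x$chrom,
                    start = fmt_num(x$start - 1),
                    end = fmt_num(x$end))
  for (col in cols) out[[col]] <- x[[col]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene model table with dosage-sensitivity scores and expression
#'
#' TSV with columns `gene_id`, `symbol`, `chrom`, `start`, `end`, `strand`,
#' `biotype`, the dosage-sensitivity scores `pct_hi` (percent), `pli`
#' (probability) and `oe_upper` (ratio), and one `tpm_<stage>` column per
#' developmental stage, in stage order. Empty score cells are read as
#' absent (`NA`), never as zero: an absent score can never satisfy a
#' haploinsufficiency criterion. Missing score columns produce a warning and
#' all-absent values.
#'
#' @param path Path to the TSV file.
#' @return A gene table; developmental stages (in declared order) are
#'   recoverable via [gene_stages()].
#' @export
read_gene_table <- function(path) {
  df <- read_tsv_strict(path)
  need <- c("gene_id", "symbol", "chrom", "start", "end", "strand", "biotype")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_schema(sprintf("gene table %s is missing column(s): %s",
                        path, paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(df$gene_id)) {
    stop_schema(sprintf("duplicate gene_id '%s' in %s",
                        df$gene_id[duplicated(df$gene_id)][1], path))
  }
  if (nrow(df)) {
    df$start <- parse_int_col(df$start, "start")
    df$end <- parse_int_col(df$end, "end")
  } else {
    df$start <- numeric(0); df$end <- numeric(0)
  }
  df$chrom <- norm_chrom(df$chrom)
  validate_gi(df, context = "gene")
  bad <- which(!(df$biotype %in% c("protein_coding", "lncRNA")))
  if (length(bad)) {
    stop_schema(sprintf("row %d: unknown biotype '%s'", bad[1], df$biotype[bad[1]]))
  }
  for (col in c("pct_hi", "pli", "oe_upper")) {
    if (col %in% names(df)) {
      df[[col]] <- parse_num_col(df[[col]], col)
    } else {
      warning(sprintf("gene table %s lacks score column '%s'; values treated as absent",
                      path, col), call. = FALSE)
      df[[col]] <- NA_real_
    }
  }
  validate_gene_scores(df)
  tpm_cols <- grep("^tpm_", names(df), value = TRUE)
  for (col in tpm_cols) {
    df[[col]] <- parse_num_col(df[[col]], col)
    if (any(df[[col]] < 0, na.rm = TRUE)) {
      stop_schema(sprintf("negative TPM in column '%s'", col))
    }
  }
  df
}

validate_gene_scores <- function(df) {
  if (any(df$pct_hi < 0 | df$pct_hi > 100, na.rm = TRUE)) {
    stop_schema("pct_hi must lie in [0, 100]")
  }
  if (any(df$pli < 0 | df$pli > 1, na.rm = TRUE)) {
    stop_schema("pli must lie in [0, 1]")
  }
  if (any(df$oe_upper < 0, na.rm = TRUE)) {
    stop_schema("oe_upper must be non-negative")
  }
  lnc <- df$biotype == "lncRNA"
  if (any(lnc & (!is.na(df$pct_hi) | !is.na(df$pli) | !is.na(df$oe_upper)))) {
    stop_schema("lncRNA genes must not carry protein-coding dosage scores")
  }
  invisible(df)
}

#' Developmental stages declared by a gene table
#'
#' @param genes A gene table from [read_gene_table()].
#' @return Character vector of stage labels in column order.
#' @export
gene_stages <- function(genes) {
  sub("^tpm_", "", grep("^tpm_", names(genes), value = TRUE))
}

#' Write a gene table
#' @param genes A gene table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  out <- genes
  for (col in c("start", "end", "pct_hi", "pli", "oe_upper",
                grep("^tpm_", names(out), value = TRUE))) {
    out[[col]] <- fmt_num(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a plain-text gene list (one identifier per line)
#'
#' Function lists (CHD panel, transcription factors, GO-derived sets) are
#' plain text, one gene identifier per line; blank lines and `#` comments are
#' skipped.
#'
#' @param path Path to the list file.
#' @return Character vector of identifiers.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' @rdname read_gene_list
#' @param ids Character vector of identifiers.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

# ---- track bundles -------------------------------------------------------

#' Assemble a track bundle
#'
#' A track bundle holds everything one annotation run needs: the cohort CNV
#' table, patient metadata, known dosage-sensitive regions, protein-coding
#' and lncRNA gene models, enhancer elements, the TAD map, a population
#' (benign) CNV track, and named gene-function lists.
#'
#' @param cnvs CNV table ([cnv_table()]).
#' @param patients data.frame with `patient_id`, `phenotype_group`, `sex`.
#' @param known_regions data.frame with `chrom`, `start`, `end`, `name`,
#'   `hi_score`, `ts_score`, `chd_link`; at least one score present per row.
#' @param genes,lncrnas Gene tables ([read_gene_table()]).
#' @param enhancers data.frame with `chrom`, `start`, `end`, `element_id`,
#'   `heart_positive`.
#' @param tads A [tad_map()].
#' @param population Interval table of population/benign CNVs.
#' @param function_lists Named list of character vectors of gene symbols.
#' @return A `track_bundle` object (a named list).
#' @export
track_bundle <- function(cnvs, patients, known_regions, genes, lncrnas,
                         enhancers, tads, population,
                         function_lists = list()) {
  structure(list(cnvs = cnvs, patients = patients,
                 known_regions = known_regions, genes = genes,
                 lncrnas = lncrnas, enhancers = enhancers, tads = tads,
                 population = population, function_lists = function_lists),
            class = "track_bundle")
}

#' Validate a track bundle
#'
#' Re-runs every per-track validator, normalizes chromosome dialects, and
#' warns (never errors) on function-list identifiers that resolve against
#' neither the protein-coding nor the lncRNA gene models.
#'
#' @param bundle A [track_bundle()].
#' @return The validated bundle, with chromosome labels normalized.
#' @export
validate_bundle <- function(bundle) {
  bundle$cnvs <- cnv_table(bundle$cnvs)
  kr <- bundle$known_regions
  kr$chrom <- norm_chrom(kr$chrom)
  validate_gi(kr, "known region")
  if (nrow(kr) && any(is.na(kr$hi_score) & is.na(kr$ts_score))) {
    stop_validation("known region without any HI/TS evidence score")
  }
  bundle$known_regions <- kr
  for (part in c("genes", "lncrnas")) {
    g <- bundle[[part]]
    g$chrom <- norm_chrom(g$chrom)
    validate_gi(g, part)
    validate_gene_scores(g)
    bundle[[part]] <- g
  }
  enh <- bundle$enhancers
  enh$chrom <- norm_chrom(enh$chrom)
  validate_gi(enh, "enhancer")
  bundle$enhancers <- enh
  bundle$tads <- tad_map(bundle$tads$tads, bundle$tads$boundaries)
  pop <- bundle$population
  pop$chrom <- norm_chrom(pop$chrom)
  validate_gi(pop, "population CNV")
  bundle$population <- pop
  known <- c(bundle$genes$symbol, bundle$lncrnas$symbol,
             bundle$genes$gene_id, bundle$lncrnas$gene_id)
  for (nm in names(bundle$function_lists)) {
    unresolved <- setdiff(bundle$function_lists[[nm]], known)
    if (length(unresolved)) {
      warning(sprintf("function list '%s': %d unresolved identifier(s), e.g. '%s'",
                      nm, length(unresolved), unresolved[1]), call. = FALSE)
    }
  }
  bundle
}

bundle_files <- function(dir) {
  list(cnvs = file.path(dir, "cnvs.tsv"),
       patients = file.path(dir, "patients.tsv"),
       known_bed = file.path(dir, "known_regions.bed"),
       known_scores = file.path(dir, "known_region_scores.tsv"),
       genes = file.path(dir, "genes.tsv"),
       lncrnas = file.path(dir, "lncrnas.tsv"),
       enhancers = file.path(dir, "enhancers.bed"),
       tads = file.path(dir, "tads.bed"),
       boundaries = file.path(dir, "boundaries.bed"),
       population = file.path(dir, "population.bed"))
}

#' Write a track bundle to a directory of plain-text track files
#'
#' Emits `cnvs.tsv`, `patients.tsv`, `known_regions.bed` (BED4) with a score
#' sidecar `known_region_scores.tsv`, `genes.tsv`, `lncrnas.tsv`,
#' `enhancers.bed` (BED4 + tissue column), `tads.bed` (BED4),
#' `boundaries.bed` (BED3), `population.bed` (BED3) and one
#' `function_<name>.txt` per function list.
#'
#' @param bundle A [track_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- bundle_files(dir)
  write_cnv_table(bundle$cnvs, f$cnvs)
  utils::write.table(bundle$patients, f$patients, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  kr <- bundle$known_regions
  write_bed_track(data.frame(chrom = kr$chrom, start = kr$start, end = kr$end,
                             name = kr$name), f$known_bed)
  sc <- kr[, c("name", "hi_score", "ts_score", "chd_link")]
  sc$hi_score <- fmt_num(sc$hi_score)
  sc$ts_score <- fmt_num(sc$ts_score)
  utils::write.table(sc, f$known_scores, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gene_table(bundle$genes, f$genes)
  write_gene_table(bundle$lncrnas, f$lncrnas)
  enh <- bundle$enhancers
  write_bed_track(data.frame(chrom = enh$chrom, start = enh$start,
                             end = enh$end, name = enh$element_id,
                             tissue = ifelse(enh$heart_positive, "heart", "none")),
                  f$enhancers, cols = c("name", "tissue"))
  tads <- bundle$tads$tads
  write_bed_track(data.frame(chrom = tads$chrom, start = tads$start,
                             end = tads$end, name = tads$tad_id), f$tads)
  write_bed_track(bundle$tads$boundaries, f$boundaries, cols = character(0))
  write_bed_track(bundle$population, f$population, cols = character(0))
  for (nm in names(bundle$function_lists)) {
    write_gene_list(bundle$function_lists[[nm]],
                    file.path(dir, sprintf("function_%s.txt", nm)))
  }
  invisible(dir)
}

#' Read a track bundle from a directory written by [write_bundle()]
#'
#' @param dir Directory containing the track files.
#' @return A validated [track_bundle()].
#' @export
read_bundle <- function(dir) {
  f <- bundle_files(dir)
  cnvs <- read_cnv_table(f$cnvs)
  patients <- read_tsv_strict(f$patients)
  kb <- read_bed_track(f$known_bed)
  sc <- read_tsv_strict(f$known_scores)
  sc$hi_score <- parse_num_col(sc$hi_score, "hi_score")
  sc$ts_score <- parse_num_col(sc$ts_score, "ts_score")
  kr <- merge(kb, sc, by = "name", sort = FALSE)
  kr <- kr[, c("chrom", "start", "end", "name", "hi_score", "ts_score", "chd_link")]
  genes <- read_gene_table(f$genes)
  lncrnas <- read_gene_table(f$lncrnas)
  eb <- read_bed_track(f$enhancers, extra_cols = c(tissue = "character"))
  enhancers <- data.frame(chrom = eb$chrom, start = eb$start, end = eb$end,
                          element_id = eb$name,
                          heart_positive = eb$tissue == "heart")
  tb <- read_bed_track(f$tads)
  tads <- tad_map(data.frame(chrom = tb$chrom, start = tb$start, end = tb$end,
                             tad_id = tb$name),
                  read_bed_track(f$boundaries)[, c("chrom", "start", "end")])
  population <- read_bed_track(f$population)[, c("chrom", "start", "end"), drop = FALSE]
  fl_files <- list.files(dir, pattern = "^function_.*\\.txt$", full.names = TRUE)
  function_lists <- lapply(fl_files, read_gene_list)
  names(function_lists) <- sub("^function_(.*)\\.txt$", "\\1", basename(fl_files))
  validate_bundle(track_bundle(cnvs, patients, kr, genes, lncrnas, enhancers,
                               tads, population, function_lists))
}
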
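# Interval algebra on 1-based inclusive genomic coordinates. All downstream
# modules (recurrence grouping, gene-effect classification, TAD rewiring)
# reduce to this algebra, so it is kept dependency-free and exactly specified;
# bulk overlap joins elsewhere go through GenomicRanges.

#' Signal a validation error
#'
#' Validation errors carry the condition class `chdcnv_validation_error`;
#' malformed input tables additionally use `chdcnv_schema_error` (see
#' [read_cnv_table()]).
#' @noRd
stop_validation <- function(msg, class = "chdcnv_validation_error") {
  stop(errorCondition(msg, class = c(class, "chdcnv_error")))
}

stop_schema <- function(msg) {
  stop_validation(msg, class = c("chdcnv_schema_error", "chdcnv_validation_error"))
}

stop_contract <- function(msg) {
  stop_validation(msg, class = c("chdcnv_contract_error", "chdcnv_validation_error"))
}

#' Normalize chromosome labels to one dialect
#'
#' Chromosome labels are normalized to a `"chr"`-prefixed dialect with
#' upper-case sex/mitochondrial chromosomes, so that `"Chr9"`, `"9"` and
#' `"chr9"` compare equal, as do `"chrx"` and `"chrX"`.
#'
#' @param chrom Character vector of chromosome labels.
#' @return Character vector of normalized labels.
#' @examples
#' norm_chrom(c("Chr9", "x", "chrY", "15"))
#' @export
norm_chrom <- function(chrom) {
  if (length(chrom) == 0L) return(character(0))
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  sex <- tolower(x) %in% c("x", "y", "m", "mt", "x/y")
  x[sex] <- toupper(x[sex])
  paste0("chr", x)
}

#' Construct a table of genomic intervals
#'
#' Intervals are 1-based and inclusive on both ends, the convention in which
#' clinical CNV coordinates are reported; zero-length intervals are
#' forbidden. BED input/output converts at the boundary layer only
#' (see [read_bed_track()]).
#'
#' @param chrom Character vector of chromosome labels (normalized via
#'   [norm_chrom()]).
#' @param start,end Integer-valued positions, 1-based inclusive;
#'   `end >= start >= 1`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`.
#' @examples
#' gi("chr9", 107409506, 107729796)
#' @export
gi <- function(chrom = character(), start = numeric(), end = numeric()) {
  out <- data.frame(chrom = norm_chrom(chrom),
                    start = as.numeric(start),
                    end = as.numeric(end))
  validate_gi(out)
}

#' The empty interval
#'
#' Empty intersections are a first-class value (a zero-row interval table),
#' not an error, so that SRO folds short-circuit cleanly.
#' @return A zero-row interval table.
#' @seealso [gi_is_empty()]
#' @export
gi_empty <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
}

#' @rdname gi_empty
#' @param x An interval table.
#' @export
gi_is_empty <- function(x) {
  nrow(x) == 0L
}

#' Validate an interval table
#'
#' @param x A data.frame with columns `chrom`, `start`, `end`.
#' @param context Label used in error messages.
#' @return `x`, invisibly unchanged, or a validation error.
#' @export
validate_gi <- function(x, context = "interval") {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop_validation(sprintf("%s table is missing column(s): %s",
                            context, paste(miss, collapse = ", ")))
  }
  bad <- which(is.na(x$start) | is.na(x$end) | x$start < 1 | x$end < x$start)
  if (length(bad)) {
    stop_validation(sprintf(
      "malformed %s at row %d: start=%s end=%s (need 1 <= start <= end)",
      context, bad[1], format(x$start[bad[1]], scientific = FALSE),
      format(x$end[bad[1]], scientific = FALSE)))
  }
  x
}

#' Interval lengths in base pairs
#'
#' @param x An interval table.
#' @return Numeric vector, `end - start + 1` per row.
#' @export
gi_width <- function(x) {
  if (gi_is_empty(x)) return(numeric(0))
  x$end - x$start + 1
}

#' Parse region strings like "chr9:107409506-107729796"
#'
#' Convenience for coordinates quoted in the clinical literature; commas and
#' a trailing del/dup/trip suffix are tolerated.
#'
#' @param x Character vector of region strings.
#' @return An interval table with one row per string.
#' @export
parse_region <- function(x) {
  x <- gsub(",", "", x)
  x <- sub("(del|dup|trip)$", "", x, ignore.case = TRUE)
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop_validation(sprintf("cannot parse region string: '%s'", x[which(bad)[1]]))
  }
  gi(vapply(m, `[`, "", 2L),
     as.numeric(vapply(m, `[`, "", 3L)),
     as.numeric(vapply(m, `[`, "", 4L)))
}

#' Default pseudoautosomal windows (GRCh37, X-axis coordinates)
#'
#' Coordinate windows within which chrX and chrY intervals are treated as one
#' shared axis under the identity mapping of [par_normalize()]. Defaults are
#' the GRCh37 PAR1 and PAR2 windows in chrX coordinates.
#'
#' @return A data.frame with columns `start`, `end`.
#' @export
par_regions <- function() {
  data.frame(start = c(60001, 154931044), end = c(2699520, 155260560))
}

#' Map pseudoautosomal X/Y intervals onto a shared axis
#'
#' A chrX or chrY interval fully contained in a PAR window is relabelled to
#' the shared axis (`"chrX"` by default) with its coordinates unchanged
#' (identity mapping, no offset). This reproduces the convention under which
#' an Xp/Yp PAR deletion pair shares one coordinate axis. Pass `par = NULL`
#' to disable.
#'
#' @param x An interval table (extra columns are preserved).
#' @param par PAR windows as from [par_regions()], or `NULL` to disable.
#' @param axis Chromosome label of the shared axis.
#' @return `x` with chrom labels rewritten where applicable.
#' @export
par_normalize <- function(x, par = par_regions(), axis = "chrX") {
  if (is.null(par) || nrow(x) == 0L) return(x)
  sex <- x$chrom %in% c("chrX", "chrY")
  if (!any(sex)) return(x)
  inside <- rep(FALSE, nrow(x))
  for (i in seq_len(nrow(par))) {
    inside <- inside | (x$start >= par$start[i] & x$end <= par$end[i])
  }
  x$chrom[sex & inside] <- axis
  x
}

#' Intersect two genomic intervals
#'
#' Returns the interval `[max(starts), min(ends)]` when the (PAR-normalized)
#' chromosomes match and the result is non-empty, and the empty interval
#' otherwise.
#'
#' @param a,b Single-row interval tables.
#' @param par PAR equivalence windows (see [par_normalize()]); `NULL`
#'   disables the mapping.
#' @return A single-row interval table, or [gi_empty()].
#' @examples
#' gi_intersect(gi("chr4", 135455435, 137460949),
#'              gi("chr4", 135700662, 135829279))
#' @export
gi_intersect <- function(a, b, par = par_regions()) {
  a <- validate_gi(a)
  b <- validate_gi(b)
  if (gi_is_empty(a) || gi_is_empty(b)) return(gi_empty())
  if (nrow(a) != 1L || nrow(b) != 1L) {
    stop_validation("gi_intersect() expects single-row intervals; use gi_sro() to fold a set")
  }
  an <- par_normalize(a, par)
  bn <- par_normalize(b, par)
  if (an$chrom != bn$chrom) return(gi_empty())
  s <- max(an$start, bn$start)
  e <- min(an$end, bn$end)
  if (s > e) return(gi_empty())
  data.frame(chrom = an$chrom, start = s, end = e)
}

#' Smallest region of overlap (SRO) of a set of intervals
#'
#' The SRO of a recurrent CNV group is the intersection of all member
#' intervals: a fold of [gi_intersect()]. It is empty as soon as any pairwise
#' intersection is empty (single-linkage chains need not share a common
#' core).
#'
#' @param x An interval table with one row per member (at least one row).
#' @param par PAR equivalence windows; see [gi_intersect()].
#' @return A single-row interval table, or [gi_empty()].
#' @examples
#' gi_sro(gi("chr15",
#'           c(22755001, 22765628, 22765628, 22765628),
#'           c(23085000, 23167699, 23208842, 23208842)))
#' @export
gi_sro <- function(x, par = par_regions()) {
  x <- validate_gi(x)
  if (gi_is_empty(x)) {
    stop_validation("gi_sro() requires at least one interval")
  }
  acc <- x[1, c("chrom", "start", "end")]
  for (i in seq_len(nrow(x))[-1]) {
    acc <- gi_intersect(acc, x[i, , drop = FALSE], par = par)
    if (gi_is_empty(acc)) return(acc)
  }
  acc
}

#' Fraction of a known region covered by a CNV
#'
#' The denominator is the known region (not the CNV): a CNV that strictly
#' contains the region covers 100% of it.
#'
#' @param region,cnv Single-row interval tables.
#' @param par PAR equivalence windows; see [gi_intersect()].
#' @return A fraction in `[0, 1]`; 1 iff `region` is contained in `cnv`,
#'   0 iff disjoint.
#' @export
coverage_fraction <- function(region, cnv, par = par_regions()) {
  ov <- gi_intersect(region, cnv, par = par)
  if (gi_is_empty(ov)) return(0)
  gi_width(ov) / gi_width(validate_gi(region))
}

#' Reciprocal overlap of two intervals
#'
#' `min(coverage_fraction(a, b), coverage_fraction(b, a))` — the symmetric
#' overlap criterion used to match an SRO against population CNV entries.
#'
#' @param a,b Single-row interval tables.
#' @param par PAR equivalence windows.
#' @return A fraction in `[0, 1]`.
#' @export
reciprocal_overlap <- function(a, b, par = par_regions()) {
  min(coverage_fraction(a, b, par = par), coverage_fraction(b, a, par = par))
}

#' Convert an interval table to a GRanges
#' @noRd
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
as_granges <- function(x, seqlevels = unique(x$chrom)) {
  GenomicRanges::GRanges(factor(x$chrom, levels = seqlevels),
                         IRanges::IRanges(start = x$start, end = x$end))
}

# findOverlaps over two interval tables with a shared seqlevels universe
find_hits <- function(a, b) {
  lv <- union(unique(a$chrom), unique(b$chrom))
  GenomicRanges::findOverlaps(as_granges(a, lv), as_granges(b, lv))
}
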
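# Cohort CNV calls: one row per reported CNV with copy-number class,
# mosaic flag, inheritance and patient metadata.

CN_CLASSES <- c("deletion", "duplication", "triplication")
INHERITANCE <- c("de_novo", "inherited", "unknown")
PHENOTYPE_GROUPS <- c("SCHD", "ICHD")
SEXES <- c("M", "F", "unknown")

#' Construct/validate a cohort CNV table
#'
#' One row per CNV call. Losses are deletions; gains are duplications or
#' triplications. The mosaic flag is carried through all downstream
#' annotation, never dropped, and is only admissible for deletions and
#' duplications.
#'
#' @param x A data.frame with columns `chrom`, `start`, `end`, `cn_class`,
#'   `mosaic`, `inheritance`, `patient_id`, `phenotype_group`, `sex`, and
#'   optionally `cnv_id` (generated when absent).
#' @return The validated table with normalized chromosome labels and a
#'   `cnv_id` column.
#' @export
cnv_table <- function(x) {
  need <- c("chrom", "start", "end", "cn_class", "mosaic", "inheritance",
            "patient_id", "phenotype_group", "sex")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop_schema(sprintf("CNV table is missing column(s): %s",
                        paste(miss, collapse = ", ")))
  }
  x$chrom <- norm_chrom(x$chrom)
  tryCatch(validate_gi(x, context = "CNV"),
           chdcnv_validation_error = function(e) stop_schema(conditionMessage(e)))
  check_level <- function(col, levels) {
    bad <- which(!(x[[col]] %in% levels))
    if (length(bad)) {
      stop_schema(sprintf("row %d: invalid %s '%s' (expected one of %s)",
                          bad[1], col, x[[col]][bad[1]],
                          paste(levels, collapse = ", ")))
    }
  }
  check_level("cn_class", CN_CLASSES)
  check_level("inheritance", INHERITANCE)
  check_level("phenotype_group", PHENOTYPE_GROUPS)
  check_level("sex", SEXES)
  if (!is.logical(x$mosaic) || anyNA(x$mosaic)) {
    stop_schema("column 'mosaic' must be logical with no missing values")
  }
  bad <- which(x$mosaic & x$cn_class == "triplication")
  if (length(bad)) {
    stop_schema(sprintf("row %d: mosaic flag is only admissible for deletions and duplications",
                        bad[1]))
  }
  if (is.null(x$cnv_id)) {
    x$cnv_id <- sprintf("cnv_%03d", seq_len(nrow(x)))
  } else if (anyDuplicated(x$cnv_id)) {
    stop_schema("duplicated cnv_id values")
  }
  x
}

#' Is a copy-number class a loss or a gain?
#'
#' Deletions are losses; duplications and triplications are gains.
#'
#' @param cn_class Character vector of copy-number classes.
#' @return Logical vector.
#' @export
is_loss <- function(cn_class) {
  cn_class == "deletion"
}

#' @rdname is_loss
#' @export
is_gain <- function(cn_class) {
  cn_class %in% c("duplication", "triplication")
}
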
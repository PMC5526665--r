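#' Format a count ratio as a percentage
#'
#' Percentages are computed as `100 * n / denom`. Display rounding follows
#' the mixed style common in comparative-genomics reports: one decimal place
#' where sub-integer granularity matters (values below 10, or when the
#' caller asks for it), nearest integer otherwise. Raw counts remain the
#' authoritative record; this helper only formats.
#'
#' @param n Numerator count.
#' @param denom Denominator count (> 0).
#' @param digits Decimal places; `NULL` (default) picks 1 when the value is
#'   below 10 and 0 otherwise.
#' @param percent_sign Append "%" (default TRUE).
#' @return Character scalar, e.g. `"78.8%"`.
#' @export
format_percent <- function(n, denom, digits = NULL, percent_sign = TRUE) {
  stopifnot(denom > 0)
  value <- 100 * n / denom
  if (is.null(digits)) digits <- if (abs(value) < 10) 1L else 0L
  out <- formatC(round(value, digits), format = "f", digits = digits)
  if (percent_sign) paste0(out, "%") else out
}

#' Percentage value of a count ratio
#'
#' @inheritParams format_percent
#' @return Numeric percentage, rounded to `digits` when given.
#' @export
percent_value <- function(n, denom, digits = NULL) {
  stopifnot(denom > 0)
  v <- 100 * n / denom
  if (is.null(digits)) v else round(v, digits)
}

#' Load a per-gene functional annotation table
#'
#' Tab-separated with header `gene_id`, `category_id`, `category_name`;
#' `gene_id` is genome-qualified (`genome_id|gene_id`). A gene may carry
#' several categories; duplicate (gene, category) rows are deduplicated.
#' Genes absent from the table are "unannotated". Rows for genes outside
#' the candidate set are kept (the mismatch is reported at tally time).
#'
#' @param path Annotation TSV path.
#' @return Data frame of class `annotation_map`.
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  ann <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("gene_id", "category_id", "category_name")
  missing <- setdiff(need, names(ann))
  if (length(missing)) {
    stop("annotation table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ann <- ann[!duplicated(ann[c("gene_id", "category_id")]), need,
             drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("annotation_map", "data.frame")
  ann
}

#' Tally functional categories over the candidate gene set
#'
#' Counts, per category, the candidate genes carrying that category. Since a
#' gene may carry several categories the per-category counts tally
#' gene-category incidences; a distinct-gene count is reported alongside.
#' The denominator is either all candidate genes (`"all_cds"`) or only the
#' annotated ones (`"annotated_only"`); with no annotated genes the tally is
#' empty rather than dividing by zero.
#'
#' @param candidates Candidate data frame from [filter_hgt_hits()] /
#'   [detect_hgt()].
#' @param annotations An `annotation_map` from [load_annotations()].
#' @param denom_mode `"all_cds"` or `"annotated_only"`.
#' @return Data frame of class `category_tally`: category_id, category_name,
#'   n_genes, n_distinct_genes, denom, fraction (percent). Attributes:
#'   `denom_mode`, `n_unmatched` (annotation rows outside the candidate
#'   set), `n_annotated` (candidate genes with >= 1 category).
#' @export
tally_categories <- function(candidates, annotations,
                             denom_mode = c("all_cds", "annotated_only")) {
  denom_mode <- match.arg(denom_mode)
  cand_keys <- paste0(candidates$genome_id, "|", candidates$gene_id)
  in_cand <- annotations$gene_id %in% cand_keys
  n_unmatched <- length(unique(annotations$gene_id[!in_cand]))
  ann <- annotations[in_cand, , drop = FALSE]
  n_annotated <- length(unique(ann$gene_id))
  denom <- if (denom_mode == "all_cds") length(cand_keys) else n_annotated

  if (nrow(ann) == 0L || denom == 0L) {
    out <- data.frame(category_id = character(0), category_name = character(0),
                      n_genes = integer(0), n_distinct_genes = integer(0),
                      denom = integer(0), fraction = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    sp <- split(ann$gene_id, paste(ann$category_id, ann$category_name,
                                   sep = "\r"))
    keys <- strsplit(names(sp), "\r", fixed = TRUE)
    out <- data.frame(
      category_id = vapply(keys, `[[`, "", 1L),
      category_name = vapply(keys, `[[`, "", 2L),
      n_genes = vapply(sp, length, 0L),
      n_distinct_genes = vapply(sp, function(v) length(unique(v)), 0L),
      denom = denom,
      stringsAsFactors = FALSE)
    out$fraction <- 100 * out$n_genes / denom
    out <- out[order(-out$n_genes, out$category_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "denom_mode") <- denom_mode
  attr(out, "n_unmatched") <- n_unmatched
  attr(out, "n_annotated") <- n_annotated
  class(out) <- c("category_tally", "data.frame")
  out
}

#' Per-genome summary of detection results
#'
#' One row per input genome (genomes with no candidates included with
#' zeros). The attached footer reports how many genomes carry at least one
#' putative horizontally transferred gene, with the percentage.
#'
#' @param detection An `hgt_detection` from [detect_hgt()].
#' @param genomes List of `genome_record`.
#' @return Data frame: genome_id, n_genes, n_hgt_genes, n_islands,
#'   n_groups_touched, frac_of_genome_genes (percent). Attribute `footer` is
#'   a list with n_genomes, n_with_hgt, pct_with_hgt.
#' @export
per_genome_summary <- function(detection, genomes) {
  ids <- vapply(genomes, `[[`, "", "genome_id")
  n_genes <- vapply(genomes, function(g) nrow(g$genes), 0L)
  cand <- detection$candidates
  isl <- detection$islands
  ig <- detection$island_groups
  n_hgt <- vapply(ids, function(id) sum(cand$genome_id == id), 0L)
  n_isl <- vapply(ids, function(id) sum(isl$genome_id == id), 0L)
  n_grp <- vapply(ids, function(id) {
    length(unique(ig$group_rank[ig$island_id %in%
                                  isl$island_id[isl$genome_id == id]]))
  }, 0L)
  out <- data.frame(
    genome_id = ids, n_genes = n_genes, n_hgt_genes = n_hgt,
    n_islands = n_isl, n_groups_touched = n_grp,
    frac_of_genome_genes = ifelse(n_genes > 0, 100 * n_hgt / n_genes, 0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  n_with <- sum(out$n_hgt_genes > 0L)
  attr(out, "footer") <- list(
    n_genomes = length(ids), n_with_hgt = n_with,
    pct_with_hgt = percent_value(n_with, length(ids), digits = 1))
  out
}
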
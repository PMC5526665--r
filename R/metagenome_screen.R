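#' Metagenome screening parameters
#'
#' A region CDS counts as *present* in a metagenome assembly when some local
#' alignment against any contig has identity strictly greater than
#' `min_identity` and covers at least `min_query_coverage` of the CDS
#' length. The strict inequality follows the convention that a positive hit
#' requires *more than* the stated identity; the coverage requirement keeps
#' an identity match over a trivial fragment from counting a gene present.
#'
#' @param min_identity Percent identity threshold, strict (default 97).
#' @param min_query_coverage Minimum aligned fraction of the CDS length
#'   (default 0.90).
#' @param seed_size Seed k-mer length for the search (default 21; hits near
#'   97% identity are still densely seeded at this length).
#' @return An object of class `screen_params`.
#' @export
screen_params <- function(min_identity = 97.0, min_query_coverage = 0.90,
                          seed_size = 21L) {
  stopifnot(min_identity > 0, min_identity <= 100,
            min_query_coverage > 0, min_query_coverage <= 1)
  structure(list(min_identity = min_identity,
                 min_query_coverage = min_query_coverage,
                 seed_size = as.integer(seed_size)),
            class = "screen_params")
}

#' Screen one region against one metagenome assembly
#'
#' Each CDS of the region is aligned separately (both strands) against every
#' contig of the assembly; the per-CDS best identity and the resulting
#' presence call are returned.
#'
#' @param region Named [Biostrings::DNAStringSet] (or named character
#'   vector) of the region's CDS nucleotide sequences, in genomic order.
#' @param assembly [Biostrings::DNAStringSet] of assembled contigs, or path
#'   to a contig FASTA.
#' @param params A [screen_params()] object.
#' @return Data frame: cds_id, present (logical), best_identity (NA when no
#'   alignment qualified on coverage).
#' @export
screen_region <- function(region, assembly, params = screen_params()) {
  if (is.character(assembly) && length(assembly) == 1L &&
      file.exists(assembly)) {
    assembly <- Biostrings::readDNAStringSet(assembly)
  }
  region <- as.character(region)
  assembly <- as.character(assembly)
  if (length(assembly) == 0L || all(!nzchar(assembly))) {
    stop("empty metagenome assembly", call. = FALSE)
  }
  if (is.null(names(region))) {
    names(region) <- sprintf("cds%03d", seq_along(region))
  }
  aln_params <- homology_params(
    min_identity = 1e-9, min_length = params$seed_size,
    kmer_size = params$seed_size)
  best_id <- rep(NA_real_, length(region))
  for (i in seq_along(region)) {
    cds <- region[[i]]
    min_cov_len <- params$min_query_coverage * nchar(cds)
    for (contig in assembly) {
      alns <- align_pair(cds, contig, aln_params, apply_thresholds = FALSE)
      if (nrow(alns) == 0L) next
      covered <- alns[(alns$q_end - alns$q_start) >= min_cov_len, ,
                      drop = FALSE]
      if (nrow(covered) == 0L) next
      top <- max(covered$pct_identity)
      if (is.na(best_id[i]) || top > best_id[i]) best_id[i] <- top
    }
  }
  data.frame(cds_id = names(region),
             present = !is.na(best_id) & best_id > params$min_identity,
             best_identity = best_id,
             stringsAsFactors = FALSE)
}

#' Presence/absence matrix of region CDS across metagenomes
#'
#' Screens every region against every assembly and assembles per-region
#' presence matrices (rows = CDS in region order, columns = metagenomes)
#' plus a per-region summary: metagenomes with at least one CDS present and
#' with all CDS present.
#'
#' @param regions Named list of regions (each as in [screen_region()]).
#' @param assemblies Named list of assemblies ([Biostrings::DNAStringSet] or
#'   FASTA paths); names are metagenome ids and must be unique.
#' @param params A [screen_params()] object.
#' @return List of class `presence_screen` with `matrices` (per region:
#'   list with `present` logical matrix and `best_identity` numeric
#'   matrix), `cells` (long data frame: region, cds_id, metagenome,
#'   present, best_identity) and `summary` (region, n_metagenomes,
#'   n_any_present, n_all_present).
#' @export
build_presence_matrix <- function(regions, assemblies,
                                  params = screen_params()) {
  stopifnot(length(regions) >= 1L, length(assemblies) >= 1L)
  if (is.null(names(assemblies)) || anyDuplicated(names(assemblies))) {
    stop("assemblies must carry unique metagenome ids", call. = FALSE)
  }
  if (is.null(names(regions))) {
    names(regions) <- sprintf("region%02d", seq_along(regions))
  }
  matrices <- list()
  cells <- list()
  summary_rows <- list()
  for (rn in names(regions)) {
    per_mg <- lapply(names(assemblies), function(mg) {
      screen_region(regions[[rn]], assemblies[[mg]], params)
    })
    names(per_mg) <- names(assemblies)
    cds_ids <- per_mg[[1L]]$cds_id
    pres <- vapply(per_mg, `[[`, logical(length(cds_ids)), "present")
    idm <- vapply(per_mg, `[[`, numeric(length(cds_ids)), "best_identity")
    pres <- matrix(pres, nrow = length(cds_ids),
                   dimnames = list(cds_ids, names(assemblies)))
    idm <- matrix(idm, nrow = length(cds_ids),
                  dimnames = list(cds_ids, names(assemblies)))
    matrices[[rn]] <- list(present = pres, best_identity = idm)
    for (mg in names(assemblies)) {
      cells[[length(cells) + 1L]] <- data.frame(
        region = rn, cds_id = cds_ids, metagenome = mg,
        present = pres[, mg], best_identity = idm[, mg],
        stringsAsFactors = FALSE)
    }
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      region = rn, n_metagenomes = length(assemblies),
      n_any_present = sum(colSums(pres) > 0L),
      n_all_present = sum(colSums(pres) == nrow(pres)),
      stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  structure(list(matrices = matrices, cells = cells,
                 summary = do.call(rbind, summary_rows)),
            class = "presence_screen")
}

#' Write the long-format presence table as TSV
#'
#' @param screen A `presence_screen` from [build_presence_matrix()].
#' @param path Output TSV path.
#' @export
write_presence_tsv <- function(screen, path) {
  write.table(screen$cells, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
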
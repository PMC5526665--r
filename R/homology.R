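#' Homology search parameters
#'
#' Thresholds and scoring for the pairwise nucleotide local-alignment search.
#' The defaults encode the conservative gene-identity criterion used for HGT
#' candidacy: an alignment of at least 99% identity over at least 500
#' nucleotides. Both cutoffs are inclusive.
#'
#' @param min_identity Minimum percent identity for a reported hit (default
#'   99). Identity is computed over all alignment columns, gap columns
#'   counting as mismatches, matching the convention of 12-column tabular hit
#'   reports.
#' @param min_length Minimum alignment length in columns (default 500).
#' @param kmer_size Exact-seed length (default 31). Near-identical targets
#'   are densely seeded at this length; lower it for permissive searches.
#' @param xdrop Retained for interface compatibility with classical
#'   seed-and-extend tools; extension windows are sized from `extend_margin`.
#' @param match_score,mismatch_score,gap_open,gap_extend Alignment scoring
#'   (defaults +1/-2/-4/-2; a gap of length L costs `gap_open` +
#'   L * `gap_extend`).
#' @param band Half-width of the banded extension around seed diagonals
#'   (default 16).
#' @param extend_margin Window slack around a seed cluster, in nucleotides
#'   (default 400).
#' @param search_both_strands Also search the reverse complement of the
#'   subject (default TRUE).
#' @return An object of class `homology_params`.
#' @export
homology_params <- function(min_identity = 99.0, min_length = 500L,
                            kmer_size = 31L, xdrop = 20L,
                            match_score = 1L, mismatch_score = -2L,
                            gap_open = -4L, gap_extend = -2L,
                            band = 16L, extend_margin = 400L,
                            search_both_strands = TRUE) {
  stopifnot(min_identity > 0, min_identity <= 100,
            min_length >= kmer_size, kmer_size >= 8, kmer_size <= 32,
            match_score > 0, mismatch_score < 0, gap_open <= 0,
            gap_extend < 0, band >= 1)
  structure(list(
    min_identity = min_identity, min_length = as.integer(min_length),
    kmer_size = as.integer(kmer_size), xdrop = as.integer(xdrop),
    match_score = as.integer(match_score),
    mismatch_score = as.integer(mismatch_score),
    gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
    band = as.integer(band), extend_margin = as.integer(extend_margin),
    search_both_strands = isTRUE(search_both_strands)
  ), class = "homology_params")
}

#' Local alignments between two nucleotide sequences
#'
#' Seed-and-extend local alignment: exact k-mer seeds shared between the two
#' sequences are clustered by diagonal and resolved with a banded affine-gap
#' local alignment around each cluster; overlapping alignments are merged
#' keeping the highest-scoring one. Deterministic; N never counts as a match.
#' An empty result is valid (no shared seed, or nothing passes thresholds).
#'
#' @param query,subject Nucleotide sequences (character or
#'   [Biostrings::DNAString]).
#' @param params A [homology_params()] object.
#' @param apply_thresholds Filter results at `min_identity`/`min_length`
#'   (default TRUE); permissive callers (the ANI module) disable this.
#' @return Data frame with pct_identity, aln_length, n_ident, q_start,
#'   q_end, s_start, s_end (0-based half-open on the input sequences),
#'   strand, score.
#' @export
align_pair <- function(query, subject, params = homology_params(),
                       apply_thresholds = TRUE) {
  query <- as.character(query)
  subject <- as.character(subject)
  stopifnot(nchar(query) > 0, nchar(subject) > 0)
  .align_pair_cpp(query, subject, params$kmer_size,
                  params$match_score, params$mismatch_score,
                  params$gap_open, params$gap_extend,
                  params$band, params$extend_margin,
                  if (apply_thresholds) params$min_identity else 0,
                  if (apply_thresholds) params$min_length else 1L,
                  params$search_both_strands)
}

empty_hits <- function() {
  data.frame(query_genome = character(0), query_gene = character(0),
             subject_genome = character(0), subject_gene = character(0),
             pct_identity = numeric(0), aln_length = integer(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             strand = character(0), score = integer(0),
             stringsAsFactors = FALSE)
}

#' All-vs-all CDS homology search across genomes
#'
#' Compares every CDS against the CDS of every *other* genome (self-genome
#' hits are never emitted) and reports the single best-scoring alignment per
#' gene pair that meets the identity and length thresholds. The hit table is
#' symmetric: if A -> B is reported, B -> A is reported too. Rows are sorted
#' by (query_genome, query_gene, subject_genome, subject_gene).
#'
#' Same-species (different genome) exclusion is *not* applied here: species
#' labels live in the detection stage (see [filter_hgt_hits()]), mirroring
#' the pipeline ordering search -> filter.
#'
#' @param genomes List of `genome_record`.
#' @param params A [homology_params()] object.
#' @return Hit data frame with columns query_genome, query_gene,
#'   subject_genome, subject_gene, pct_identity, aln_length, q_start, q_end,
#'   s_start, s_end, strand, score.
#' @export
search_all_vs_all <- function(genomes, params = homology_params()) {
  stopifnot(length(genomes) >= 2L)
  ids <- vapply(genomes, `[[`, "", "genome_id")
  if (anyDuplicated(ids)) stop("duplicated genome_id", call. = FALSE)
  seqsets <- lapply(genomes, gene_sequences)
  keys <- unlist(lapply(seq_along(genomes), function(i)
    paste0(ids[i], "|", names(seqsets[[i]]))))
  if (anyDuplicated(keys)) {
    stop("duplicated (genome_id, gene_id) across inputs", call. = FALSE)
  }

  rows <- list()
  for (i in seq_len(length(genomes) - 1L)) {
    for (j in seq(i + 1L, length(genomes))) {
      qs <- as.character(seqsets[[i]])
      ss <- as.character(seqsets[[j]])
      cand <- .kmer_pairs_cpp(qs, ss, params$kmer_size)
      if (nrow(cand) == 0L) next
      for (r in seq_len(nrow(cand))) {
        qi <- cand[r, 1L]; sj <- cand[r, 2L]
        alns <- align_pair(qs[[qi]], ss[[sj]], params)
        if (nrow(alns) == 0L) next
        # best-scoring alignment per gene pair; ties by q_start, then s_start
        best <- alns[order(-alns$score, alns$q_start, alns$s_start), ][1L, ]
        rows[[length(rows) + 1L]] <- data.frame(
          query_genome = ids[i], query_gene = names(qs)[qi],
          subject_genome = ids[j], subject_gene = names(ss)[sj],
          pct_identity = best$pct_identity, aln_length = best$aln_length,
          q_start = best$q_start, q_end = best$q_end,
          s_start = best$s_start, s_end = best$s_end,
          strand = best$strand, score = best$score,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else empty_hits()
  hits <- symmetrize_hits(hits)
  sort_hits(hits)
}

# add the mirrored direction for every hit (B -> A from A -> B)
symmetrize_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  mirror <- hits
  mirror$query_genome <- hits$subject_genome
  mirror$query_gene <- hits$subject_gene
  mirror$subject_genome <- hits$query_genome
  mirror$subject_gene <- hits$query_gene
  mirror$q_start <- hits$s_start; mirror$q_end <- hits$s_end
  mirror$s_start <- hits$q_start; mirror$s_end <- hits$q_end
  out <- rbind(hits, mirror)
  out[!duplicated(out[c("query_genome", "query_gene",
                        "subject_genome", "subject_gene")]), , drop = FALSE]
}

sort_hits <- function(hits) {
  o <- order(hits$query_genome, hits$query_gene, hits$subject_genome,
             hits$subject_gene)
  out <- hits[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Import 12-column tabular hits
#'
#' Reads the standard 12-column tabular hit report (qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore)
#' as produced by external search tools, converts the 1-based inclusive
#' coordinates to the internal 0-based half-open convention, drops
#' same-genome rows (counted in attribute `n_same_genome`), and applies the
#' identity and length thresholds exactly as the internal search does.
#'
#' @param path Tabular file path (no header).
#' @param id_map Either NULL (headers are expected to be of the form
#'   `genome_id|gene_id`), or a data frame with columns `header`,
#'   `genome_id`, `gene_id` resolving sequence headers.
#' @param params A [homology_params()] object (thresholds).
#' @return Hit data frame; attribute `n_same_genome` counts dropped rows.
#' @export
read_tabular_hits <- function(path, id_map = NULL,
                              params = homology_params()) {
  if (!file.exists(path)) stop("hit file not found: ", path, call. = FALSE)
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 12L) {
    stop("expected 12 tab-separated columns, got ", ncol(raw), call. = FALSE)
  }
  names(raw)[1:12] <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                        "gapopen", "qstart", "qend", "sstart", "send",
                        "evalue", "bitscore")
  for (col in c("pident", "length", "qstart", "qend", "sstart", "send")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v)) {
      stop("malformed value in column ", col, " at line ",
           which(is.na(v))[1L], call. = FALSE)
    }
    raw[[col]] <- v
  }
  resolve <- function(h) {
    if (is.null(id_map)) {
      parts <- strsplit(h, "|", fixed = TRUE)
      bad <- vapply(parts, length, 0L) < 2L
      if (any(bad)) {
        stop("cannot resolve sequence id: ", h[bad][1L], call. = FALSE)
      }
      data.frame(genome_id = vapply(parts, `[[`, "", 1L),
                 gene_id = vapply(parts, function(p)
                   paste(p[-1L], collapse = "|"), ""),
                 stringsAsFactors = FALSE)
    } else {
      i <- match(h, id_map$header)
      if (anyNA(i)) {
        stop("cannot resolve sequence id: ", h[is.na(i)][1L], call. = FALSE)
      }
      data.frame(genome_id = id_map$genome_id[i], gene_id = id_map$gene_id[i],
                 stringsAsFactors = FALSE)
    }
  }
  q <- resolve(raw$qseqid)
  s <- resolve(raw$sseqid)
  same <- q$genome_id == s$genome_id
  n_same <- sum(same)
  if (n_same > 0L) {
    warning(n_same, " same-genome row(s) dropped", call. = FALSE)
  }
  keep <- !same & raw$pident >= params$min_identity &
    raw$length >= params$min_length
  raw <- raw[keep, , drop = FALSE]
  q <- q[keep, , drop = FALSE]
  s <- s[keep, , drop = FALSE]
  # subject coordinates are reported descending on minus-strand hits
  minus <- raw$sstart > raw$send
  s_lo <- ifelse(minus, raw$send, raw$sstart)
  s_hi <- ifelse(minus, raw$sstart, raw$send)
  hits <- data.frame(
    query_genome = q$genome_id, query_gene = q$gene_id,
    subject_genome = s$genome_id, subject_gene = s$gene_id,
    pct_identity = raw$pident, aln_length = as.integer(raw$length),
    q_start = as.integer(raw$qstart) - 1L, q_end = as.integer(raw$qend),
    s_start = as.integer(s_lo) - 1L, s_end = as.integer(s_hi),
    strand = ifelse(minus, "-", "+"),
    score = as.integer(round(raw$bitscore)),
    stringsAsFactors = FALSE)
  hits <- sort_hits(symmetrize_hits(hits))
  attr(hits, "n_same_genome") <- n_same
  hits
}

#' Write / read the internal hit table
#'
#' Plain TSV with a header; columns as in the hit data frame.
#' @param hits Hit data frame.
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  if (!file.exists(path)) stop("hit file not found: ", path, call. = FALSE)
  hits <- read.delim(path, stringsAsFactors = FALSE)
  need <- names(empty_hits())
  missing <- setdiff(need, names(hits))
  if (length(missing)) {
    stop("hit table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  hits[need]
}
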
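#' ANI parameters
#'
#' Settings for fragment-based average nucleotide identity. Defaults follow
#' the widely used fragment-based ANI definition: the genome is cut into
#' 1000-nt non-overlapping fragments, each fragment is aligned against the
#' other genome, and a fragment contributes to the mean only when its best
#' hit reaches 70% identity over at least 70% of the fragment length. The
#' mean over both directions is the reported two-way ANI.
#'
#' @param fragment_length Fragment size in nt (default 1000).
#' @param fragment_step Tiling step (default 1000, i.e. non-overlapping;
#'   smaller values overlap fragments).
#' @param best_hit_min_identity Minimum percent identity for a qualifying
#'   best hit (default 70).
#' @param best_hit_min_coverage Minimum aligned fraction of the fragment for
#'   a qualifying best hit (default 0.70).
#' @param min_fragments Minimum number of qualifying fragments per direction
#'   for the ANI to be defined (default 5).
#' @param seed_size Seed k-mer length for the permissive fragment search
#'   (default 15; shorter than the homology default because fragments down
#'   to 70% identity must still be seedable).
#' @return An object of class `ani_params`.
#' @export
ani_params <- function(fragment_length = 1000L, fragment_step = 1000L,
                       best_hit_min_identity = 70.0,
                       best_hit_min_coverage = 0.70,
                       min_fragments = 5L, seed_size = 15L) {
  stopifnot(fragment_length > 0, fragment_step > 0,
            best_hit_min_coverage > 0, best_hit_min_coverage <= 1,
            best_hit_min_identity > 0, best_hit_min_identity <= 100,
            min_fragments >= 1)
  structure(list(
    fragment_length = as.integer(fragment_length),
    fragment_step = as.integer(fragment_step),
    best_hit_min_identity = best_hit_min_identity,
    best_hit_min_coverage = best_hit_min_coverage,
    min_fragments = as.integer(min_fragments),
    seed_size = as.integer(seed_size)
  ), class = "ani_params")
}

#' Tile a genome into ANI fragments
#'
#' Fragments tile each contig with the configured length and step; fragments
#' never span contigs. A terminal fragment shorter than `fragment_length` is
#' kept only when it is at least half the fragment length.
#'
#' @param genome A `genome_record`.
#' @param params An [ani_params()] object.
#' @return Data frame with contig_id, start (0-based) and sequence.
#' @export
fragment_genome <- function(genome, params = ani_params()) {
  stopifnot(inherits(genome, "genome_record"), length(genome$contigs) >= 1L)
  L <- params$fragment_length
  step <- params$fragment_step
  out <- list()
  seqs <- as.character(genome$contigs)
  for (cid in names(seqs)) {
    n <- nchar(seqs[[cid]])
    starts <- seq.int(0L, max(0L, n - 1L), by = step)
    for (st in starts) {
      en <- min(st + L, n)
      if (en - st < L && en - st < 0.5 * L) next
      out[[length(out) + 1L]] <- data.frame(
        contig_id = cid, start = st,
        sequence = substr(seqs[[cid]], st + 1L, en),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(contig_id = character(0), start = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# one direction: mean best-hit identity of A's fragments against B;
# the subject index is built once for all fragments
ani_one_way <- function(frags, subject_contigs, params) {
  if (nrow(frags) == 0L) return(list(n = 0L, mean = NA_real_))
  best <- .best_fragment_hits_cpp(
    frags$sequence, as.character(subject_contigs), params$seed_size,
    1L, -2L, -4L, -2L, 16L, 400L)
  flen <- nchar(frags$sequence)
  pct <- ifelse(best$aln_length > 0,
                100 * best$n_ident / best$aln_length, NA_real_)
  qual <- !is.na(pct) & pct >= params$best_hit_min_identity &
    best$aln_length >= params$best_hit_min_coverage * flen
  list(n = sum(qual),
       mean = if (any(qual)) mean(pct[qual]) else NA_real_)
}

#' Fragment-based ANI between two genomes
#'
#' Each fragment of genome A is aligned against all contigs of genome B
#' (permissive seed-and-extend search); the fragment qualifies when its best
#' hit reaches the identity and coverage thresholds, and the one-way ANI is
#' the mean identity over qualifying fragments. The two-way ANI is the mean
#' of both directions. When either direction has fewer than `min_fragments`
#' qualifying fragments the result is flagged `defined = FALSE` and the ANI
#' fields are NA (never silently 0): unrelated genomes have *undefined* ANI,
#' and downstream filtering treats them as distant.
#'
#' @param genome_a,genome_b `genome_record` objects.
#' @param params An [ani_params()] object.
#' @return List of class `ani_result` with genome_a, genome_b, ani_ab,
#'   ani_ba, ani_two_way, n_fragments_used_ab, n_fragments_used_ba, defined.
#' @export
compute_ani <- function(genome_a, genome_b, params = ani_params()) {
  fa <- fragment_genome(genome_a, params)
  fb <- fragment_genome(genome_b, params)
  ab <- ani_one_way(fa, genome_b$contigs, params)
  ba <- ani_one_way(fb, genome_a$contigs, params)
  defined <- ab$n >= params$min_fragments && ba$n >= params$min_fragments
  structure(list(
    genome_a = genome_a$genome_id, genome_b = genome_b$genome_id,
    ani_ab = if (defined) ab$mean else NA_real_,
    ani_ba = if (defined) ba$mean else NA_real_,
    ani_two_way = if (defined) mean(c(ab$mean, ba$mean)) else NA_real_,
    n_fragments_used_ab = ab$n, n_fragments_used_ba = ba$n,
    defined = defined
  ), class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("ANI %s ~ %s: %.3f (ab %.3f / ba %.3f; %d / %d fragments)\n",
                x$genome_a, x$genome_b, x$ani_two_way, x$ani_ab, x$ani_ba,
                x$n_fragments_used_ab, x$n_fragments_used_ba))
  } else {
    cat(sprintf("ANI %s ~ %s: undefined (%d / %d qualifying fragments)\n",
                x$genome_a, x$genome_b,
                x$n_fragments_used_ab, x$n_fragments_used_ba))
  }
  invisible(x)
}

#' Pairwise ANI table for a genome collection
#'
#' Computes [compute_ani()] for every unordered genome pair. The result is a
#' symmetric lookup: `ani_lookup(matrix, a, b)` equals `ani_lookup(matrix,
#' b, a)`.
#'
#' @param genomes List of `genome_record` (at least 2).
#' @param params An [ani_params()] object.
#' @return Data frame of class `ani_table` with one row per unordered pair:
#'   genome_a, genome_b, ani_ab, ani_ba, ani_two_way, n_frag_ab, n_frag_ba,
#'   defined.
#' @export
build_ani_matrix <- function(genomes, params = ani_params()) {
  stopifnot(length(genomes) >= 2L)
  rows <- list()
  for (i in seq_len(length(genomes) - 1L)) {
    for (j in seq(i + 1L, length(genomes))) {
      r <- compute_ani(genomes[[i]], genomes[[j]], params)
      rows[[length(rows) + 1L]] <- data.frame(
        genome_a = r$genome_a, genome_b = r$genome_b,
        ani_ab = r$ani_ab, ani_ba = r$ani_ba,
        ani_two_way = r$ani_two_way,
        n_frag_ab = r$n_fragments_used_ab, n_frag_ba = r$n_fragments_used_ba,
        defined = r$defined, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ani_table", "data.frame")
  out
}

#' Look up the two-way ANI for a genome pair
#'
#' @param ani An `ani_table` from [build_ani_matrix()] or [read_ani_tsv()].
#' @param a,b Genome ids (order irrelevant).
#' @return The two-way ANI in percent, or NA when the pair's ANI is
#'   undefined or the pair is absent.
#' @export
ani_lookup <- function(ani, a, b) {
  hit <- (ani$genome_a == a & ani$genome_b == b) |
         (ani$genome_a == b & ani$genome_b == a)
  if (!any(hit)) return(NA_real_)
  ani$ani_two_way[which(hit)[1L]]
}

#' Write / read an ANI table as TSV
#'
#' Values are serialized at 4 decimals; a written-then-read table is
#' identical to that precision.
#'
#' @param ani An `ani_table`.
#' @param path TSV path.
#' @export
write_ani_tsv <- function(ani, path) {
  out <- ani
  for (col in c("ani_ab", "ani_ba", "ani_two_way")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA", sprintf("%.4f", out[[col]]))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ani_tsv
#' @param genome_ids Optional character vector of genome ids; when given,
#'   the table is validated to contain every unordered pair and an error
#'   lists any gaps.
#' @export
read_ani_tsv <- function(path, genome_ids = NULL) {
  if (!file.exists(path)) stop("ANI file not found: ", path, call. = FALSE)
  ani <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("genome_a", "genome_b", "ani_ab", "ani_ba", "ani_two_way",
            "n_frag_ab", "n_frag_ba", "defined")
  missing <- setdiff(need, names(ani))
  if (length(missing)) {
    stop("ANI table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ani$defined <- as.logical(ani$defined)
  if (!is.null(genome_ids)) {
    pairs <- t(utils::combn(sort(genome_ids), 2L))
    have <- paste(pmin(ani$genome_a, ani$genome_b),
                  pmax(ani$genome_a, ani$genome_b))
    want <- paste(pairs[, 1L], pairs[, 2L])
    gaps <- setdiff(want, have)
    if (length(gaps)) {
      stop("ANI table is missing pair(s): ", paste(gaps, collapse = "; "),
           call. = FALSE)
    }
  }
  class(ani) <- c("ani_table", "data.frame")
  ani
}
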
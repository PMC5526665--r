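#' Read an annotated bacterial genome
#'
#' Parses a genome plus its CDS annotation into the internal `genome_record`
#' model used throughout the package. Two layouts are supported: a GenBank
#' flat file (one or more LOCUS records, CDS features with location and
#' qualifiers), or a FASTA file of contigs accompanied by a GFF3 sidecar with
#' CDS lines (same path with extension `.gff`/`.gff3`, or given explicitly).
#'
#' Input coordinates (1-based, inclusive) are converted to the internal
#' 0-based half-open convention. CDS with unresolvable coordinates (e.g.
#' beyond the contig end, or joins across contigs) are skipped and counted in
#' the parse report. Compound locations within one contig are flattened to
#' their enclosing interval. Ambiguity codes other than N are mapped to N.
#'
#' @param path Path to a GenBank file or a contig FASTA.
#' @param format_hint One of `"auto"`, `"genbank"`, `"fasta+gff3"`.
#' @param gff_path Optional explicit GFF3 path for the `fasta+gff3` layout.
#' @param genome_id Genome identifier; defaults to the file base name.
#'   Must contain no whitespace or path separators.
#' @param species_label,genus,phylum Optional taxon labels (usually supplied
#'   later via a metadata table, see [read_genome_metadata()]).
#' @return A `genome_record`: list with `genome_id`, `species_label`,
#'   `genus`, `phylum`, `contigs` (named [Biostrings::DNAStringSet]), `genes`
#'   (data.frame: gene_id, contig_id, start, end, strand, product) and
#'   `parse_report` (list with `n_skipped`).
#' @export
read_genome <- function(path, format_hint = c("auto", "genbank", "fasta+gff3"),
                        gff_path = NULL, genome_id = NULL,
                        species_label = "", genus = "", phylum = "") {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(gb|gbk|gbff|genbank|fa|fna|fasta)$", "",
                     basename(path), ignore.case = TRUE)
  }
  if (grepl("[[:space:]/\\\\]", genome_id)) {
    stop("genome_id must contain no whitespace or path separators: ",
         genome_id, call. = FALSE)
  }
  if (format_hint == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format_hint <- if (length(first) && grepl("^LOCUS", first)) "genbank"
                   else "fasta+gff3"
  }
  if (format_hint == "genbank") {
    parsed <- parse_genbank(path)
  } else {
    if (is.null(gff_path)) {
      cand <- c(sub("\\.[^.]+$", ".gff3", path), sub("\\.[^.]+$", ".gff", path))
      gff_path <- cand[file.exists(cand)][1]
      if (is.na(gff_path)) {
        stop("no GFF3 sidecar found for ", path, call. = FALSE)
      }
    }
    parsed <- parse_fasta_gff3(path, gff_path)
  }
  contigs <- clean_ambiguity(parsed$contigs)
  genes <- parsed$genes
  n_skipped <- parsed$n_skipped

  # validate coordinates against contig bounds; skip unresolvable features
  clen <- setNames(Biostrings::width(contigs), names(contigs))
  ok <- genes$contig_id %in% names(contigs) &
    genes$start >= 0L & genes$end > genes$start &
    genes$end <= clen[genes$contig_id]
  ok[is.na(ok)] <- FALSE
  n_skipped <- n_skipped + sum(!ok)
  genes <- genes[ok, , drop = FALSE]
  rownames(genes) <- NULL
  if (nrow(genes) == 0L) {
    stop("no CDS features parsed from ", path, call. = FALSE)
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicated gene_id within genome ", genome_id, call. = FALSE)
  }
  new_genome_record(genome_id, species_label, genus, phylum, contigs, genes,
                    n_skipped)
}

new_genome_record <- function(genome_id, species_label, genus, phylum,
                              contigs, genes, n_skipped = 0L) {
  stopifnot(all(genes$strand %in% c("+", "-")))
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  structure(list(
    genome_id = genome_id,
    species_label = species_label,
    genus = genus,
    phylum = phylum,
    contigs = contigs,
    genes = genes,
    parse_report = list(n_skipped = as.integer(n_skipped))
  ), class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("genome_record %s (%s): %d contig(s), %d CDS, %d skipped\n",
              x$genome_id,
              if (nzchar(x$species_label)) x$species_label else "unlabelled",
              length(x$contigs), nrow(x$genes), x$parse_report$n_skipped))
  invisible(x)
}

# map IUPAC ambiguity codes other than N to N; the aligner treats any
# non-ACGT base as a universal mismatch
clean_ambiguity <- function(contigs) {
  seqs <- toupper(as.character(contigs))
  seqs <- gsub("[^ACGT]", "N", seqs)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(contigs)
  out
}

# --- GenBank flat-file parsing --------------------------------------------
#
# Minimal parser for LOCUS records with a FEATURES table and ORIGIN block:
# enough for IMG/ER- or RefSeq-style annotated genomes. Only CDS features
# are extracted; location strings may use complement() and join(); compound
# locations within one contig are flattened to min..max.
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec_starts <- grep("^LOCUS", lines)
  if (length(rec_starts) == 0L) {
    stop("not a GenBank flat file (no LOCUS line): ", path, call. = FALSE)
  }
  rec_ends <- c(rec_starts[-1L] - 1L, length(lines))
  contig_seqs <- character(0)
  genes <- list()
  n_skipped <- 0L
  auto_id <- 0L
  for (r in seq_along(rec_starts)) {
    rec <- lines[rec_starts[r]:rec_ends[r]]
    contig_id <- strsplit(trimws(rec[1L]), "[[:space:]]+")[[1L]][2L]
    if (is.na(contig_id)) contig_id <- sprintf("contig%03d", r)

    origin_at <- grep("^ORIGIN", rec)
    seq <- ""
    if (length(origin_at)) {
      body <- rec[(origin_at[1L] + 1L):length(rec)]
      body <- body[!grepl("^//", body)]
      seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
    }
    contig_seqs[contig_id] <- seq

    feat_at <- grep("^FEATURES", rec)
    if (!length(feat_at)) next
    feat_end <- if (length(origin_at)) origin_at[1L] - 1L else length(rec)
    feat <- rec[(feat_at[1L] + 1L):feat_end]
    # feature headers start at column 6; qualifiers are indented further
    hdr <- grepl("^ {5}\\S", feat)
    idx <- which(hdr)
    if (!length(idx)) next
    ends <- c(idx[-1L] - 1L, length(feat))
    for (f in seq_along(idx)) {
      block <- feat[idx[f]:ends[f]]
      key <- strsplit(trimws(block[1L]), "[[:space:]]+")[[1L]]
      if (key[1L] != "CDS") next
      # location may continue over multiple lines until the first qualifier
      qual_at <- grep("^\\s+/", block)
      loc_end <- if (length(qual_at)) qual_at[1L] - 1L else length(block)
      loc <- paste(trimws(sub("^\\s*CDS\\s*", "", block[1:loc_end])),
                   collapse = "")
      parsed_loc <- parse_gb_location(loc)
      if (is.null(parsed_loc)) { n_skipped <- n_skipped + 1L; next }
      qtext <- paste(block, collapse = "\n")
      gene_id <- gb_qualifier(qtext, "locus_tag")
      if (is.na(gene_id)) gene_id <- gb_qualifier(qtext, "protein_id")
      if (is.na(gene_id)) {
        auto_id <- auto_id + 1L
        gene_id <- sprintf("cds%05d", auto_id)
      }
      product <- gb_qualifier(qtext, "product")
      if (is.na(product)) product <- ""
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gene_id, contig_id = contig_id,
        start = parsed_loc$start - 1L, end = parsed_loc$end,
        strand = parsed_loc$strand, product = product,
        stringsAsFactors = FALSE)
    }
  }
  contigs <- Biostrings::DNAStringSet(
    gsub("[^ACGTN]", "N", contig_seqs))
  names(contigs) <- names(contig_seqs)
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(0), contig_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               product = character(0), stringsAsFactors = FALSE)
  list(contigs = contigs, genes = genes, n_skipped = n_skipped)
}

# Parse a GenBank location string. Returns list(start, end, strand) in
# 1-based inclusive coordinates, or NULL when unresolvable (references to
# other records, i.e. cross-contig joins, or no digits).
parse_gb_location <- function(loc) {
  loc <- gsub("[[:space:]<>]", "", loc)
  if (grepl(":", loc, fixed = TRUE)) return(NULL)  # ACCESSION:pos form
  strand <- if (grepl("complement", loc)) "-" else "+"
  nums <- suppressWarnings(as.integer(
    regmatches(loc, gregexpr("[0-9]+", loc))[[1L]]))
  if (length(nums) < 2L || anyNA(nums)) return(NULL)
  list(start = min(nums), end = max(nums), strand = strand)
}

gb_qualifier <- function(qtext, name) {
  pat <- paste0("/", name, "=\"([^\"]*)\"")
  m <- regmatches(qtext, regexec(pat, qtext))[[1L]]
  if (length(m) < 2L) NA_character_ else gsub("\\s+", " ", m[2L])
}

# --- FASTA + GFF3 ----------------------------------------------------------
parse_fasta_gff3 <- function(fasta_path, gff_path) {
  contigs <- Biostrings::readDNAStringSet(fasta_path)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  gff <- rtracklayer::import(gff_path, format = "gff3")
  gff <- gff[gff$type == "CDS"]
  n_skipped <- 0L
  if (length(gff) == 0L) {
    genes <- data.frame(gene_id = character(0), contig_id = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), product = character(0),
                        stringsAsFactors = FALSE)
    return(list(contigs = contigs, genes = genes, n_skipped = n_skipped))
  }
  ids <- if (!is.null(gff$ID)) as.character(gff$ID) else NA_character_
  prod <- if (!is.null(gff$product)) as.character(gff$product) else ""
  prod[is.na(prod)] <- ""
  strand <- as.character(GenomicRanges::strand(gff))
  strand[!strand %in% c("+", "-")] <- "+"
  genes <- data.frame(
    gene_id = ids,
    contig_id = as.character(GenomicRanges::seqnames(gff)),
    start = GenomicRanges::start(gff) - 1L,
    end = GenomicRanges::end(gff),
    strand = strand,
    product = prod,
    stringsAsFactors = FALSE)
  if (anyNA(genes$gene_id)) {
    genes$gene_id[is.na(genes$gene_id)] <-
      sprintf("cds%05d", which(is.na(genes$gene_id)))
  }
  # a CDS split over multiple GFF3 lines (same ID) is flattened to its
  # enclosing interval on one contig; IDs spanning contigs are skipped
  if (anyDuplicated(genes$gene_id)) {
    parts <- split(genes, genes$gene_id)
    flat <- lapply(parts, function(p) {
      if (length(unique(p$contig_id)) > 1L) return(NULL)
      p$start[1L] <- min(p$start); p$end[1L] <- max(p$end)
      p[1L, , drop = FALSE]
    })
    n_skipped <- n_skipped + sum(vapply(flat, is.null, logical(1)))
    genes <- do.call(rbind, flat[!vapply(flat, is.null, logical(1))])
    genes <- genes[order(genes$contig_id, genes$start), , drop = FALSE]
    rownames(genes) <- NULL
  }
  list(contigs = contigs, genes = genes, n_skipped = n_skipped)
}

# --- derived accessors -----------------------------------------------------

#' Strand-resolved CDS sequences of a genome
#'
#' @param genome A `genome_record`.
#' @return A named [Biostrings::DNAStringSet], one entry per CDS (minus-strand
#'   features reverse-complemented), names = gene_id.
#' @export
gene_sequences <- function(genome) {
  stopifnot(inherits(genome, "genome_record"))
  g <- genome$genes
  seqs <- character(nrow(g))
  contigs <- as.character(genome$contigs)
  for (i in seq_len(nrow(g))) {
    s <- substr(contigs[[g$contig_id[i]]], g$start[i] + 1L, g$end[i])
    if (g$strand[i] == "-") s <- .revcomp_cpp(s)
    seqs[i] <- s
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- g$gene_id
  out
}

#' Per-gene table of a genome
#'
#' @param genome A `genome_record`.
#' @return Data frame with genome_id, gene_id, contig_id, start, end, strand,
#'   length and product columns (0-based half-open coordinates).
#' @export
genes_table <- function(genome) {
  stopifnot(inherits(genome, "genome_record"))
  g <- genome$genes
  data.frame(genome_id = genome$genome_id, gene_id = g$gene_id,
             contig_id = g$contig_id, start = g$start, end = g$end,
             strand = g$strand, length = g$end - g$start,
             product = g$product, stringsAsFactors = FALSE)
}

#' Write per-gene FASTA for one genome
#'
#' One record per CDS with header `genome_id|gene_id`; writing then reading
#' preserves sequences exactly.
#'
#' @param genome A `genome_record`.
#' @param out Output FASTA path.
#' @return Invisibly, the number of records written.
#' @export
write_gene_fasta <- function(genome, out) {
  seqs <- gene_sequences(genome)
  if (length(seqs) == 0L) {
    stop("genome ", genome$genome_id, " has no CDS to write", call. = FALSE)
  }
  names(seqs) <- paste0(genome$genome_id, "|", names(seqs))
  dir_ok <- dir.exists(dirname(out))
  if (!dir_ok) stop("cannot write to ", out, call. = FALSE)
  Biostrings::writeXStringSet(seqs, out)
  invisible(length(seqs))
}

#' Read a genome metadata table
#'
#' Tab-separated with header columns `genome_id`, `species_label`, `genus`,
#' `phylum` (the last two may be empty). Species, genus and phylum labels are
#' curated inputs; they are never inferred from sequence.
#'
#' @param path Metadata TSV path.
#' @return Data frame keyed by genome_id.
#' @export
read_genome_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  meta <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("genome_id", "species_label", "genus", "phylum")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta$genome_id)) {
    stop("duplicated genome_id in metadata", call. = FALSE)
  }
  meta[need]
}

#' Attach metadata labels to genome records
#'
#' @param genomes List of `genome_record`.
#' @param meta Data frame from [read_genome_metadata()].
#' @return The list with species/genus/phylum labels filled in.
#' @export
apply_metadata <- function(genomes, meta) {
  idx <- match(vapply(genomes, `[[`, "", "genome_id"), meta$genome_id)
  for (i in seq_along(genomes)) {
    if (is.na(idx[i])) next
    genomes[[i]]$species_label <- meta$species_label[idx[i]]
    genomes[[i]]$genus <- meta$genus[idx[i]]
    genomes[[i]]$phylum <- meta$phylum[idx[i]]
  }
  genomes
}

# metadata table from the records themselves (synthetic communities carry
# their labels); used when no external TSV is supplied
metadata_from_genomes <- function(genomes) {
  data.frame(
    genome_id = vapply(genomes, `[[`, "", "genome_id"),
    species_label = vapply(genomes, `[[`, "", "species_label"),
    genus = vapply(genomes, `[[`, "", "genus"),
    phylum = vapply(genomes, `[[`, "", "phylum"),
    stringsAsFactors = FALSE)
}
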
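# Fixtures are built in code at test time; nothing binary ships with the
# package.

# construct a genome_record directly (bypassing file I/O)
make_record <- function(genome_id, contigs, genes,
                        species = paste0("Species_", genome_id),
                        genus = "", phylum = "") {
  hgtscan:::new_genome_record(
    genome_id, species, genus, phylum,
    Biostrings::DNAStringSet(contigs), genes)
}

gene_row <- function(gene_id, contig_id, start, end, strand = "+",
                     product = "hypothetical protein") {
  data.frame(gene_id = gene_id, contig_id = contig_id,
             start = as.integer(start), end = as.integer(end),
             strand = strand, product = product, stringsAsFactors = FALSE)
}

# a single-contig genome whose only notable content is the given genes,
# embedded in random background
make_simple_genome <- function(genome_id, gene_seqs, gap = 2000L,
                               flank = 1500L, species = NULL,
                               genus = "", phylum = "") {
  seqs <- as.character(gene_seqs)
  n <- length(seqs)
  parts <- character(0)
  genes <- list()
  pos <- 0L
  for (i in seq_len(n)) {
    pad <- hgtscan::random_sequence(if (i == 1L) flank else gap, 0.5)
    parts <- c(parts, pad, seqs[i])
    pos <- pos + nchar(pad)
    genes[[i]] <- gene_row(sprintf("gene%02d", i), "c1", pos,
                           pos + nchar(seqs[i]))
    pos <- pos + nchar(seqs[i])
  }
  parts <- c(parts, hgtscan::random_sequence(flank, 0.5))
  make_record(genome_id, c(c1 = paste(parts, collapse = "")),
              do.call(rbind, genes),
              species = if (is.null(species)) paste0("Species_", genome_id)
                        else species,
              genus = genus, phylum = phylum)
}

# minimal GenBank flat file writer for parser tests
write_genbank <- function(path, contigs, cds) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cid in names(contigs)) {
    seq <- contigs[[cid]]
    writeLines(sprintf("LOCUS       %s %d bp DNA linear", cid, nchar(seq)),
               con)
    writeLines("FEATURES             Location/Qualifiers", con)
    rows <- cds[cds$contig_id == cid, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      loc <- sprintf("%d..%d", rows$start1[i], rows$end1[i])
      if (rows$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"",
                         rows$gene_id[i]), con)
      writeLines(sprintf("                     /product=\"%s\"",
                         rows$product[i]), con)
    }
    writeLines("ORIGIN", con)
    for (off in seq(1L, nchar(seq), by = 60L)) {
      writeLines(sprintf("%9d %s", off,
                         substr(seq, off, min(off + 59L, nchar(seq)))), con)
    }
    writeLines("//", con)
  }
  path
}

# full Smith-Waterman oracle (independent of the seed-and-extend path);
# same scoring scheme: match +1, mismatch -2, gap open -4, gap extend -2,
# best of both subject strands
sw_oracle <- function(q, s) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  one <- function(subj) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(q), Biostrings::DNAString(subj), type = "local",
      substitutionMatrix = mat, gapOpening = 4, gapExtension = 2)
    list(score = Biostrings::score(pa), n_ident = Biostrings::nmatch(pa),
         cols = Biostrings::nchar(pa))
  }
  fwd <- one(s)
  rev <- one(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s))))
  if (rev$score > fwd$score) rev else fwd
}

# brute-force transitive closure over islands sharing genes via edges;
# independent of igraph
brute_force_groups <- function(island_gene_sets, edge_pairs) {
  n <- length(island_gene_sets)
  comp <- seq_len(n)
  linked <- function(i, j) {
    any(vapply(seq_len(nrow(edge_pairs)), function(r) {
      (edge_pairs[r, 1L] %in% island_gene_sets[[i]] &&
         edge_pairs[r, 2L] %in% island_gene_sets[[j]]) ||
        (edge_pairs[r, 2L] %in% island_gene_sets[[i]] &&
           edge_pairs[r, 1L] %in% island_gene_sets[[j]])
    }, TRUE))
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (comp[i] != comp[j] && nrow(edge_pairs) > 0L && linked(i, j)) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# substitute exactly the given 1-based positions, rotating A->C->G->T->A
substitute_at <- function(seq, positions) {
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  chars[positions] <- rot[chars[positions]]
  paste(chars, collapse = "")
}

hamming_pct <- function(a, b) {
  100 * sum(charToRaw(a) == charToRaw(b)) / nchar(a)
}

# the acceptance-scale community: 8 genomes x 100 kb, two planted islands
# (divergence 0 and 0.005), one relative pair at rate 0.05, one transposon
# confounder bridging the two islands
acceptance_community_config <- function(seed = 20240611) {
  community_config(
    n_genomes = 8, genome_length = 100000L, seed = seed,
    relative_pairs = list(relative_pair("g7", "g8", 0.05)),
    planted_islands = list(
      island_spec("islA", donor = "g1", recipients = c("g2", "g3"),
                  n_genes = 5L, divergence = 0),
      island_spec("islB", donor = "g4", recipients = c("g5", "g6"),
                  n_genes = 4L, divergence = 0.005)),
    transposons = list(transposon_spec(
      "tn1", genomes = c("g1", "g2", "g3", "g4", "g5", "g6"),
      adjacent_to = c(NA, "islA", NA, NA, "islB", NA))))
}
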
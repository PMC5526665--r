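# Seeded synthetic communities with planted gene transfer.
#
# Backgrounds are independent random sequences, so any near-identical
# cross-genome similarity is either planted (islands, transposons) or
# vertical (relative pairs built by whole-genome mutation of a shared
# ancestor). Substitution-only divergence keeps identity and ANI analytic:
# Hamming distance is the exact pairwise divergence, which makes recovery
# thresholds checkable without an aligner.

#' Random nucleotide sequence at a target GC content
#'
#' @param length Sequence length.
#' @param gc_content GC fraction in `[0,1]`.
#' @return Character scalar.
#' @export
random_sequence <- function(length, gc_content = 0.5) {
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p),
        collapse = "")
}

#' Mutate a sequence at a fixed per-site rate
#'
#' Each position mutates independently with probability `rate`;
#' substitutions are drawn uniformly over the three alternative bases (so
#' the Hamming distance to the input equals the realized substitution
#' count). With `allow_indels`, 10% of mutation events become short (1-3 nt)
#' insertions or deletions instead. Positions that are not A/C/G/T are left
#' untouched. Deterministic given `seed`.
#'
#' @param seq Nucleotide sequence (character scalar).
#' @param rate Per-site mutation probability in `[0,1)`.
#' @param seed Optional integer seed; when given the global RNG state is
#'   left untouched.
#' @param allow_indels Allow short indels (default FALSE).
#' @return The mutated sequence with attributes `n_substitutions`,
#'   `n_insertions`, `n_deletions` and `realized_rate` (events per input
#'   site).
#' @export
mutate_sequence <- function(seq, rate, seed = NULL, allow_indels = FALSE) {
  stopifnot(rate >= 0, rate < 1)
  run <- function() {
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    n <- length(chars)
    mutable <- chars %in% c("A", "C", "G", "T")
    hit <- runif(n) < rate & mutable
    idx <- which(hit)
    is_indel <- if (allow_indels && length(idx)) runif(length(idx)) < 0.1
                else rep(FALSE, length(idx))
    n_ins <- 0L; n_del <- 0L
    sub_idx <- idx[!is_indel]
    # substitution: uniformly one of the three other bases
    if (length(sub_idx)) {
      bases <- c("A", "C", "G", "T")
      for (i in sub_idx) {
        chars[i] <- sample(setdiff(bases, chars[i]), 1L)
      }
    }
    if (any(is_indel)) {
      # apply indels right-to-left so earlier coordinates stay valid
      for (i in rev(idx[is_indel])) {
        len <- sample(1:3, 1L)
        if (runif(1L) < 0.5) {
          ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                       collapse = "")
          chars[i] <- paste0(chars[i], ins)
          n_ins <- n_ins + 1L
        } else {
          drop <- i:min(length(chars), i + len - 1L)
          chars[drop] <- ""
          n_del <- n_del + 1L
        }
      }
    }
    out <- paste(chars, collapse = "")
    attr(out, "n_substitutions") <- length(sub_idx)
    attr(out, "n_insertions") <- n_ins
    attr(out, "n_deletions") <- n_del
    attr(out, "realized_rate") <- length(idx) / max(1L, n)
    out
  }
  if (is.null(seed)) run() else with_preserved_rng(seed, run())
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of one planted island
#'
#' A multi-gene cassette (genes separated by short intergenic gaps) built in
#' a donor genome and copied contiguously into each recipient at a
#' controlled per-site divergence (substitution-only).
#'
#' @param spec_id Unique island identifier.
#' @param donor Donor genome id.
#' @param recipients Character vector of recipient genome ids.
#' @param n_genes Number of genes in the cassette.
#' @param gene_lengths Gene lengths in nt (recycled/validated against
#'   `n_genes`); NULL draws uniformly from 600-1200 nt.
#' @param intergene_gaps Gaps between consecutive genes (length
#'   `n_genes - 1`); NULL draws uniformly from 200-1500 nt (always below
#'   the 5 kb island-merging distance).
#' @param divergence Per-site substitution rate applied to each recipient
#'   copy (default 0).
#' @return An `island_spec` list.
#' @export
island_spec <- function(spec_id, donor, recipients, n_genes = 5L,
                        gene_lengths = NULL, intergene_gaps = NULL,
                        divergence = 0) {
  stopifnot(n_genes >= 1, divergence >= 0, divergence < 1,
            length(recipients) >= 1)
  if (!is.null(gene_lengths)) stopifnot(length(gene_lengths) == n_genes)
  if (!is.null(intergene_gaps) && n_genes > 1L) {
    stopifnot(length(intergene_gaps) == n_genes - 1L,
              all(intergene_gaps < 5000))
  }
  structure(list(spec_id = spec_id, donor = donor, recipients = recipients,
                 n_genes = as.integer(n_genes), gene_lengths = gene_lengths,
                 intergene_gaps = intergene_gaps, divergence = divergence),
            class = "island_spec")
}

#' Specification of a transposon confounder
#'
#' One short (default 1.2 kb) mobile-element sequence copied *verbatim* into
#' several genomes. A placement may be anchored next to a planted island
#' (within the island-merging distance), which chains otherwise unrelated
#' groups together -- the documented group-merging artifact.
#'
#' @param tn_id Unique transposon identifier.
#' @param genomes Genomes receiving one copy each.
#' @param adjacent_to Character vector parallel to `genomes`: the spec_id of
#'   the island the copy should land next to, or NA for a standalone locus.
#' @param length Element length in nt (default 1200).
#' @return A `transposon_spec` list.
#' @export
transposon_spec <- function(tn_id, genomes, adjacent_to = NULL,
                            length = 1200L) {
  if (is.null(adjacent_to)) adjacent_to <- rep(NA_character_, length(genomes))
  stopifnot(length(adjacent_to) == length(genomes), length >= 500)
  structure(list(tn_id = tn_id, genomes = genomes,
                 adjacent_to = adjacent_to, length = as.integer(length)),
            class = "transposon_spec")
}

#' Specification of a vertically related genome pair
#'
#' The second genome is a whole-genome mutated copy of the first at the
#' stated substitution rate, so the expected ANI of the pair is
#' `100 * (1 - rate)`. A small number of genes are kept identical between
#' the two (highly conserved core genes): these trip the homology threshold
#' and must be removed by the ANI filter, never by luck.
#'
#' @param genome_i,genome_j Genome ids (genome_j is derived from genome_i).
#' @param substitution_rate Per-site substitution rate in `[0,1)`.
#' @param n_conserved_genes Background genes copied unmutated (default 2).
#' @return A `relative_pair` list.
#' @export
relative_pair <- function(genome_i, genome_j, substitution_rate,
                          n_conserved_genes = 2L) {
  stopifnot(substitution_rate >= 0, substitution_rate < 1)
  structure(list(genome_i = genome_i, genome_j = genome_j,
                 substitution_rate = substitution_rate,
                 n_conserved_genes = as.integer(n_conserved_genes)),
            class = "relative_pair")
}

#' Synthetic community configuration
#'
#' @param n_genomes Number of genomes (ids `g1`, `g2`, ...).
#' @param genome_length Length of each (single-contig) genome in nt.
#' @param gc_content Background GC fraction.
#' @param genes_per_genome Background genes per genome.
#' @param gene_length_range Min/max background gene length in nt.
#' @param core_length Length of the shared ancestral core region in nt
#'   (default 15000). Real bacterial genomes -- however distantly related --
#'   share universally conserved sequence (ribosomal RNA operons and other
#'   core loci) at moderate identity; it is this alignable core that anchors
#'   cross-genus ANI in the 70-85% range. Each genome carries a copy of a
#'   community-wide ancestral core, independently mutated at
#'   `core_divergence`, so that unrelated genome pairs have a defined,
#'   realistically low ANI instead of aligning nowhere outside planted
#'   elements. The core carries no CDS annotation.
#' @param core_divergence Per-genome substitution rate applied to the
#'   ancestral core (default 0.12, giving ~78% pairwise identity between
#'   unrelated genomes).
#' @param relative_pairs List of [relative_pair()] objects.
#' @param planted_islands List of [island_spec()] objects.
#' @param transposons List of [transposon_spec()] objects.
#' @param seed Integer seed (mandatory: communities are reproducible by
#'   construction).
#' @return A `community_config` list.
#' @export
community_config <- function(n_genomes, genome_length = 100000L,
                             gc_content = 0.5, genes_per_genome = 25L,
                             gene_length_range = c(600L, 1500L),
                             core_length = 15000L, core_divergence = 0.12,
                             relative_pairs = list(),
                             planted_islands = list(),
                             transposons = list(), seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_genomes >= 1, genome_length >= 1000,
            gc_content > 0, gc_content < 1,
            core_length >= 0, core_length < genome_length,
            core_divergence >= 0, core_divergence < 1,
            gene_length_range[1L] <= gene_length_range[2L])
  ids <- paste0("g", seq_len(n_genomes))
  for (rp in relative_pairs) {
    stopifnot(inherits(rp, "relative_pair"),
              rp$genome_i %in% ids, rp$genome_j %in% ids)
  }
  spec_ids <- vapply(planted_islands, `[[`, "", "spec_id")
  if (anyDuplicated(spec_ids)) stop("duplicated spec_id", call. = FALSE)
  for (sp in planted_islands) {
    stopifnot(inherits(sp, "island_spec"),
              sp$donor %in% ids, all(sp$recipients %in% ids))
  }
  for (tn in transposons) {
    stopifnot(inherits(tn, "transposon_spec"), all(tn$genomes %in% ids))
  }
  structure(list(
    n_genomes = as.integer(n_genomes), genome_ids = ids,
    genome_length = as.integer(genome_length), gc_content = gc_content,
    genes_per_genome = as.integer(genes_per_genome),
    gene_length_range = as.integer(gene_length_range),
    core_length = as.integer(core_length),
    core_divergence = core_divergence,
    relative_pairs = relative_pairs, planted_islands = planted_islands,
    transposons = transposons, seed = as.integer(seed)
  ), class = "community_config")
}

# Clearance kept between independently placed elements so planted islands
# never merge by accident (must exceed the 5 kb island-joining distance).
PLACEMENT_CLEARANCE <- 6000L
# An island may later receive an adjacency-anchored transposon on its right
# (gap up to 4.5 kb + 1.2 kb element + 5 kb separation), so that zone is
# reserved at island placement time.
ADJACENCY_RESERVE <- 11000L

#' Generate a synthetic community with ground truth
#'
#' Builds `n_genomes` single-contig genomes: independent random backgrounds
#' with non-overlapping background genes in the front portion; relative
#' pairs as whole-genome mutated copies; island cassettes written into the
#' gene-free tail of donor and recipients (recipient copies mutated at the
#' island's divergence); transposon copies written verbatim, optionally
#' adjacent (within 5 kb) to a planted island. Byte-identical output for
#' identical configs.
#'
#' @param config A [community_config()] object.
#' @param truth_params A [homology_params()] object defining detectability:
#'   a planted copy is detectable when some partner copy of the same element
#'   is within the identity threshold over at least the length threshold
#'   (computed by exact Hamming identity, substitution-only construction).
#' @param detect_params A [detection_params()] object (island gap and ANI
#'   ceiling used for expected islands/groups).
#' @return List with `genomes` (list of `genome_record`) and `truth` (class
#'   `truth_set`; see Details).
#' @details The `truth_set` contains: `genes` (one row per planted copy:
#'   genome_id, gene_id, element_id, role, contig_id, start, end, length,
#'   detectable), `vertical_genes` (conserved genes of relative pairs, which
#'   must *not* be detected), `pair_identity` (exact pairwise identity
#'   between copies of each element), `expected_islands` (island partition
#'   of detectable planted genes by the gap rule), `expected_groups` (island
#'   partition into groups using only same-element links), and
#'   `expected_groups_merged` (the partition after transposon-induced
#'   chaining -- what proximity clustering is expected to report),
#'   `relative_pairs` (with expected ANI).
#' @export
generate_community <- function(config,
                               truth_params = homology_params(),
                               detect_params = detection_params()) {
  stopifnot(inherits(config, "community_config"))
  with_preserved_rng(config$seed, build_community(config, truth_params,
                                                  detect_params))
}

build_community <- function(config, truth_params, detect_params) {
  ids <- config$genome_ids
  L <- config$genome_length

  # --- backgrounds --------------------------------------------------------
  # every genome opens with its own mutated copy of a community-wide
  # ancestral core (unannotated), the alignable anchor for cross-pair ANI
  ancestral_core <- if (config$core_length > 0L) {
    random_sequence(config$core_length, config$gc_content)
  } else ""
  states <- list()
  for (g in ids) {
    glens <- sample(seq(config$gene_length_range[1L],
                        config$gene_length_range[2L]),
                    config$genes_per_genome, replace = TRUE)
    gaps <- sample(100:400, config$genes_per_genome, replace = TRUE)
    need <- config$core_length + sum(glens) + sum(gaps)
    if (need + PLACEMENT_CLEARANCE >= L) {
      stop("config infeasible: core and background genes do not fit in ",
           L, " nt", call. = FALSE)
    }
    seq <- random_sequence(L, config$gc_content)
    if (config$core_length > 0L) {
      core_copy <- as.character(
        mutate_sequence(ancestral_core, config$core_divergence))
      substr(seq, 1L, config$core_length) <- core_copy
    }
    pos <- config$core_length
    genes <- data.frame(gene_id = sprintf("bg%03d", seq_len(length(glens))),
                        contig_id = "c1",
                        start = integer(length(glens)),
                        end = integer(length(glens)),
                        strand = sample(c("+", "-"), length(glens),
                                        replace = TRUE),
                        product = "hypothetical protein",
                        stringsAsFactors = FALSE)
    for (i in seq_along(glens)) {
      pos <- pos + gaps[i]
      genes$start[i] <- pos
      genes$end[i] <- pos + glens[i]
      pos <- pos + glens[i]
    }
    states[[g]] <- list(seq = seq, genes = genes, tail_start = pos,
                        occupied = list())
  }

  # --- relative pairs -----------------------------------------------------
  vertical_rows <- list()
  rel_rows <- list()
  for (rp in config$relative_pairs) {
    si <- states[[rp$genome_i]]
    mut <- mutate_sequence(si$seq, rp$substitution_rate)
    sj <- list(seq = as.character(mut), genes = si$genes,
               tail_start = si$tail_start, occupied = list())
    n_cons <- min(rp$n_conserved_genes, nrow(si$genes))
    cons_idx <- if (n_cons > 0L) sort(sample(nrow(si$genes), n_cons))
                else integer(0)
    for (ci in cons_idx) {
      gstart <- si$genes$start[ci]; gend <- si$genes$end[ci]
      substr(sj$seq, gstart + 1L, gend) <- substr(si$seq, gstart + 1L, gend)
      vertical_rows[[length(vertical_rows) + 1L]] <- data.frame(
        element_id = paste0("vert_", rp$genome_i, "_", rp$genome_j),
        genome_id = c(rp$genome_i, rp$genome_j),
        gene_id = si$genes$gene_id[ci],
        length = gend - gstart, stringsAsFactors = FALSE)
    }
    states[[rp$genome_j]] <- sj
    rel_rows[[length(rel_rows) + 1L]] <- data.frame(
      genome_i = rp$genome_i, genome_j = rp$genome_j,
      substitution_rate = rp$substitution_rate,
      expected_ani = 100 * (1 - rp$substitution_rate),
      n_conserved_genes = n_cons, stringsAsFactors = FALSE)
  }

  # --- tail placement helpers ---------------------------------------------
  place_free <- function(state, len, reserve_right = 0L) {
    lo <- state$tail_start + PLACEMENT_CLEARANCE
    hi <- L - len - reserve_right - 100L
    if (hi <= lo) stop("config infeasible: no room in genome tail",
                       call. = FALSE)
    for (try in 1:500) {
      st <- sample(lo:hi, 1L)
      ok <- TRUE
      for (iv in state$occupied) {
        if (st - PLACEMENT_CLEARANCE < iv[2L] &&
            iv[1L] < st + len + reserve_right + PLACEMENT_CLEARANCE) {
          ok <- FALSE; break
        }
      }
      if (ok) return(st)
    }
    stop(sprintf(
      "config infeasible: could not place a %d nt element (tail %d-%d, %d elements already placed)",
      len, lo, hi, length(state$occupied)), call. = FALSE)
  }
  place_adjacent <- function(state, len, anchor_end) {
    gap <- sample(500:4500, 1L)
    st <- anchor_end + gap
    if (st + len + 100L > L) stop("config infeasible: adjacency placement",
                                  call. = FALSE)
    st
  }
  write_in <- function(state, at, cassette, reserve_right = 0L) {
    substr(state$seq, at + 1L, at + nchar(cassette)) <- cassette
    state$occupied[[length(state$occupied) + 1L]] <-
      c(at, at + nchar(cassette) + reserve_right)
    state
  }

  # --- island cassettes ---------------------------------------------------
  # only islands that may receive an adjacency-anchored transposon need the
  # right-hand reserve
  adj_targets <- unique(stats::na.omit(unlist(
    lapply(config$transposons, `[[`, "adjacent_to"))))
  truth_rows <- list()
  spec_layouts <- list()
  island_span <- list()  # per genome|spec: c(start, end) of the placed copy
  for (sp in config$planted_islands) {
    glens <- if (is.null(sp$gene_lengths))
      sample(600:1200, sp$n_genes, replace = TRUE) else sp$gene_lengths
    gaps <- if (sp$n_genes > 1L) {
      if (is.null(sp$intergene_gaps))
        sample(200:1500, sp$n_genes - 1L, replace = TRUE)
      else sp$intergene_gaps
    } else integer(0)
    cas_len <- sum(glens) + sum(gaps)
    cassette <- random_sequence(cas_len, config$gc_content)
    offs <- integer(sp$n_genes)
    pos <- 0L
    for (i in seq_len(sp$n_genes)) {
      offs[i] <- pos
      pos <- pos + glens[i] + if (i < sp$n_genes) gaps[i] else 0L
    }
    strands <- sample(c("+", "-"), sp$n_genes, replace = TRUE)
    spec_layouts[[sp$spec_id]] <- list(glens = glens, offs = offs,
                                       strands = strands, seq = cassette)
    carriers <- c(sp$donor, sp$recipients)
    for (g in carriers) {
      copy <- if (g == sp$donor) cassette else
        as.character(mutate_sequence(cassette, sp$divergence))
      reserve <- if (sp$spec_id %in% adj_targets) ADJACENCY_RESERVE else 0L
      at <- place_free(states[[g]], nchar(copy), reserve_right = reserve)
      states[[g]] <- write_in(states[[g]], at, copy,
                              reserve_right = reserve)
      island_span[[paste0(g, "|", sp$spec_id)]] <- c(at, at + nchar(copy))
      for (i in seq_len(sp$n_genes)) {
        gid <- sprintf("%s_%02d", sp$spec_id, i)
        states[[g]]$genes <- rbind(states[[g]]$genes, data.frame(
          gene_id = gid, contig_id = "c1",
          start = at + offs[i], end = at + offs[i] + glens[i],
          strand = strands[i], product = "hypothetical protein",
          stringsAsFactors = FALSE))
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          genome_id = g, gene_id = gid, element_id = sp$spec_id,
          element_gene = i, role = "island", contig_id = "c1",
          start = at + offs[i], end = at + offs[i] + glens[i],
          length = glens[i],
          sequence = substr(copy, offs[i] + 1L, offs[i] + glens[i]),
          stringsAsFactors = FALSE)
      }
    }
  }

  # --- transposon confounders ---------------------------------------------
  for (tn in config$transposons) {
    tseq <- random_sequence(tn$length, config$gc_content)
    for (t in seq_along(tn$genomes)) {
      g <- tn$genomes[t]
      anchor <- tn$adjacent_to[t]
      at <- if (!is.na(anchor)) {
        span <- island_span[[paste0(g, "|", anchor)]]
        if (is.null(span)) {
          stop("transposon anchored to island ", anchor,
               " absent from genome ", g, call. = FALSE)
        }
        place_adjacent(states[[g]], tn$length, span[2L])
      } else {
        place_free(states[[g]], tn$length)
      }
      states[[g]] <- write_in(states[[g]], at, tseq)
      gid <- paste0(tn$tn_id, "_cp")
      states[[g]]$genes <- rbind(states[[g]]$genes, data.frame(
        gene_id = gid, contig_id = "c1",
        start = at, end = at + tn$length, strand = "+",
        product = "IS3 family transposase", stringsAsFactors = FALSE))
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        genome_id = g, gene_id = gid, element_id = tn$tn_id,
        element_gene = 1L, role = "transposon", contig_id = "c1",
        start = at, end = at + tn$length, length = tn$length,
        sequence = tseq, stringsAsFactors = FALSE)
    }
  }

  # --- assemble genome records --------------------------------------------
  n <- length(ids)
  rel_j <- vapply(config$relative_pairs, `[[`, "", "genome_j")
  rel_i <- vapply(config$relative_pairs, `[[`, "", "genome_i")
  genomes <- vector("list", n)
  for (k in seq_len(n)) {
    g <- ids[k]
    st <- states[[g]]
    contigs <- Biostrings::DNAStringSet(setNames(st$seq, "c1"))
    genes <- st$genes[order(st$genes$start), , drop = FALSE]
    rownames(genes) <- NULL
    # relatives share a genus; everyone else gets their own
    genus <- if (g %in% rel_j) paste0("Genus_", rel_i[match(g, rel_j)])
             else paste0("Genus_", g)
    phylum <- if (g %in% rel_j) {
      paste0("Phylum", (match(rel_i[match(g, rel_j)], ids) - 1) %% 2 + 1)
    } else paste0("Phylum", (k - 1) %% 2 + 1)
    genomes[[k]] <- new_genome_record(
      genome_id = g, species_label = paste0("Species_", g),
      genus = genus, phylum = phylum, contigs = contigs, genes = genes)
  }
  names(genomes) <- ids

  truth <- build_truth(config, truth_rows, vertical_rows, rel_rows,
                       truth_params, detect_params)
  list(genomes = genomes, truth = truth)
}

# exact Hamming identity between equal-length sequences
hamming_identity <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  100 * sum(ra == rb) / length(ra)
}

build_truth <- function(config, truth_rows, vertical_rows, rel_rows,
                        truth_params, detect_params) {
  genes <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(genome_id = character(0), gene_id = character(0),
               element_id = character(0), element_gene = integer(0),
               role = character(0), contig_id = character(0),
               start = integer(0), end = integer(0), length = integer(0),
               sequence = character(0), stringsAsFactors = FALSE)
  vertical <- if (length(vertical_rows)) do.call(rbind, vertical_rows) else
    data.frame(element_id = character(0), genome_id = character(0),
               gene_id = character(0), length = integer(0),
               stringsAsFactors = FALSE)
  rels <- if (length(rel_rows)) do.call(rbind, rel_rows) else
    data.frame(genome_i = character(0), genome_j = character(0),
               substitution_rate = numeric(0), expected_ani = numeric(0),
               n_conserved_genes = integer(0), stringsAsFactors = FALSE)

  # exact pairwise identity between copies of the same element gene
  pid_rows <- list()
  if (nrow(genes)) {
    byg <- split(seq_len(nrow(genes)),
                 paste(genes$element_id, genes$element_gene))
    for (ii in byg) {
      if (length(ii) < 2L) next
      for (a in seq_len(length(ii) - 1L)) {
        for (b in seq(a + 1L, length(ii))) {
          ia <- ii[a]; ib <- ii[b]
          pid_rows[[length(pid_rows) + 1L]] <- data.frame(
            element_id = genes$element_id[ia],
            element_gene = genes$element_gene[ia],
            genome_a = genes$genome_id[ia], gene_a = genes$gene_id[ia],
            genome_b = genes$genome_id[ib], gene_b = genes$gene_id[ib],
            identity = hamming_identity(genes$sequence[ia],
                                        genes$sequence[ib]),
            length = genes$length[ia], stringsAsFactors = FALSE)
        }
      }
    }
  }
  pair_identity <- if (length(pid_rows)) do.call(rbind, pid_rows) else
    data.frame(element_id = character(0), element_gene = integer(0),
               genome_a = character(0), gene_a = character(0),
               genome_b = character(0), gene_b = character(0),
               identity = numeric(0), length = integer(0),
               stringsAsFactors = FALSE)

  # a copy is detectable when some partner copy is within the identity
  # threshold over at least the length threshold
  qualifying <- pair_identity[
    pair_identity$identity >= truth_params$min_identity &
      pair_identity$length >= truth_params$min_length, , drop = FALSE]
  det_keys <- unique(c(paste(qualifying$genome_a, qualifying$gene_a),
                       paste(qualifying$genome_b, qualifying$gene_b)))
  genes$detectable <- paste(genes$genome_id, genes$gene_id) %in% det_keys

  # expected islands: detectable planted genes merged by the gap rule
  det <- genes[genes$detectable, , drop = FALSE]
  det <- det[order(det$genome_id, det$contig_id, det$start), , drop = FALSE]
  exp_isl <- list()
  if (nrow(det)) {
    grp <- paste(det$genome_id, det$contig_id)
    for (gname in unique(grp)) {
      block <- det[grp == gname, , drop = FALSE]
      run_end <- block$end[1L]; no <- 1L
      assign <- integer(nrow(block)); assign[1L] <- no
      for (i in seq_len(nrow(block))[-1L]) {
        if (block$start[i] - run_end > detect_params$island_max_gap) {
          no <- no + 1L; run_end <- block$end[i]
        } else run_end <- max(run_end, block$end[i])
        assign[i] <- no
      }
      for (k in seq_len(no)) {
        part <- block[assign == k, , drop = FALSE]
        eid <- sprintf("%s|exp%02d", part$genome_id[1L], k)
        exp_isl[[length(exp_isl) + 1L]] <- data.frame(
          expected_island_id = eid, genome_id = part$genome_id,
          gene_id = part$gene_id, element_id = part$element_id,
          stringsAsFactors = FALSE)
      }
    }
  }
  expected_islands <- if (length(exp_isl)) do.call(rbind, exp_isl) else
    data.frame(expected_island_id = character(0), genome_id = character(0),
               gene_id = character(0), element_id = character(0),
               stringsAsFactors = FALSE)

  # expected groups: union-find over expected islands joined by qualifying
  # copy pairs (skipping pairs excluded by the ANI filter, i.e. relatives
  # above the ANI ceiling); transposon links are included only in the
  # "merged" partition
  excluded_pair <- function(a, b) {
    for (r in seq_len(nrow(rels))) {
      if (setequal(c(a, b), c(rels$genome_i[r], rels$genome_j[r])) &&
          rels$expected_ani[r] > detect_params$max_ani) return(TRUE)
    }
    FALSE
  }
  isl_of <- setNames(expected_islands$expected_island_id,
                     paste(expected_islands$genome_id,
                           expected_islands$gene_id))
  components_from <- function(use_roles) {
    ids <- unique(expected_islands$expected_island_id)
    parent <- setNames(ids, ids)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    union2 <- function(a, b) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[[max(ra, rb)]] <<- min(ra, rb)
    }
    role_of <- setNames(genes$role, paste(genes$genome_id, genes$gene_id))
    for (r in seq_len(nrow(qualifying))) {
      ka <- paste(qualifying$genome_a[r], qualifying$gene_a[r])
      kb <- paste(qualifying$genome_b[r], qualifying$gene_b[r])
      if (!(ka %in% names(isl_of)) || !(kb %in% names(isl_of))) next
      if (!(role_of[[ka]] %in% use_roles)) next
      if (excluded_pair(qualifying$genome_a[r], qualifying$genome_b[r])) next
      union2(isl_of[[ka]], isl_of[[kb]])
    }
    comp <- vapply(ids, find, "")
    unname(split(ids, comp))
  }
  expected_groups <- components_from("island")
  expected_groups_merged <- components_from(c("island", "transposon"))

  structure(list(
    genes = genes[setdiff(names(genes), "sequence")],
    vertical_genes = vertical,
    pair_identity = pair_identity,
    expected_islands = expected_islands,
    expected_groups = expected_groups,
    expected_groups_merged = expected_groups_merged,
    relative_pairs = rels,
    config = config
  ), class = "truth_set")
}

#' Score pipeline output against a synthetic truth set
#'
#' Gene-level precision/recall over detectable planted genes, the fraction
#' of expected islands recovered with exactly matching gene sets, and
#' precision/recall of island co-membership pairs against the expected
#' group partition (`"merged"` by default: the partition proximity
#' clustering is expected to report, including documented transposon
#' chaining; `"pure"` scores against per-element groups instead).
#'
#' With no detected positives, precision is reported as 1 with
#' `precision_defined = FALSE` rather than NaN.
#'
#' @param detection An `hgt_detection` from [detect_hgt()].
#' @param truth A `truth_set` from [generate_community()].
#' @param partition `"merged"` or `"pure"`.
#' @return List of class `recovery_metrics`.
#' @export
evaluate_recovery <- function(detection, truth,
                              partition = c("merged", "pure")) {
  partition <- match.arg(partition)
  stopifnot(inherits(detection, "hgt_detection"),
            inherits(truth, "truth_set"))
  bad <- setdiff(detection$candidates$genome_id, truth$config$genome_ids)
  if (length(bad)) {
    stop("detection references genome(s) outside the community: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  detected <- paste(detection$candidates$genome_id,
                    detection$candidates$gene_id)
  truth_pos <- with(truth$genes[truth$genes$detectable, , drop = FALSE],
                    paste(genome_id, gene_id))
  tp <- length(intersect(detected, truth_pos))
  precision_defined <- length(detected) > 0L
  precision <- if (precision_defined) tp / length(detected) else 1
  recall <- if (length(truth_pos)) tp / length(truth_pos) else 1

  # island exact-match fraction
  exp_sets <- lapply(split(paste(truth$expected_islands$genome_id,
                                 truth$expected_islands$gene_id),
                           truth$expected_islands$expected_island_id), sort)
  det_sets <- lapply(split(paste(detection$members$genome_id,
                                 detection$members$gene_id),
                           detection$members$island_id), sort)
  matched <- vapply(exp_sets, function(s)
    any(vapply(det_sets, identical, TRUE, y = s)), TRUE)
  island_exact <- if (length(exp_sets)) mean(matched) else 1

  # group co-membership over genes (restricted to detectable truth genes)
  groups <- if (partition == "merged") truth$expected_groups_merged
            else truth$expected_groups
  isl_grp <- setNames(
    rep(seq_along(groups), lengths(groups)), unlist(groups))
  truth_group_of <- setNames(
    isl_grp[truth$expected_islands$expected_island_id],
    paste(truth$expected_islands$genome_id,
          truth$expected_islands$gene_id))
  det_rank_of <- local({
    m <- merge(detection$members, detection$island_groups, by = "island_id")
    setNames(m$group_rank, paste(m$genome_id, m$gene_id))
  })
  universe <- intersect(names(truth_group_of), names(det_rank_of))
  co_pairs <- function(assign) {
    if (length(universe) < 2L) return(character(0))
    cmb <- utils::combn(sort(universe), 2L)
    same <- assign[cmb[1L, ]] == assign[cmb[2L, ]]
    paste(cmb[1L, same], cmb[2L, same], sep = "\r")
  }
  truth_co <- co_pairs(truth_group_of)
  det_co <- co_pairs(det_rank_of)
  group_precision <- if (length(det_co)) {
    length(intersect(det_co, truth_co)) / length(det_co)
  } else 1
  group_recall <- if (length(truth_co)) {
    length(intersect(det_co, truth_co)) / length(truth_co)
  } else 1

  structure(list(
    gene_precision = precision, gene_recall = recall,
    precision_defined = precision_defined,
    n_detected = length(detected), n_truth_detectable = length(truth_pos),
    island_exact_match = island_exact,
    group_comembership_precision = group_precision,
    group_comembership_recall = group_recall,
    partition = partition
  ), class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("recovery vs %s truth: gene P=%.3f R=%.3f; island exact %.3f; ",
           "group co-membership P=%.3f R=%.3f\n"),
    x$partition, x$gene_precision, x$gene_recall, x$island_exact_match,
    x$group_comembership_precision, x$group_comembership_recall))
  invisible(x)
}

#' Write a community to disk as FASTA + GFF3 + metadata + truth JSON
#'
#' The on-disk layout is exactly what [read_genome()] and the pipeline
#' consume, so synthetic communities exercise the same input path as real
#' data.
#'
#' @param community List from [generate_community()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in community$genomes) {
    fa <- file.path(dir, paste0(g$genome_id, ".fna"))
    Biostrings::writeXStringSet(g$contigs, fa)
    gff <- file.path(dir, paste0(g$genome_id, ".gff3"))
    write_gff3(g, gff)
  }
  meta <- metadata_from_genomes(community$genomes)
  write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- community$truth
  jsonlite::write_json(
    list(genes = truth$genes, vertical_genes = truth$vertical_genes,
         expected_islands = truth$expected_islands,
         expected_groups = truth$expected_groups,
         expected_groups_merged = truth$expected_groups_merged,
         relative_pairs = truth$relative_pairs),
    file.path(dir, "truth.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

# minimal GFF3 writer for CDS features (1-based inclusive on output)
write_gff3 <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- genome$genes
  for (i in seq_len(nrow(g))) {
    attrs <- sprintf("ID=%s;product=%s", g$gene_id[i],
                     gsub("[;=\t]", " ", g$product[i]))
    writeLines(sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                       g$contig_id[i], "hgtscan", g$start[i] + 1L, g$end[i],
                       g$strand[i], attrs), con)
  }
  invisible(path)
}
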
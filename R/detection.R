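#' Detection parameters
#'
#' Thresholds for turning homology hits into HGT candidates, islands and
#' groups. A hit survives only between genomes that differ under
#' `species_key` and whose pairwise ANI is *not above* `max_ani` (an
#' undefined ANI passes: the filter exists to remove close relatives, and
#' unrelated genomes with too little alignable sequence must never be
#' excluded). Candidate genes within `island_max_gap` nucleotides of each
#' other on the same contig form one island.
#'
#' @param max_ani ANI ceiling in percent (default 89): pairs with two-way
#'   ANI strictly above this are treated as vertical relatives and their
#'   hits discarded.
#' @param island_max_gap Maximum inter-feature gap within an island, in
#'   nucleotides, inclusive (default 5000).
#' @param species_key Which label defines "same species" for the hit filter:
#'   `"species_label"` (default) or `"genome_id"`.
#' @param min_island_genes Minimum genes per reported island (default 1).
#' @param mobile_keywords Keywords (regex-escaped literals, matched
#'   case-insensitively against product annotations) that mark mobile
#'   elements.
#' @param promiscuous_min_genomes A gene hitting more than this many
#'   distinct partner genomes is flagged as promiscuous (default 10), a
#'   diagnostic for transposon-driven group merging.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(max_ani = 89.0, island_max_gap = 5000L,
                             species_key = c("species_label", "genome_id"),
                             min_island_genes = 1L,
                             mobile_keywords = c(
                               "transposase", "integrase", "conjugal",
                               "conjugation", "phage", "recombinase",
                               "mobile element", "insertion sequence"),
                             promiscuous_min_genomes = 10L) {
  species_key <- match.arg(species_key)
  stopifnot(max_ani > 0, max_ani <= 100, island_max_gap >= 0,
            min_island_genes >= 1)
  structure(list(
    max_ani = max_ani, island_max_gap = as.integer(island_max_gap),
    species_key = species_key,
    min_island_genes = as.integer(min_island_genes),
    mobile_keywords = mobile_keywords,
    promiscuous_min_genomes = as.integer(promiscuous_min_genomes)
  ), class = "detection_params")
}

#' Filter homology hits down to HGT candidates
#'
#' A hit is retained iff (a) the two genomes differ under `species_key`, and
#' (b) the genome pair's two-way ANI is not above `max_ani` (undefined ANI
#' passes). Candidate genes are all genes incident to at least one retained
#' hit.
#'
#' @param hits Hit data frame ([search_all_vs_all()] / [read_tabular_hits()]).
#' @param ani An `ani_table`.
#' @param meta Genome metadata data frame (genome_id, species_label, genus,
#'   phylum).
#' @param params A [detection_params()] object.
#' @return List with `edges` (retained hits) and `candidates` (data frame:
#'   genome_id, gene_id, n_supporting_hits).
#' @export
filter_hgt_hits <- function(hits, ani, meta, params = detection_params()) {
  unknown <- setdiff(unique(c(hits$query_genome, hits$subject_genome)),
                     meta$genome_id)
  if (length(unknown)) {
    stop("hit references unknown genome(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (nrow(hits) == 0L) {
    return(list(edges = hits,
                candidates = data.frame(genome_id = character(0),
                                        gene_id = character(0),
                                        n_supporting_hits = integer(0),
                                        stringsAsFactors = FALSE)))
  }
  key <- setNames(meta[[params$species_key]], meta$genome_id)
  diff_species <- key[hits$query_genome] != key[hits$subject_genome]

  pair_ani <- mapply(function(a, b) ani_lookup(ani, a, b),
                     hits$query_genome, hits$subject_genome)
  ani_pass <- is.na(pair_ani) | pair_ani <= params$max_ani

  edges <- hits[diff_species & ani_pass, , drop = FALSE]
  rownames(edges) <- NULL
  genes <- rbind(
    data.frame(genome_id = edges$query_genome, gene_id = edges$query_gene,
               stringsAsFactors = FALSE),
    data.frame(genome_id = edges$subject_genome, gene_id = edges$subject_gene,
               stringsAsFactors = FALSE))
  if (nrow(genes)) {
    tab <- stats::aggregate(list(n_supporting_hits = rep(1L, nrow(genes))),
                            by = genes[c("genome_id", "gene_id")], FUN = sum)
    tab <- tab[order(tab$genome_id, tab$gene_id), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(genome_id = character(0), gene_id = character(0),
                      n_supporting_hits = integer(0), stringsAsFactors = FALSE)
  }
  list(edges = edges, candidates = tab)
}

#' Assemble candidate genes into islands
#'
#' Per genome and contig, candidate genes are sorted by start coordinate and
#' consecutive candidates whose inter-feature gap (next start minus the
#' running maximum end) is at most `island_max_gap` are merged into one
#' island. The boundary is inclusive: a gap of exactly `island_max_gap`
#' still merges. Non-candidate genes lying inside a gap neither join nor
#' break an island; genes on different contigs are never merged.
#'
#' @param candidates Candidate data frame from [filter_hgt_hits()].
#' @param genomes List of `genome_record` supplying coordinates.
#' @param params A [detection_params()] object.
#' @return List with `islands` (data frame: island_id, genome_id, contig_id,
#'   span_start, span_end, n_genes, nt_content) and `members` (data frame:
#'   island_id, genome_id, gene_id, start, end).
#' @export
assemble_islands <- function(candidates, genomes,
                             params = detection_params()) {
  gtabs <- do.call(rbind, lapply(genomes, genes_table))
  key <- paste(gtabs$genome_id, gtabs$gene_id)
  idx <- match(paste(candidates$genome_id, candidates$gene_id), key)
  if (anyNA(idx)) {
    stop("candidate gene(s) not resolvable to coordinates: ",
         paste(head(paste(candidates$genome_id, candidates$gene_id)[is.na(idx)]),
               collapse = ", "), call. = FALSE)
  }
  cand <- cbind(candidates,
                gtabs[idx, c("contig_id", "start", "end"), drop = FALSE])
  cand <- cand[order(cand$genome_id, cand$contig_id, cand$start, cand$end), ,
               drop = FALSE]
  islands <- list(); members <- list()
  if (nrow(cand)) {
    grp <- paste(cand$genome_id, cand$contig_id, sep = "\r")
    for (g in unique(grp)) {
      block <- cand[grp == g, , drop = FALSE]
      run_end <- block$end[1L]
      island_no <- 1L
      assign <- integer(nrow(block))
      assign[1L] <- island_no
      for (i in seq_len(nrow(block))[-1L]) {
        gap <- block$start[i] - run_end
        if (gap > params$island_max_gap) {
          island_no <- island_no + 1L
          run_end <- block$end[i]
        } else {
          run_end <- max(run_end, block$end[i])
        }
        assign[i] <- island_no
      }
      for (k in seq_len(island_no)) {
        part <- block[assign == k, , drop = FALSE]
        if (nrow(part) < params$min_island_genes) next
        iid <- sprintf("%s|%s|i%03d", part$genome_id[1L], part$contig_id[1L],
                       k)
        islands[[length(islands) + 1L]] <- data.frame(
          island_id = iid, genome_id = part$genome_id[1L],
          contig_id = part$contig_id[1L],
          span_start = min(part$start), span_end = max(part$end),
          n_genes = nrow(part),
          nt_content = sum(part$end - part$start),
          stringsAsFactors = FALSE)
        members[[length(members) + 1L]] <- data.frame(
          island_id = iid, genome_id = part$genome_id,
          gene_id = part$gene_id, start = part$start, end = part$end,
          stringsAsFactors = FALSE)
      }
    }
  }
  empty_isl <- data.frame(island_id = character(0), genome_id = character(0),
                          contig_id = character(0), span_start = integer(0),
                          span_end = integer(0), n_genes = integer(0),
                          nt_content = integer(0), stringsAsFactors = FALSE)
  empty_mem <- data.frame(island_id = character(0), genome_id = character(0),
                          gene_id = character(0), start = integer(0),
                          end = integer(0), stringsAsFactors = FALSE)
  list(islands = if (length(islands)) do.call(rbind, islands) else empty_isl,
       members = if (length(members)) do.call(rbind, members) else empty_mem)
}

#' Cluster islands into cross-genome groups
#'
#' Builds the graph whose vertices are islands and whose edges connect
#' islands containing genes joined by a retained hit, and returns its
#' connected components: islands that share at least one gene (directly or
#' transitively through other islands) end up in the same group.
#'
#' @param islands Output of [assemble_islands()].
#' @param edges Retained hits from [filter_hgt_hits()].
#' @return Data frame mapping island_id to group_id (arbitrary but
#'   deterministic component labels; see [rank_groups()] for final ranks).
#' @export
cluster_groups <- function(islands, edges) {
  isl <- islands$islands
  mem <- islands$members
  if (nrow(isl) == 0L) {
    return(data.frame(island_id = character(0), group_id = integer(0),
                      stringsAsFactors = FALSE))
  }
  gene_key <- paste(mem$genome_id, mem$gene_id)
  island_of <- setNames(mem$island_id, gene_key)
  if (nrow(edges)) {
    qa <- island_of[paste(edges$query_genome, edges$query_gene)]
    sb <- island_of[paste(edges$subject_genome, edges$subject_gene)]
    if (anyNA(qa) || anyNA(sb)) {
      stop("retained hit endpoint not assigned to any island", call. = FALSE)
    }
    el <- cbind(qa, sb)
    el <- el[qa != sb, , drop = FALSE]
  } else {
    el <- matrix(character(0), ncol = 2)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1L], to = el[, 2L], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = isl$island_id, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership
  out <- data.frame(island_id = isl$island_id,
                    group_id = as.integer(comp[isl$island_id]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Rank groups and compute group statistics
#'
#' Groups are ranked by descending total gene count, ties broken by
#' descending total nucleotide content, then by the lexicographically
#' smallest member genome id, so the numbering is fully deterministic.
#' Statistics per group: number of member species, islands, genes, summed
#' CDS nucleotides, mean genes per species, whether all members share one
#' phylum / one genus (NA when labels are missing, not FALSE), and whether
#' any member gene's product matches the mobile-element keyword list.
#'
#' @param membership Island-to-group map from [cluster_groups()].
#' @param islands Output of [assemble_islands()].
#' @param genomes List of `genome_record` (for product annotations).
#' @param meta Metadata data frame.
#' @param params A [detection_params()] object.
#' @return List with `groups` (one row per group, ranked) and
#'   `island_groups` (island_id, group_rank).
#' @export
rank_groups <- function(membership, islands, genomes, meta,
                        params = detection_params()) {
  isl <- merge(islands$islands, membership, by = "island_id")
  mem <- merge(islands$members, membership, by = "island_id")
  if (nrow(isl) == 0L) {
    groups <- data.frame(group_rank = integer(0), n_islands = integer(0),
                         n_species = integer(0), total_genes = integer(0),
                         total_nt = integer(0),
                         mean_genes_per_species = numeric(0),
                         same_phylum = logical(0), single_genus = logical(0),
                         contains_mobile = logical(0),
                         stringsAsFactors = FALSE)
    return(list(groups = groups,
                island_groups = data.frame(island_id = character(0),
                                           group_rank = integer(0),
                                           stringsAsFactors = FALSE)))
  }
  gtabs <- do.call(rbind, lapply(genomes, genes_table))
  prod_of <- setNames(gtabs$product, paste(gtabs$genome_id, gtabs$gene_id))
  species_of <- setNames(meta$species_label, meta$genome_id)
  genus_of <- setNames(meta$genus, meta$genome_id)
  phylum_of <- setNames(meta$phylum, meta$genome_id)
  kw <- paste(params$mobile_keywords, collapse = "|")

  stats_rows <- lapply(split(seq_len(nrow(isl)), isl$group_id), function(ii) {
    part <- isl[ii, , drop = FALSE]
    gmem <- mem[mem$group_id == part$group_id[1L], , drop = FALSE]
    sp <- unique(species_of[part$genome_id])
    total_genes <- sum(part$n_genes)
    lab_all <- function(v) {
      vals <- unique(v)
      if (any(is.na(vals)) || any(!nzchar(vals))) NA
      else length(vals) == 1L
    }
    prods <- prod_of[paste(gmem$genome_id, gmem$gene_id)]
    data.frame(
      group_id = part$group_id[1L],
      n_islands = nrow(part),
      n_species = length(sp),
      total_genes = total_genes,
      total_nt = sum(part$nt_content),
      mean_genes_per_species = total_genes / length(sp),
      same_phylum = lab_all(phylum_of[part$genome_id]),
      single_genus = lab_all(genus_of[part$genome_id]),
      contains_mobile = any(grepl(kw, prods, ignore.case = TRUE)),
      min_genome = min(part$genome_id),
      stringsAsFactors = FALSE)
  })
  groups <- do.call(rbind, stats_rows)
  o <- order(-groups$total_genes, -groups$total_nt, groups$min_genome)
  groups <- groups[o, , drop = FALSE]
  groups$group_rank <- seq_len(nrow(groups))
  island_groups <- merge(
    data.frame(group_id = groups$group_id, group_rank = groups$group_rank),
    isl[c("island_id", "group_id")], by = "group_id")[c("island_id",
                                                        "group_rank")]
  island_groups <- island_groups[order(island_groups$group_rank,
                                       island_groups$island_id), ,
                                 drop = FALSE]
  rownames(island_groups) <- NULL
  groups <- groups[c("group_rank", "n_islands", "n_species", "total_genes",
                     "total_nt", "mean_genes_per_species", "same_phylum",
                     "single_genus", "contains_mobile")]
  rownames(groups) <- NULL
  list(groups = groups, island_groups = island_groups)
}

#' Shared-CDS counts between species pairs
#'
#' For each unordered species pair, the number of distinct gene pairs
#' connected by a retained hit (direction-invariant); pairs with zero shared
#' CDS are omitted.
#'
#' @param edges Retained hits from [filter_hgt_hits()].
#' @param meta Metadata data frame.
#' @return Data frame: species_a, species_b, shared_cds_count.
#' @export
species_connections <- function(edges, meta) {
  empty <- data.frame(species_a = character(0), species_b = character(0),
                      shared_cds_count = integer(0), stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) return(empty)
  species_of <- setNames(meta$species_label, meta$genome_id)
  ga <- paste(edges$query_genome, edges$query_gene)
  gb <- paste(edges$subject_genome, edges$subject_gene)
  gene_pair <- paste(pmin(ga, gb), pmax(ga, gb), sep = "\r")
  sa <- species_of[edges$query_genome]
  sb <- species_of[edges$subject_genome]
  sp_pair <- paste(pmin(sa, sb), pmax(sa, sb), sep = "\r")
  dedup <- !duplicated(gene_pair)
  tab <- table(sp_pair[dedup])
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(species_a = vapply(parts, `[[`, "", 1L),
                    species_b = vapply(parts, `[[`, "", 2L),
                    shared_cds_count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$species_a, out$species_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag promiscuous genes
#'
#' A gene whose retained hits reach more than `promiscuous_min_genomes`
#' distinct partner genomes is flagged as a potential group-merging mobile
#' element (a transposon inserted next to unrelated islands in many genomes
#' will chain their groups together). Groups are *not* split automatically;
#' this is a reported diagnostic.
#'
#' @param edges Retained hits from [filter_hgt_hits()].
#' @param params A [detection_params()] object.
#' @return Data frame: genome_id, gene_id, n_partner_genomes, for flagged
#'   genes only.
#' @export
flag_promiscuous_genes <- function(edges, params = detection_params()) {
  empty <- data.frame(genome_id = character(0), gene_id = character(0),
                      n_partner_genomes = integer(0), stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) return(empty)
  d <- rbind(
    data.frame(genome_id = edges$query_genome, gene_id = edges$query_gene,
               partner = edges$subject_genome, stringsAsFactors = FALSE),
    data.frame(genome_id = edges$subject_genome, gene_id = edges$subject_gene,
               partner = edges$query_genome, stringsAsFactors = FALSE))
  d <- d[!duplicated(d), , drop = FALSE]
  agg <- stats::aggregate(list(n_partner_genomes = d$partner),
                          by = d[c("genome_id", "gene_id")],
                          FUN = function(x) length(unique(x)))
  flagged <- agg[agg$n_partner_genomes > params$promiscuous_min_genomes, ,
                 drop = FALSE]
  flagged <- flagged[order(flagged$genome_id, flagged$gene_id), , drop = FALSE]
  rownames(flagged) <- NULL
  flagged
}

#' Run the full detection stage
#'
#' Convenience wrapper: filter hits, assemble islands, cluster and rank
#' groups, tabulate species connections and promiscuous genes.
#'
#' @param hits Hit data frame.
#' @param ani An `ani_table`.
#' @param genomes List of `genome_record`.
#' @param meta Metadata data frame (defaults to labels carried by the
#'   records themselves).
#' @param params A [detection_params()] object.
#' @return List of class `hgt_detection`: edges, candidates, islands,
#'   members, island_groups, groups, connections, promiscuous, params.
#' @export
detect_hgt <- function(hits, ani, genomes, meta = NULL,
                       params = detection_params()) {
  if (is.null(meta)) meta <- metadata_from_genomes(genomes)
  flt <- filter_hgt_hits(hits, ani, meta, params)
  isl <- assemble_islands(flt$candidates, genomes, params)
  membership <- cluster_groups(isl, flt$edges)
  ranked <- rank_groups(membership, isl, genomes, meta, params)
  structure(list(
    edges = flt$edges,
    candidates = flt$candidates,
    islands = isl$islands,
    members = isl$members,
    island_groups = ranked$island_groups,
    groups = ranked$groups,
    connections = species_connections(flt$edges, meta),
    promiscuous = flag_promiscuous_genes(flt$edges, params),
    params = params
  ), class = "hgt_detection")
}

#' @export
print.hgt_detection <- function(x, ...) {
  cat(sprintf(
    "hgt_detection: %d retained hits, %d candidate genes, %d islands, %d groups\n",
    nrow(x$edges), nrow(x$candidates), nrow(x$islands), nrow(x$groups)))
  invisible(x)
}
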
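# hand-built hit tables / ANI tables keep the filter logic fully observable

mk_hit <- function(qg, qgene, sg, sgene, pid = 99.5, len = 800L) {
  data.frame(query_genome = qg, query_gene = qgene, subject_genome = sg,
             subject_gene = sgene, pct_identity = pid,
             aln_length = as.integer(len), q_start = 0L, q_end = len,
             s_start = 0L, s_end = len, strand = "+", score = len,
             stringsAsFactors = FALSE)
}

mk_ani_row <- function(a, b, ani, defined = TRUE) {
  data.frame(genome_a = a, genome_b = b,
             ani_ab = if (defined) ani else NA_real_,
             ani_ba = if (defined) ani else NA_real_,
             ani_two_way = if (defined) ani else NA_real_,
             n_frag_ab = 10L, n_frag_ba = 10L, defined = defined,
             stringsAsFactors = FALSE)
}

mk_meta <- function(ids, species = NULL, genus = "", phylum = "") {
  data.frame(genome_id = ids,
             species_label = if (is.null(species)) paste0("sp_", ids)
                             else species,
             genus = genus, phylum = phylum, stringsAsFactors = FALSE)
}

test_that("hit filter removes same-species pairs and high-ANI pairs, keeps the rest", {
  ids <- c("gA", "gB", "gC", "gD", "gE")
  meta <- mk_meta(ids)
  meta$species_label[meta$genome_id == "gE"] <- "sp_gA"  # same species as gA
  ani <- rbind(mk_ani_row("gA", "gB", 85.0),
               mk_ani_row("gA", "gC", 88.0),
               mk_ani_row("gA", "gD", 89.5),
               mk_ani_row("gA", "gE", NA, defined = FALSE),
               mk_ani_row("gB", "gC", NA, defined = FALSE),
               mk_ani_row("gB", "gD", NA, defined = FALSE),
               mk_ani_row("gB", "gE", NA, defined = FALSE),
               mk_ani_row("gC", "gD", NA, defined = FALSE),
               mk_ani_row("gC", "gE", NA, defined = FALSE),
               mk_ani_row("gD", "gE", NA, defined = FALSE))
  hits <- rbind(
    mk_hit("gA", "a1", "gB", "b1", 99.2, 600),  # ANI 85 -> retained
    mk_hit("gA", "a2", "gC", "c1"),             # ANI 88 -> retained
    mk_hit("gA", "a3", "gD", "d1"),             # ANI 89.5 -> excluded
    mk_hit("gA", "a4", "gE", "e1"),             # same species -> excluded
    mk_hit("gB", "b2", "gC", "c2"))             # undefined ANI -> retained
  flt <- filter_hgt_hits(hits, ani, meta)
  expect_equal(nrow(flt$edges), 3L)
  expect_setequal(flt$edges$query_gene, c("a1", "a2", "b2"))
  expect_setequal(paste(flt$candidates$genome_id, flt$candidates$gene_id),
                  c("gA a1", "gA a2", "gB b1", "gB b2", "gC c1", "gC c2"))
  # unknown genome in hits is a validation error
  expect_error(
    filter_hgt_hits(mk_hit("gZ", "z", "gA", "a1"), ani, meta),
    "unknown genome")
})

test_that("ANI exactly at the ceiling passes; only strictly-above is excluded", {
  meta <- mk_meta(c("gA", "gB"))
  hits <- mk_hit("gA", "a1", "gB", "b1")
  at_cutoff <- filter_hgt_hits(hits, mk_ani_row("gA", "gB", 89.0), meta)
  expect_equal(nrow(at_cutoff$edges), 1L)
  above <- filter_hgt_hits(hits, mk_ani_row("gA", "gB", 89.0001), meta)
  expect_equal(nrow(above$edges), 0L)
})

test_that("islands merge by inter-feature gap with an inclusive 5 kb boundary", {
  set.seed(30)
  genome <- make_record(
    "gA", c(c1 = random_sequence(20000, 0.5), c2 = random_sequence(6000, 0.5)),
    rbind(gene_row("x1", "c1", 0, 1000),
          gene_row("x2", "c1", 3000, 4000),
          gene_row("x3", "c1", 10000, 11000),
          gene_row("y1", "c2", 0, 800)))
  cand <- data.frame(genome_id = "gA", gene_id = c("x1", "x2", "x3", "y1"),
                     n_supporting_hits = 1L, stringsAsFactors = FALSE)
  isl <- assemble_islands(cand, list(genome))
  # gaps: x1-x2 = 2000 (merge), x2-x3 = 6000 (split); y1 on another contig
  expect_equal(nrow(isl$islands), 3L)
  sets <- lapply(split(isl$members$gene_id, isl$members$island_id), sort)
  expect_true(any(vapply(sets, identical, TRUE, y = c("x1", "x2"))))
  expect_true(any(vapply(sets, identical, TRUE, y = "x3")))
  expect_true(any(vapply(sets, identical, TRUE, y = "y1")))
  one <- isl$islands[isl$islands$n_genes == 2L, ]
  expect_equal(one$span_start, 0L)
  expect_equal(one$span_end, 4000L)
  expect_equal(one$nt_content, 2000L)

  # boundary: gap of exactly 5000 merges, 5001 splits
  g2 <- make_record("gB", c(c1 = random_sequence(16000, 0.5)),
                    rbind(gene_row("z1", "c1", 0, 1000),
                          gene_row("z2", "c1", 6000, 7000),
                          gene_row("z3", "c1", 12001, 13000)))
  cand2 <- data.frame(genome_id = "gB", gene_id = c("z1", "z2", "z3"),
                      n_supporting_hits = 1L, stringsAsFactors = FALSE)
  isl2 <- assemble_islands(cand2, list(g2))
  expect_equal(nrow(isl2$islands), 2L)      # z1+z2 (gap 5000), z3 (gap 5001)
  expect_equal(sort(isl2$islands$n_genes), c(1L, 2L))
})

test_that("non-candidate genes inside a gap neither join nor break an island", {
  set.seed(31)
  genome <- make_record("gA", c(c1 = random_sequence(10000, 0.5)),
                        rbind(gene_row("x1", "c1", 0, 1000),
                              gene_row("mid", "c1", 2000, 2500),
                              gene_row("x2", "c1", 4000, 5000)))
  cand <- data.frame(genome_id = "gA", gene_id = c("x1", "x2"),
                     n_supporting_hits = 1L, stringsAsFactors = FALSE)
  isl <- assemble_islands(cand, list(genome))
  expect_equal(nrow(isl$islands), 1L)
  expect_setequal(isl$members$gene_id, c("x1", "x2"))
})

test_that("island clustering is transitive and matches brute-force closure", {
  set.seed(32)
  # fixed cases: shared gene -> one group; chaining A-B-C; singletons
  genomes <- list(
    make_record("gA", c(c1 = random_sequence(9000, 0.5)),
                rbind(gene_row("a1", "c1", 0, 800),
                      gene_row("a2", "c1", 1500, 2300))),
    make_record("gB", c(c1 = random_sequence(9000, 0.5)),
                rbind(gene_row("b1", "c1", 0, 800),
                      gene_row("b2", "c1", 7000, 7800))),
    make_record("gC", c(c1 = random_sequence(9000, 0.5)),
                gene_row("c1", "c1", 0, 800)))
  cand <- data.frame(
    genome_id = c("gA", "gA", "gB", "gB", "gC"),
    gene_id = c("a1", "a2", "b1", "b2", "c1"),
    n_supporting_hits = 1L, stringsAsFactors = FALSE)
  isl <- assemble_islands(cand, genomes)
  expect_equal(nrow(isl$islands), 4L)  # {a1,a2}, {b1}, {b2}, {c1}
  # chain: a2-b1 and b2-c1 share genes; b1,b2 are different islands of gB,
  # so the chain only links pairs, yielding two groups
  edges <- rbind(mk_hit("gA", "a2", "gB", "b1"),
                 mk_hit("gB", "b2", "gC", "c1"))
  membership <- cluster_groups(isl, edges)
  grp <- setNames(membership$group_id, membership$island_id)
  isl_of <- setNames(isl$members$island_id,
                     paste(isl$members$genome_id, isl$members$gene_id))
  expect_equal(grp[[isl_of[["gA a2"]]]], grp[[isl_of[["gB b1"]]]])
  expect_equal(grp[[isl_of[["gB b2"]]]], grp[[isl_of[["gC c1"]]]])
  # the two chains are not connected to each other
  expect_false(grp[[isl_of[["gA a2"]]]] == grp[[isl_of[["gB b2"]]]])

  # brute-force transitive closure agreement on the same instance
  sets <- split(paste(isl$members$genome_id, isl$members$gene_id),
                isl$members$island_id)
  ep <- cbind(paste(edges$query_genome, edges$query_gene),
              paste(edges$subject_genome, edges$subject_gene))
  bf <- brute_force_groups(sets, ep)
  ours <- grp[names(sets)]
  expect_equal(length(unique(bf)), length(unique(ours)))
  expect_equal(as.vector(table(bf)[order(table(bf))]),
               as.vector(table(ours)[order(table(ours))]))
})

test_that("clustering matches brute-force closure on random island graphs", {
  set.seed(33)
  for (rep in 1:10) {
    n_isl <- sample(4:12, 1L)
    # islands: one gene each across distinct genomes
    genomes <- lapply(seq_len(n_isl), function(i)
      make_record(sprintf("g%02d", i), c(c1 = random_sequence(2000, 0.5)),
                  gene_row("x", "c1", 0, 800)))
    cand <- data.frame(genome_id = sprintf("g%02d", seq_len(n_isl)),
                       gene_id = "x", n_supporting_hits = 1L,
                       stringsAsFactors = FALSE)
    isl <- assemble_islands(cand, genomes)
    n_edges <- sample(0:(n_isl), 1L)
    edges <- do.call(rbind, lapply(seq_len(n_edges), function(e) {
      ij <- sample(n_isl, 2L)
      mk_hit(sprintf("g%02d", ij[1L]), "x", sprintf("g%02d", ij[2L]), "x")
    }))
    if (is.null(edges)) edges <- mk_hit("g01", "x", "g01", "x")[0, ]
    membership <- cluster_groups(isl, edges)
    sets <- split(paste(isl$members$genome_id, isl$members$gene_id),
                  isl$members$island_id)
    ep <- if (nrow(edges)) cbind(paste(edges$query_genome, edges$query_gene),
                                 paste(edges$subject_genome,
                                       edges$subject_gene))
          else matrix(character(0), ncol = 2)
    bf <- brute_force_groups(sets, ep)
    ours <- setNames(membership$group_id,
                     membership$island_id)[names(sets)]
    # identical partitions up to relabelling
    expect_equal(tapply(seq_along(bf), bf, function(i) sort(names(sets)[i]),
                        simplify = FALSE)[order(vapply(
                          tapply(seq_along(bf), bf, function(i)
                            sort(names(sets)[i]), simplify = FALSE),
                          `[[`, "", 1L))],
                 tapply(seq_along(ours), ours, function(i)
                   sort(names(sets)[i]), simplify = FALSE)[order(vapply(
                     tapply(seq_along(ours), ours, function(i)
                       sort(names(sets)[i]), simplify = FALSE),
                     `[[`, "", 1L))],
                 ignore_attr = TRUE)
  }
})

test_that("group ranking is deterministic with the documented tie rules", {
  set.seed(34)
  # two groups with equal gene counts; nt content breaks the tie
  genomes <- list(
    make_record("gA", c(c1 = random_sequence(12000, 0.5)),
                rbind(gene_row("a1", "c1", 0, 4000),
                      gene_row("a2", "c1", 4500, 8500))),   # 8000 nt
    make_record("gB", c(c1 = random_sequence(12000, 0.5)),
                rbind(gene_row("b1", "c1", 0, 3000),
                      gene_row("b2", "c1", 3500, 6500))),   # 6000 nt
    make_record("gC", c(c1 = random_sequence(12000, 0.5)),
                gene_row("c1", "c1", 0, 4000)),
    make_record("gD", c(c1 = random_sequence(12000, 0.5)),
                gene_row("d1", "c1", 0, 3000)))
  meta <- mk_meta(c("gA", "gB", "gC", "gD"),
                  phylum = c("P1", "P1", "P2", "P1"))
  cand <- data.frame(genome_id = c("gA", "gA", "gB", "gB", "gC", "gD"),
                     gene_id = c("a1", "a2", "b1", "b2", "c1", "d1"),
                     n_supporting_hits = 1L, stringsAsFactors = FALSE)
  isl <- assemble_islands(cand, genomes)
  edges <- rbind(mk_hit("gA", "a1", "gC", "c1", len = 4000),
                 mk_hit("gA", "a2", "gC", "c1", len = 4000),
                 mk_hit("gB", "b1", "gD", "d1", len = 3000),
                 mk_hit("gB", "b2", "gD", "d1", len = 3000))
  membership <- cluster_groups(isl, edges)
  ranked <- rank_groups(membership, isl, genomes, meta)
  expect_equal(nrow(ranked$groups), 2L)
  expect_equal(ranked$groups$total_genes, c(3L, 3L))
  expect_equal(ranked$groups$total_nt, c(12000L, 9000L))  # nt breaks tie
  expect_equal(ranked$groups$mean_genes_per_species, c(1.5, 1.5))
  expect_equal(ranked$groups$same_phylum, c(FALSE, TRUE))
})

test_that("missing taxon labels give unknown (NA), not FALSE", {
  set.seed(35)
  genomes <- list(
    make_record("gA", c(c1 = random_sequence(3000, 0.5)),
                gene_row("a1", "c1", 0, 800)),
    make_record("gB", c(c1 = random_sequence(3000, 0.5)),
                gene_row("b1", "c1", 0, 800)))
  meta <- mk_meta(c("gA", "gB"))   # empty genus/phylum
  cand <- data.frame(genome_id = c("gA", "gB"), gene_id = c("a1", "b1"),
                     n_supporting_hits = 1L, stringsAsFactors = FALSE)
  isl <- assemble_islands(cand, genomes)
  membership <- cluster_groups(isl, mk_hit("gA", "a1", "gB", "b1"))
  ranked <- rank_groups(membership, isl, genomes, meta)
  expect_true(is.na(ranked$groups$same_phylum))
  expect_true(is.na(ranked$groups$single_genus))
})

test_that("species connections count distinct gene pairs symmetrically", {
  meta <- mk_meta(c("gA", "gB"))
  edges <- rbind(mk_hit("gA", "a1", "gB", "b1"),
                 mk_hit("gB", "b1", "gA", "a1"),   # mirror, same gene pair
                 mk_hit("gA", "a2", "gB", "b2"))
  tab <- species_connections(edges, meta)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$shared_cds_count, 2L)
  expect_equal(nrow(species_connections(edges[0, ], meta)), 0L)
})

test_that("mobile-element products set the group flag and promiscuity is thresholded", {
  set.seed(36)
  genomes <- list(
    make_record("gA", c(c1 = random_sequence(3000, 0.5)),
                gene_row("a1", "c1", 0, 1200,
                         product = "IS3 family transposase")),
    make_record("gB", c(c1 = random_sequence(3000, 0.5)),
                gene_row("b1", "c1", 0, 1200, product = "permease")))
  meta <- mk_meta(c("gA", "gB"))
  cand <- data.frame(genome_id = c("gA", "gB"), gene_id = c("a1", "b1"),
                     n_supporting_hits = 1L, stringsAsFactors = FALSE)
  isl <- assemble_islands(cand, genomes)
  edges <- mk_hit("gA", "a1", "gB", "b1")
  ranked <- rank_groups(cluster_groups(isl, edges), isl, genomes, meta)
  expect_true(ranked$groups$contains_mobile)
  # promiscuity: a1 partners with 1 genome; threshold 0 flags it, default 10
  # does not
  expect_equal(nrow(flag_promiscuous_genes(edges)), 0L)
  flagged <- flag_promiscuous_genes(edges,
                                    detection_params(promiscuous_min_genomes = 0L))
  expect_true("a1" %in% flagged$gene_id)
})

test_that("candidate genes partition exactly into islands and groups", {
  comm <- generate_community(
    community_config(n_genomes = 4, genome_length = 40000,
                     genes_per_genome = 8, core_length = 8000, seed = 40,
                     planted_islands = list(
                       island_spec("isl1", donor = "g1",
                                   recipients = c("g2", "g3"),
                                   n_genes = 3L))))
  ani <- build_ani_matrix(comm$genomes)
  hits <- search_all_vs_all(comm$genomes)
  det <- detect_hgt(hits, ani, comm$genomes)
  expect_equal(sum(det$islands$n_genes), nrow(det$candidates))
  expect_equal(sum(det$groups$total_genes), nrow(det$candidates))
  expect_equal(nrow(det$members), nrow(det$candidates))
  # every island is in exactly one group
  expect_setequal(det$island_groups$island_id, det$islands$island_id)
  expect_false(anyDuplicated(det$island_groups$island_id) > 0L)
})

test_that("shrinking the island gap never decreases the island count", {
  comm <- generate_community(
    community_config(n_genomes = 3, genome_length = 40000,
                     genes_per_genome = 8, core_length = 8000, seed = 41,
                     planted_islands = list(
                       island_spec("isl1", donor = "g1",
                                   recipients = c("g2", "g3"),
                                   n_genes = 4L))))
  ani <- build_ani_matrix(comm$genomes)
  hits <- search_all_vs_all(comm$genomes)
  meta <- hgtscan:::metadata_from_genomes(comm$genomes)
  flt <- filter_hgt_hits(hits, ani, meta)
  n_prev <- -1L
  for (gap in c(5000L, 2000L, 800L, 100L, 0L)) {
    isl <- assemble_islands(flt$candidates, comm$genomes,
                            detection_params(island_max_gap = gap))
    expect_gte(nrow(isl$islands), n_prev)
    n_prev <- nrow(isl$islands)
  }
})

test_that("raising the ANI ceiling never grows the candidate set", {
  meta <- mk_meta(c("gA", "gB", "gC"))
  ani <- rbind(mk_ani_row("gA", "gB", 85), mk_ani_row("gA", "gC", 92),
               mk_ani_row("gB", "gC", 96))
  hits <- rbind(mk_hit("gA", "a1", "gB", "b1"),
                mk_hit("gA", "a2", "gC", "c1"),
                mk_hit("gB", "b2", "gC", "c2"))
  sizes <- vapply(c(100, 95, 89, 80), function(ceiling) {
    nrow(filter_hgt_hits(hits, ani, meta,
                         detection_params(max_ani = ceiling))$candidates)
  }, 0L)
  expect_true(all(diff(sizes) <= 0L))
})
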
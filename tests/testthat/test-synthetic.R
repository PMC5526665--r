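test_that("mutation is seeded, rate-0 is the identity, and Hamming recounts events", {
  set.seed(70)
  s <- random_sequence(10000, 0.5)
  expect_identical(as.character(mutate_sequence(s, 0)), s)
  m1 <- mutate_sequence(s, 0.01, seed = 123)
  m2 <- mutate_sequence(s, 0.01, seed = 123)
  expect_identical(as.character(m1), as.character(m2))
  expect_identical(attr(m1, "n_substitutions"), attr(m2, "n_substitutions"))
  # Hamming distance equals the realized substitution count
  d <- sum(charToRaw(s) != charToRaw(as.character(m1)))
  expect_equal(d, attr(m1, "n_substitutions"))
  # indels change length when enabled, never otherwise
  expect_equal(nchar(as.character(mutate_sequence(s, 0.05, seed = 1))),
               nchar(s))
  mi <- mutate_sequence(s, 0.05, seed = 1, allow_indels = TRUE)
  expect_true(attr(mi, "n_insertions") + attr(mi, "n_deletions") > 0)
})

test_that("identical configs generate byte-identical communities and truth", {
  cfg <- community_config(n_genomes = 3, genome_length = 40000,
                          genes_per_genome = 8, core_length = 8000,
                          seed = 71,
                          planted_islands = list(
                            island_spec("isl1", donor = "g1",
                                        recipients = "g2", n_genes = 3L)))
  a <- generate_community(cfg)
  b <- generate_community(cfg)
  for (g in names(a$genomes)) {
    expect_identical(as.character(a$genomes[[g]]$contigs),
                     as.character(b$genomes[[g]]$contigs))
    expect_identical(a$genomes[[g]]$genes, b$genomes[[g]]$genes)
  }
  expect_identical(a$truth$genes, b$truth$genes)
  expect_identical(a$truth$expected_groups, b$truth$expected_groups)
})

test_that("construction registers planted genes, islands and groups in the truth", {
  cfg <- community_config(
    n_genomes = 6, genome_length = 60000, genes_per_genome = 10,
    core_length = 10000, seed = 72,
    relative_pairs = list(relative_pair("g5", "g6", 0.05)),
    planted_islands = list(
      island_spec("isl1", donor = "g1", recipients = c("g2", "g3"),
                  n_genes = 5L, gene_lengths = rep(700L, 5), divergence = 0)))
  comm <- generate_community(cfg)
  truth <- comm$truth
  isl_genes <- truth$genes[truth$genes$role == "island", ]
  expect_equal(nrow(isl_genes), 15L)            # 5 genes x 3 carriers
  expect_true(all(isl_genes$detectable))        # divergence 0
  expect_equal(length(unique(truth$expected_islands$expected_island_id)), 3L)
  expect_equal(length(truth$expected_groups), 1L)
  expect_equal(truth$relative_pairs$expected_ani, 95)
  # conserved vertical genes recorded for both members of the pair
  expect_equal(sort(unique(truth$vertical_genes$genome_id)), c("g5", "g6"))
  # the genomes really carry the genes the truth claims
  for (i in seq_len(nrow(isl_genes))) {
    g <- comm$genomes[[isl_genes$genome_id[i]]]
    expect_true(isl_genes$gene_id[i] %in% g$genes$gene_id)
  }
})

test_that("island copies beyond the identity threshold are marked undetectable", {
  cfg <- community_config(
    n_genomes = 2, genome_length = 40000, genes_per_genome = 8,
    core_length = 8000, seed = 73,
    planted_islands = list(
      island_spec("far", donor = "g1", recipients = "g2", n_genes = 3L,
                  gene_lengths = rep(1000L, 3), divergence = 0.03)))
  truth <- generate_community(cfg)$truth
  # at 97% realized identity nothing reaches the 99% detection threshold
  expect_true(all(!truth$genes$detectable))
  expect_true(all(truth$pair_identity$identity < 99))
})

test_that("infeasible configurations fail loudly", {
  expect_error(community_config(n_genomes = 2, seed = 1,
                                planted_islands = list(
                                  island_spec("x", donor = "g9",
                                              recipients = "g1"))))
  cfg <- community_config(n_genomes = 2, genome_length = 10000,
                          genes_per_genome = 30, core_length = 2000,
                          seed = 1)
  expect_error(generate_community(cfg), "infeasible")
})

test_that("recovery metrics behave at the degenerate ends", {
  cfg <- community_config(n_genomes = 3, genome_length = 40000,
                          genes_per_genome = 8, core_length = 8000,
                          seed = 74,
                          planted_islands = list(
                            island_spec("isl1", donor = "g1",
                                        recipients = "g2", n_genes = 3L)))
  comm <- generate_community(cfg)
  ani <- build_ani_matrix(comm$genomes)
  hits <- search_all_vs_all(comm$genomes)
  det <- detect_hgt(hits, ani, comm$genomes)
  perfect <- evaluate_recovery(det, comm$truth)
  expect_equal(perfect$gene_precision, 1)
  expect_equal(perfect$gene_recall, 1)
  expect_equal(perfect$island_exact_match, 1)
  expect_equal(perfect$group_comembership_precision, 1)
  expect_equal(perfect$group_comembership_recall, 1)

  # empty detection: recall 0, precision reported 1 with a flag
  empty <- detect_hgt(hits[0, ], ani, comm$genomes)
  zero <- evaluate_recovery(empty, comm$truth)
  expect_equal(zero$gene_recall, 0)
  expect_equal(zero$gene_precision, 1)
  expect_false(zero$precision_defined)

  # a doctored truth missing one planted copy: the pipeline still finds it,
  # so precision drops below 1 while recall stays 1
  doctored <- comm$truth
  drop_gene <- which(doctored$genes$detectable)[1L]
  doctored$genes <- doctored$genes[-drop_gene, , drop = FALSE]
  dm <- evaluate_recovery(det, doctored)
  expect_lt(dm$gene_precision, 1)
  expect_equal(dm$gene_recall, 1)

  # mismatched genomes are a validation error
  other <- generate_community(
    community_config(n_genomes = 2, genome_length = 30000,
                     genes_per_genome = 6, core_length = 6000, seed = 75))
  fake <- det
  fake$candidates$genome_id[1L] <- "g99"
  expect_error(evaluate_recovery(fake, comm$truth), "outside the community")
})

test_that("genes shared only between close relatives are never candidates", {
  cfg <- community_config(
    n_genomes = 4, genome_length = 40000, genes_per_genome = 8,
    core_length = 8000, seed = 76,
    relative_pairs = list(relative_pair("g1", "g2", 0.05,
                                        n_conserved_genes = 3L)))
  comm <- generate_community(cfg)
  ani <- build_ani_matrix(comm$genomes)
  # the conserved genes do produce raw homology hits...
  hits <- search_all_vs_all(comm$genomes)
  expect_gt(nrow(hits), 0L)
  # ...but the pair ANI is ~95, above the ceiling, so the filter removes them
  expect_gt(ani_lookup(ani, "g1", "g2"), 89)
  det <- detect_hgt(hits, ani, comm$genomes)
  expect_equal(nrow(det$candidates), 0L)

  # the same genes duplicated between unrelated genomes DO become candidates
  cfg2 <- community_config(
    n_genomes = 4, genome_length = 40000, genes_per_genome = 8,
    core_length = 8000, seed = 76,
    planted_islands = list(
      island_spec("dup", donor = "g1", recipients = "g3", n_genes = 1L,
                  gene_lengths = 900L)))
  comm2 <- generate_community(cfg2)
  det2 <- detect_hgt(search_all_vs_all(comm2$genomes),
                     build_ani_matrix(comm2$genomes), comm2$genomes)
  expect_gt(nrow(det2$candidates), 0L)
})
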
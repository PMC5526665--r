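test_that("identical sequences give one full-length perfect hit", {
  set.seed(10)
  q <- random_sequence(1000, 0.5)
  a <- align_pair(q, q)
  expect_equal(nrow(a), 1L)
  expect_equal(a$pct_identity, 100.0)
  expect_equal(a$aln_length, 1000L)
  expect_equal(a$strand, "+")
})

test_that("a reverse-complement subject is found on the minus strand", {
  set.seed(11)
  q <- random_sequence(800, 0.5)
  s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
  a <- align_pair(q, s)
  expect_equal(nrow(a), 1L)
  expect_equal(a$strand, "-")
  expect_equal(a$pct_identity, 100.0)
  expect_equal(a$aln_length, 800L)
  # with strand search off, nothing is found
  a2 <- align_pair(q, s, homology_params(search_both_strands = FALSE))
  expect_equal(nrow(a2), 0L)
})

test_that("95% identity over 600 nt yields no hit at the 99%/500 nt threshold", {
  set.seed(12)
  q <- random_sequence(600, 0.5)
  s <- substitute_at(q, seq(10, 590, by = 20))  # 30 evenly spaced subs
  a <- align_pair(q, s)
  expect_equal(nrow(a), 0L)
  # the full local-alignment oracle agrees: its best alignment is below the
  # identity threshold, and no >=99% segment reaches 500 columns
  o <- sw_oracle(q, s)
  expect_lt(100 * o$n_ident / o$cols, 99)
})

test_that("identity and length thresholds are inclusive", {
  set.seed(13)
  s500 <- random_sequence(500, 0.5)
  expect_equal(nrow(align_pair(s500, s500)), 1L)
  s499 <- random_sequence(499, 0.5)
  expect_equal(nrow(align_pair(s499, s499)), 0L)
  # exactly 99.0% identity over 1000 columns is retained, 98.9% is not
  s1000 <- random_sequence(1000, 0.5)
  at99 <- substitute_at(s1000, seq(50, 950, by = 100))   # 10 subs
  expect_equal(align_pair(s1000, at99)$pct_identity, 99.0)
  at989 <- substitute_at(s1000, seq(45, 945, by = 90))   # 11 subs
  expect_equal(nrow(align_pair(s1000, at989)), 0L)
})

test_that("all-vs-all search reports both directions and sorts deterministically", {
  set.seed(14)
  shared <- random_sequence(1000, 0.5)
  ga <- make_simple_genome("ga", c(shared, random_sequence(800, 0.5)))
  gb <- make_simple_genome("gb", c(random_sequence(700, 0.5), shared))
  hits <- search_all_vs_all(list(ga, gb))
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$query_genome, c("ga", "gb"))
  expect_equal(hits$pct_identity, c(100, 100))
  expect_equal(hits$aln_length, c(1000L, 1000L))
  # byte-identical on rerun and invariant (up to direction) to input order
  hits2 <- search_all_vs_all(list(ga, gb))
  expect_identical(hits, hits2)
  hits3 <- search_all_vs_all(list(gb, ga))
  expect_identical(hits, hits3)
})

test_that("raising thresholds never grows the hit set", {
  set.seed(15)
  base <- replicate(3, random_sequence(900, 0.5))
  ga <- make_simple_genome("ga", base)
  gb <- make_simple_genome("gb", vapply(base, function(s)
    as.character(mutate_sequence(s, 0.005)), ""))
  key <- function(h) paste(h$query_gene, h$subject_gene)
  loose <- search_all_vs_all(list(ga, gb),
                             homology_params(min_identity = 98,
                                             min_length = 400))
  tight_id <- search_all_vs_all(list(ga, gb),
                                homology_params(min_identity = 99.5,
                                                min_length = 400))
  tight_len <- search_all_vs_all(list(ga, gb),
                                 homology_params(min_identity = 98,
                                                 min_length = 901))
  expect_true(all(key(tight_id) %in% key(loose)))
  expect_true(all(key(tight_len) %in% key(loose)))
})

test_that("duplicate gene ids across genomes are rejected", {
  set.seed(16)
  ga <- make_simple_genome("gx", random_sequence(600, 0.5))
  gb <- make_simple_genome("gx", random_sequence(600, 0.5))
  expect_error(search_all_vs_all(list(ga, gb)), "duplicated genome_id")
})

test_that("tabular hit import applies thresholds, drops same-genome rows and converts coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rows <- c(
    "gx|g1\tgy|g9\t99.31\t642\t4\t0\t1\t642\t10\t651\t0.0\t1180",
    "gx|g1\tgy|g8\t98.90\t2000\t22\t0\t1\t2000\t1\t2000\t0.0\t3000",
    "gx|g1\tgx|g2\t100.00\t900\t0\t0\t1\t900\t1\t900\t0.0\t1700",
    "gx|g3\tgy|g7\t99.50\t800\t4\t0\t1\t800\t800\t1\t0.0\t1500")
  writeLines(rows, path)
  expect_warning(hits <- read_tabular_hits(path), "same-genome")
  expect_equal(attr(hits, "n_same_genome"), 1L)
  # retained: g1-g9 and g3-g7 (plus mirrored directions)
  expect_equal(nrow(hits), 4L)
  fwd <- hits[hits$query_gene == "g1" & hits$subject_gene == "g9", ]
  expect_equal(fwd$q_start, 0L)
  expect_equal(fwd$q_end, 642L)
  expect_equal(fwd$s_start, 9L)
  expect_equal(fwd$s_end, 651L)
  minus <- hits[hits$query_gene == "g3", ]
  expect_equal(minus$strand, "-")
  expect_equal(minus$s_start, 0L)
  expect_equal(minus$s_end, 800L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gx|g1\tgy|g9\tnot_a_number\t642\t4\t0\t1\t642\t10\t651\t0\t1",
             bad)
  expect_error(read_tabular_hits(bad), "line 1")
  unresolvable <- withr::local_tempfile(fileext = ".tsv")
  writeLines("plainheader\tgy|g9\t99.5\t642\t4\t0\t1\t642\t10\t651\t0\t1",
             unresolvable)
  expect_error(read_tabular_hits(unresolvable), "plainheader")
})

test_that("seed-and-extend agrees with the Smith-Waterman oracle at pipeline-relevant divergences", {
  set.seed(17)
  for (rep in 1:15) {
    n <- sample(300:2000, 1L)
    q <- random_sequence(n, 0.5)
    s <- as.character(mutate_sequence(q, sample(c(0, 0.005, 0.02, 0.05), 1L)))
    mine <- align_pair(q, s, homology_params(kmer_size = 15),
                       apply_thresholds = FALSE)
    expect_gt(nrow(mine), 0L)
    best <- mine[which.max(mine$score), ]
    o <- sw_oracle(q, s)
    expect_equal(best$score, o$score)
    expect_lt(abs(best$pct_identity - 100 * o$n_ident / o$cols), 0.5)
  }
})
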
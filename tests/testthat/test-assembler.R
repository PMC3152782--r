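single_strand_reads <- function(seqs) {
  tibble::tibble(id = paste0("r", seq_along(seqs)), sequence = seqs,
                 quality = strrep("I", nchar(seqs)), stranded = TRUE,
                 multiplicity = 1L)
}

test_that("graph edges are the weighted k-mer multiset (oracle check)", {
  g <- suppressWarnings(
    build_graph(single_strand_reads("ACGTAC"), 4, both_strands = FALSE))
  expect_equal(g$edges$kmer, sort(c("ACGT", "CGTA", "GTAC")))
  expect_equal(g$edges$count, c(1, 1, 1))

  r2 <- single_strand_reads("ACGTAC"); r2$multiplicity <- 2L
  g2 <- suppressWarnings(build_graph(r2, 4, both_strands = FALSE))
  expect_equal(g2$edges$count, 2 * g$edges$count)

  withr::local_seed(17)
  seqs <- vapply(rep(12, 50), random_dna, character(1))
  r3 <- single_strand_reads(seqs)
  r3$multiplicity <- sample(1:3, 50, replace = TRUE)
  g3 <- build_graph(r3, 5, both_strands = FALSE)
  exp <- oracle_count_kmers(seqs, r3$multiplicity, 5, weighted = TRUE)
  expect_equal(g3$edges$kmer, exp$kmer)
  expect_equal(g3$edges$count, exp$count)
  # mass conservation: total edge mass = weighted k-mer positions
  expect_equal(sum(g3$edges$count), sum(r3$multiplicity * (12 - 5 + 1)))

  # double-stranded graph also carries every reverse-complement k-mer
  g4 <- build_graph(r3, 5, both_strands = TRUE)
  expect_setequal(g4$edges$kmer, union(exp$kmer, oracle_revcomp(exp$kmer)))
})

test_that("unitigs reconstruct a repeat-free transcript and split at
           repeats", {
  withr::local_seed(41)
  tx <- random_dna(300)
  reads <- tile_reads(tx, depth = 40, read_len = 30)
  g <- build_graph(reads, 21, both_strands = FALSE)
  u <- extract_unitigs(g, cov_cutoff = 1)
  expect_equal(u$sequence, tx)

  # double-stranded graph reports the lexicographically smaller orientation
  g2 <- build_graph(reads, 21, both_strands = TRUE)
  u2 <- extract_unitigs(g2)
  expect_equal(u2$sequence, min(tx, oracle_revcomp(tx)))

  # an internal exact repeat longer than k-1 breaks the path
  k <- 15
  rep_unit <- random_dna(k + 5)
  tx_rep <- paste0(random_dna(80), rep_unit, random_dna(60), rep_unit,
                   random_dna(80))
  reads_rep <- tile_reads(tx_rep, depth = 40, read_len = 30, prefix = "q")
  u3 <- extract_unitigs(build_graph(reads_rep, k, both_strands = FALSE))
  expect_gt(nrow(u3), 1)
  # every unitig is still an exact substring of the transcript
  expect_true(all(vapply(u3$sequence, grepl, logical(1), x = tx_rep,
                         fixed = TRUE)))
})

test_that("cov_cutoff discards unitigs below mean edge coverage", {
  reads <- single_strand_reads("ACGTACGTTT")
  g <- build_graph(reads, 5, both_strands = FALSE)
  expect_equal(nrow(extract_unitigs(g, cov_cutoff = 2)), 0)
  expect_gt(nrow(extract_unitigs(g, cov_cutoff = 1)), 0)
})

test_that("tip clipping removes weak spurs, is idempotent, and leaves clean
           graphs alone", {
  withr::local_seed(53)
  tx <- random_dna(200)
  reads <- tile_reads(tx, depth = 30, read_len = 30)
  g <- build_graph(reads, 15, both_strands = FALSE)
  expect_equal(clip_tips(g)$edges, g$edges)  # clean linear graph unchanged

  # plant an error spur: one read with a substitution near its end
  bad <- substring(tx, 50, 79)
  substr(bad, 28, 28) <- c(A = "C", C = "G", G = "T", T = "A")[
    substr(bad, 28, 28)]
  reads2 <- rbind(reads, single_strand_reads(bad))
  g2 <- build_graph(reads2, 15, both_strands = FALSE)
  expect_gt(nrow(g2$edges), nrow(g$edges))
  clipped <- clip_tips(g2)
  # the spur's k-mers are removed exactly (counts on the main path keep the
  # error read's contribution to its correct k-mers)
  expect_equal(clipped$edges$kmer, g$edges$kmer)
  expect_identical(clip_tips(clipped)$edges, clipped$edges)  # idempotent
  u <- extract_unitigs(clipped)
  expect_equal(u$sequence, tx)
})

test_that("assemble recovers error-free transcripts at full length", {
  withr::local_seed(61)
  tx1 <- random_dna(400); tx2 <- random_dna(350)
  reads <- rbind(tile_reads(tx1, 50, 34, prefix = "a"),
                 tile_reads(tx2, 50, 34, prefix = "b"))
  contigs <- assemble(reads, k = 21)
  expect_equal(sort(contigs$sequence),
               sort(c(min(tx1, oracle_revcomp(tx1)),
                      min(tx2, oracle_revcomp(tx2)))))
  expect_true(all(contigs$provenance == "k=21"))
  # determinism: identical input, identical output
  expect_identical(assemble(reads, k = 21), contigs)
})

test_that("multi-k union is a superset of every single-k run and rescues
           short-read transcripts", {
  withr::local_seed(71)
  tx <- random_dna(300)
  reads <- tile_reads(tx, depth = 50, read_len = 24)
  multi <- multi_k_assemble(reads, k_values = c(19, 21, 23))
  for (k in c(19, 21, 23)) {
    single <- assemble(reads, k = k)
    expect_true(all(single$sequence %in% multi$sequence))
  }
  expect_identical(
    multi_k_assemble(reads, k_values = 21)[, c("sequence", "mean_cov")],
    assemble(reads, k = 21)[, c("sequence", "mean_cov")]
  )
  # read length 24: k=19 recovers the transcript full-length, k=33 cannot,
  # but the union still contains it
  multi_wide <- suppressWarnings(multi_k_assemble(reads, k_values = c(19, 33)))
  expect_true(min(tx, oracle_revcomp(tx)) %in% multi_wide$sequence)
})
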
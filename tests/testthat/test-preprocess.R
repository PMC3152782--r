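make_reads <- function(seqs, stranded = TRUE) {
  tibble::tibble(
    id = paste0("r", seq_along(seqs)), sequence = seqs,
    quality = strrep("I", nchar(seqs)), stranded = stranded,
    multiplicity = 1L
  )
}

test_that("dereplication collapses exact duplicates and conserves mass", {
  r <- make_reads(c("ACGT", "ACGT", "ACGT"))
  u <- dereplicate(r)
  expect_equal(nrow(u), 1)
  expect_equal(u$multiplicity, 3L)
  expect_equal(u$id, "r1")  # first-seen representative

  r2 <- make_reads(c("ACGT", "TTTT"))
  expect_equal(dereplicate(r2)$multiplicity, c(1L, 1L))

  # no reverse-complement collapsing: a read and its revcomp stay distinct
  r3 <- make_reads(c("AACGT", revcomp("AACGT")))
  expect_equal(nrow(dereplicate(r3)), 2)

  withr::local_seed(21)
  r4 <- make_reads(sample(c("AAAA", "CCCC", "ACGT"), 50, replace = TRUE))
  u4 <- dereplicate(r4)
  expect_equal(sum(u4$multiplicity), 50)
  expect_false(any(duplicated(u4$sequence)))
})

test_that("k-mer counting matches positions, weights, and the brute-force
           oracle", {
  expect_equal(count_kmers(make_reads("AAAA"), 3)$count, 2)
  w <- make_reads("AAAA"); w$multiplicity <- 5L
  expect_equal(count_kmers(w, 3, weighted = TRUE)$count, 10)
  expect_equal(count_kmers(w, 3, weighted = FALSE)$count, 2)
  # k-mers spanning N are skipped; reads shorter than k contribute nothing
  expect_equal(count_kmers(make_reads("ACNGT"), 3)$count, numeric(0))
  expect_equal(nrow(count_kmers(make_reads("AC"), 3)), 0)

  withr::local_seed(33)
  for (k in c(2, 4, 7)) {
    seqs <- vapply(sample(3:12, 10, replace = TRUE), random_dna, character(1))
    seqs[3] <- sub("^(.)(.)", "\\1N", seqs[3])
    r <- make_reads(seqs); r$multiplicity <- sample(1:4, 10, replace = TRUE)
    for (wt in c(FALSE, TRUE)) {
      got <- count_kmers(r, k, weighted = wt)
      exp <- oracle_count_kmers(seqs, r$multiplicity, k, weighted = wt)
      expect_equal(got$kmer, exp$kmer)
      expect_equal(got$count, exp$count)
    }
  }
})

test_that("rare k-mer filtering keeps exactly the reads the oracle keeps", {
  # distinct overlapping reads tiling one transcript: a central read's every
  # k-mer occurs in >= 3 unique reads (kept); an edge read's terminal k-mer
  # occurs only in itself (dropped)
  withr::local_seed(13)
  tx <- random_dna(20)
  r <- make_reads(substring(tx, 1:11, 10:20))
  tab <- count_kmers(r, 4)
  kept <- filter_rare_kmer_reads(r, tab, min_count = 3)
  expect_true(r$sequence[6] %in% kept$sequence)
  expect_false(r$sequence[1] %in% kept$sequence)
  expect_equal(nrow(kept) + attr(kept, "dropped_count"), nrow(r))

  # reads shorter than k pass (no evidence against them)
  short <- make_reads(c("ACG"))
  tab2 <- count_kmers(short, 5)
  expect_equal(nrow(filter_rare_kmer_reads(short, tab2, 3)), 1)

  # randomized instance with a planted singleton-error read
  withr::local_seed(77)
  tx <- random_dna(80)
  reads <- tile_reads(tx, depth = 10, read_len = 20)
  err <- reads$sequence[1]
  substr(err, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(err, 10, 10))[1]
  reads <- rbind(reads, make_reads(err))
  u <- dereplicate(reads)
  tab3 <- count_kmers(u, 9)
  kept3 <- filter_rare_kmer_reads(u, tab3, 3)
  expect_equal(kept3$sequence,
               u$sequence[oracle_keep_reads(u$sequence, tab3, 9, 3)])
})

test_that("filtering order matters: each strategy can drop reads the other
           keeps", {
  # Witness A: filter_then_derep drops what derep_then_filter keeps.
  # One fragment PCR-amplified 5x, plus 2 distinct fragments sharing its
  # k-mers. Weighted raw counts make everything abundant; after derep the
  # duplicated fragment is a single unique read, and a k-mer private to an
  # edge region falls below 3 in the unique set.
  tx <- "ACGGTTCACCGATG"
  dup <- substr(tx, 1, 8)    # one fragment, 5 copies
  o1 <- substr(tx, 2, 9); o2 <- substr(tx, 3, 10)
  reads <- make_reads(c(rep(dup, 5), o1, o2))
  k <- 6
  a <- preprocess_reads(reads, "derep_then_filter", k = k, min_count = 3)
  b <- preprocess_reads(reads, "filter_then_derep", k = k, min_count = 3)
  # raw weighted counts: dup's first k-mer has count 5 -> kept by (b);
  # unique counts: that k-mer occurs once -> dropped by (a)
  expect_true(dup %in% b$sequence)
  expect_false(dup %in% a$sequence)

  # Witness B: derep_then_filter keeps what filter_then_derep drops is
  # impossible for unweighted-vs-weighted counting of the same multiset
  # (weighted counts dominate unique counts), so the discriminating
  # direction uses min_count sitting between the two counts -- already
  # covered above; here we confirm the dominance property on random data.
  withr::local_seed(99)
  tx2 <- random_dna(60)
  rr <- tile_reads(tx2, depth = 6, read_len = 15)
  rr <- rbind(rr, rr[1:5, ])
  ka <- preprocess_reads(rr, "derep_then_filter", k = 8, min_count = 3)
  kb <- preprocess_reads(rr, "filter_then_derep", k = 8, min_count = 3)
  expect_true(all(ka$sequence %in% kb$sequence))

  expect_equal(preprocess_reads(rr, "none")$sequence,
               dereplicate(rr)$sequence)
  expect_error(preprocess_reads(rr, "bogus"))
})

test_that("pools are dereplicated independently per strandedness flag", {
  r <- rbind(make_reads(rep("ACGTACGT", 2), stranded = TRUE),
             make_reads(rep("ACGTACGT", 3), stranded = FALSE))
  u <- preprocess_reads(r, "none")
  expect_equal(nrow(u), 2)
  expect_equal(sort(u$multiplicity), c(2L, 3L))
  expect_equal(sort(u$stranded), c(FALSE, TRUE))
})
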
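mk_reads <- function(seqs, stranded = TRUE, prefix = "r") {
  tibble::tibble(id = paste0(prefix, seq_along(seqs)), sequence = seqs,
                 quality = strrep("I", nchar(seqs)), stranded = stranded,
                 multiplicity = 1L)
}
mk_contigs <- function(seqs) {
  tibble::tibble(id = sprintf("c%02d", seq_along(seqs)), sequence = seqs,
                 provenance = "k=21", oriented = FALSE)
}

test_that("read mapping places exact and reverse-complement reads and
           matches the brute-force pileup", {
  withr::local_seed(101)
  tx <- random_dna(400)
  contigs <- mk_contigs(tx)

  r1 <- substr(tx, 51, 84)
  m1 <- map_reads(mk_reads(r1), contigs)
  expect_equal(m1$hits$strand, "+")
  expect_equal(m1$hits$pos, 50)
  expect_equal(m1$hits$mismatches, 0)

  m2 <- map_reads(mk_reads(oracle_revcomp(r1)), contigs)
  expect_equal(m2$hits$strand, "-")
  expect_equal(m2$hits$pos, 50)

  # 200 simulated stranded reads: coverage equals the brute-force pileup
  starts <- sample.int(400 - 34 + 1, 200, replace = TRUE)
  reads <- mk_reads(substring(tx, starts, starts + 33))
  m3 <- map_reads(reads, contigs)
  expect_equal(nrow(m3$hits), 200)
  oracle <- oracle_pileup_total(400, m3$hits, 34)
  cov <- m3$coverage
  expect_equal(cov$total, oracle)
  expect_equal(cov$fwd + cov$rev, cov$total)  # all reads stranded here
  # base counts column-sum to depth
  bc <- m3$base_counts
  expect_equal(bc$A + bc$C + bc$G + bc$T, cov$total)
})

test_that("multi-mapping reads are excluded from hits and coverage", {
  withr::local_seed(103)
  dup <- random_dna(120)
  contigs <- mk_contigs(c(paste0(dup, random_dna(80)),
                          paste0(random_dna(90), dup)))
  read <- substr(dup, 11, 44)
  m <- map_reads(mk_reads(read), contigs)
  expect_equal(nrow(m$hits), 0)
  expect_equal(m$n_ambiguous, 1)
  expect_true(all(m$coverage$total == 0))
})

test_that("low-coverage stretches longer than one read length are excised,
           with exact boundary semantics", {
  withr::local_seed(107)
  tx <- random_dna(500)
  contigs <- mk_contigs(tx)
  # reads covering [0,200) and [300,500) only, depth ~10
  left <- tile_reads(substr(tx, 1, 200), 10, 34, prefix = "l")
  right <- tile_reads(substr(tx, 301, 500), 10, 34, prefix = "q")
  m <- map_reads(rbind(left, right), contigs)
  frags <- split_low_coverage(contigs, m, min_reads = 3, read_length = 34,
                              min_fragment_length = 50)
  # oracle: runs of depth < 3 longer than 34 bp are excised
  depth <- oracle_pileup_total(500, m$hits, 34)
  rl_runs <- rle(depth < 3)
  e <- cumsum(rl_runs$lengths); s <- e - rl_runs$lengths
  cut <- rl_runs$values & rl_runs$lengths > 34
  keep_s <- c(0, e[cut]); keep_e <- c(s[cut], 500)
  expected <- substring(tx, keep_s + 1, keep_e)
  expected <- expected[nchar(expected) >= 50]
  expect_equal(frags$sequence, expected)
  expect_equal(nrow(frags), 2)
  # fragment conservation: pieces plus the excised gap rebuild the contig
  gap <- substr(tx, keep_e[1] + 1, keep_s[2])
  expect_equal(paste0(frags$sequence[1], gap, frags$sequence[2]), tx)

  # uniform full coverage: unchanged
  full <- tile_reads(tx, 10, 34, prefix = "f")
  mf <- map_reads(full, contigs)
  expect_equal(split_low_coverage(contigs, mf, 3, 34)$sequence, tx)

  # a zero-coverage run of exactly one read length is NOT split (strict >)
  cov0 <- mf$coverage
  run <- 101:134  # 34 positions
  zero <- mk_contigs(tx)
  mz <- mf
  mz$coverage$total[run] <- 0L
  expect_equal(nrow(split_low_coverage(zero, mz, 3, 34)), 1)
  mz$coverage$total[135] <- 0L  # 35 positions: split
  expect_equal(nrow(split_low_coverage(zero, mz, 3, 34,
                                       min_fragment_length = 50)), 2)
})

test_that("strand transitions split contigs; antisense overlaps are kept on
           both strands", {
  withr::local_seed(109)
  g <- random_dna(1000)
  contigs <- mk_contigs(g)
  # transcript A: genome[0,600) sense; transcript B: revcomp(genome[400,1000))
  a_reads <- tile_reads(substr(g, 1, 600), 30, 34, prefix = "a")
  b_reads <- tile_reads(oracle_revcomp(substr(g, 401, 1000)), 30, 34,
                        prefix = "b")
  m <- map_reads(rbind(a_reads, b_reads), contigs)
  segs <- split_strand_transitions(contigs, m, window = 50, purity = 0.9)
  expect_equal(sort(segs$strand), c("+", "-")[order(c("+", "-"))])
  plus <- segs[segs$strand == "+", ]
  minus <- segs[segs$strand == "-", ]
  # each strand's contig covers its full transcript (overlap on both)
  expect_true(grepl(substr(g, 30, 570), plus$sequence, fixed = TRUE))
  expect_true(grepl(substr(g, 431, 970), minus$sequence, fixed = TRUE))

  # orientation: "-" segment is reverse-complemented to mRNA sense
  oriented <- orient_contigs(segs)
  expect_true(all(oriented$oriented))
  b_sense <- oriented$sequence[oriented$strand == "-"]
  expect_true(grepl(substr(oracle_revcomp(substr(g, 401, 1000)), 30, 570),
                    b_sense, fixed = TRUE))

  # a purely forward contig stays whole
  solo <- mk_contigs(substr(g, 1, 300))
  ms <- map_reads(tile_reads(substr(g, 1, 300), 20, 34, prefix = "s"), solo)
  one <- split_strand_transitions(solo, ms)
  expect_equal(one$strand, "+")
  expect_equal(one$sequence, substr(g, 1, 300))
  expect_equal(orient_contigs(one)$sequence, substr(g, 1, 300))

  # no stranded evidence: contig passes through unoriented
  ns <- map_reads(tile_reads(substr(g, 1, 300), 20, 34, prefix = "n",
                             stranded = FALSE), solo)
  none <- split_strand_transitions(solo, ns)
  expect_true(is.na(none$strand))
  expect_false(orient_contigs(none)$oriented)
})

test_that("consensus polishing corrects planted errors and never flips
           well-supported bases", {
  withr::local_seed(113)
  tx <- random_dna(600)
  broken <- tx
  spots <- c(100, 350, 599)
  for (p in spots)
    substr(broken, p, p) <- c(A = "C", C = "G", G = "T", T = "A")[
      substr(broken, p, p)]
  contigs <- mk_contigs(broken)
  reads <- tile_reads(tx, 50, 34)  # error-free reads from the true sequence
  m <- map_reads(reads, contigs, max_mismatches = 2)
  polished <- polish_contigs(contigs, m, min_depth = 3)
  expect_equal(polished$sequence, tx)
  expect_equal(attr(polished, "n_corrections"), 3L)
  expect_equal(nchar(polished$sequence), nchar(broken))

  # unanimous agreement: nothing changes
  agree <- mk_contigs(tx)
  m2 <- map_reads(reads, agree)
  expect_equal(polish_contigs(agree, m2)$sequence, tx)
  expect_equal(attr(polish_contigs(agree, m2), "n_corrections"), 0L)
})
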
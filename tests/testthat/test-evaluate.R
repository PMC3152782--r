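eval_ctg <- function(seqs) {
  tibble::tibble(id = sprintf("c%02d", seq_along(seqs)), sequence = seqs,
                 provenance = "k=21", oriented = TRUE)
}

test_that("contig alignment finds exact, spliced and tied placements with
           s = matches - mismatches", {
  withr::local_seed(211)
  g <- random_dna(5000)
  genome <- tibble::tibble(id = "chr1", sequence = g)

  # exact substring: full-length single-block hit, score = length
  sub <- substr(g, 1001, 1400)
  h <- align_contigs(eval_ctg(sub), genome)
  expect_equal(nrow(h), 1)
  expect_equal(h$score, 400)
  expect_equal(h$mismatches, 0)
  b <- h$blocks[[1]]
  expect_equal(sum(b[, "qe"] - b[, "qs"]), 400)
  expect_equal(unname(b[1, "ts"]), 1000)

  # two genome blocks separated by a 1000 bp intron: one spliced hit
  spliced <- paste0(substr(g, 101, 300), substr(g, 1301, 1500))
  h2 <- align_contigs(eval_ctg(spliced), genome, max_intron = 5000)
  expect_equal(nrow(h2), 1)
  expect_equal(nrow(h2$blocks[[1]]), 2)
  expect_equal(h2$score, 400)
  gap <- unname(h2$blocks[[1]][2, "ts"] - h2$blocks[[1]][1, "te"])
  expect_equal(gap, 1000)

  # reverse-complement contig aligns on the minus strand
  h3 <- align_contigs(eval_ctg(oracle_revcomp(sub)), genome)
  expect_equal(h3$strand, "-")
  expect_equal(h3$score, 400)

  # two equally scoring loci: both best hits retained
  g2 <- paste0(g, substr(g, 1001, 1400))
  h4 <- align_contigs(eval_ctg(sub), tibble::tibble(id = "chr1",
                                                    sequence = g2))
  expect_equal(nrow(h4), 2)
  expect_equal(unique(h4$score), 400)

  # mismatches reduce the score
  mm <- sub
  substr(mm, 200, 200) <- c(A = "C", C = "G", G = "T", T = "A")[
    substr(mm, 200, 200)]
  h5 <- align_contigs(eval_ctg(mm), genome)
  expect_equal(h5$score, 399 - 1)
  expect_equal(h5$mismatches, 1)
})

test_that("accuracy counts contigs aligning over the threshold fraction", {
  withr::local_seed(223)
  g <- random_dna(4000)
  genome <- tibble::tibble(id = "chr1", sequence = g)
  good <- substring(g, c(1, 501, 1001), c(400, 900, 1500))
  junk <- random_dna(300)
  contigs <- eval_ctg(c(good, junk))
  hits <- align_contigs(contigs, genome)
  a <- accuracy(contigs, hits, aligned_frac = 0.95)
  expect_equal(as.numeric(a), 75)
  expect_error(accuracy(contigs[0, ], hits), "zero")
})

test_that("completeness and contiguity follow strict thresholds and the
           per-base oracle", {
  genes <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "chr1",
                          strand = "+", start = c(0L, 1000L),
                          end = c(500L, 1600L))
  # synthetic hits: gA tiled by two contigs 60%+40%; gB covered 80.0% by one
  mkhit <- function(q, ts, te) tibble::tibble(
    query_id = q, target_id = "chr1", strand = "+", matches = te - ts,
    mismatches = 0L, score = te - ts,
    blocks = list(matrix(c(0L, te - ts, ts, te), 1,
                         dimnames = list(NULL, c("qs", "qe", "ts", "te")))))
  hits <- dplyr::bind_rows(mkhit("c1", 0L, 300L), mkhit("c2", 250L, 500L),
                           mkhit("c3", 1000L, 1480L))
  comp <- completeness(genes, hits, gene_frac = 0.8)
  pg <- attr(comp, "per_gene")
  expect_equal(pg$covered_frac, c(1.0, 0.8))
  # gene covered exactly 80.0% is NOT complete (strict >)
  expect_equal(pg$complete, c(TRUE, FALSE))
  expect_equal(as.numeric(comp), 50)

  cont <- contiguity(genes, hits, gene_frac = 0.8)
  pc <- attr(cont, "per_gene")
  # gA: best single contig covers 60% -> complete but not contiguous
  expect_equal(pc$best_single_contig_frac, c(0.6, 0.8))
  expect_equal(as.numeric(cont), 0)

  # oracle equivalence on a randomized interval fixture
  withr::local_seed(227)
  rgenes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:12), chrom = "chr1", strand = "+",
    start = as.integer(seq(0, 11) * 800),
    end = as.integer(seq(0, 11) * 800 + sample(300:700, 12)))
  rhits <- dplyr::bind_rows(lapply(1:40, function(i) {
    s <- sample.int(9000, 1); w <- sample(100:900, 1)
    mkhit(sprintf("q%02d", sample(12, 1)), s, s + w)
  }))
  got <- attr(completeness(rgenes, rhits), "per_gene")$covered_frac
  blk <- dplyr::bind_rows(lapply(seq_len(nrow(rhits)), function(h)
    tibble::tibble(ts = rhits$blocks[[h]][, "ts"],
                   te = rhits$blocks[[h]][, "te"])))
  exp <- vapply(seq_len(nrow(rgenes)), function(g)
    oracle_gene_covered_frac(rgenes$start[g], rgenes$end[g], blk$ts, blk$te),
    numeric(1))
  expect_equal(got, exp)
  # contiguity never exceeds completeness
  expect_lte(as.numeric(contiguity(rgenes, rhits)),
             as.numeric(completeness(rgenes, rhits)))
})

test_that("gene fusions require > 50% overlap of two or more genes", {
  genes <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "chr1",
                          strand = c("+", "-"), start = c(0L, 1000L),
                          end = c(1000L, 2000L))
  mkhit <- function(q, ts, te) tibble::tibble(
    query_id = q, target_id = "chr1", strand = "+", matches = te - ts,
    mismatches = 0L, score = te - ts,
    blocks = list(matrix(c(0L, te - ts, ts, te), 1,
                         dimnames = list(NULL, c("qs", "qe", "ts", "te")))))
  # 60% of gA and 70% of gB -> fusion
  f1 <- gene_fusions(genes, mkhit("c1", 400L, 1700L), n_contigs = 4)
  expect_equal(f1$count, 1)
  expect_equal(f1$pct, 25)
  expect_equal(f1$contigs$genes, "gA,gB")
  # 60% of gA, 30% of gB -> no fusion
  f2 <- gene_fusions(genes, mkhit("c1", 400L, 1300L), n_contigs = 4)
  expect_equal(f2$count, 0)
  # exactly 50% is not an overlap (strict >)
  f3 <- gene_fusions(genes, mkhit("c1", 500L, 1500L), n_contigs = 4)
  expect_equal(f3$count, 0)
})

test_that("a truth transcriptome evaluates perfectly against its own
           genome", {
  cfg <- simulation_config(n_genes = 12, antisense_overlap_frac = 0.5,
                           seed = 5)
  truth <- generate_transcriptome(cfg)
  contigs <- tibble::tibble(
    id = truth$transcripts$transcript_id,
    sequence = truth$transcripts$sequence,
    provenance = "truth", oriented = TRUE)
  ev <- evaluate_assembly(contigs, truth$genome, truth$genes)
  expect_equal(ev$report$accuracy_pct, 100)
  expect_equal(ev$report$completeness_pct, 100)
  expect_equal(ev$report$contiguity_pct, 100)
  expect_equal(ev$report$fusion_count, 0)
  # broom-style accessors
  expect_equal(nrow(glance(ev)), 1)
  expect_equal(nrow(tidy(ev)), 12)
})

test_that("gene coverage statistics use the sample variance and truth
           labels", {
  stats0 <- gene_coverage_stats(tibble::tibble(gene_id = c("a", "b"),
                                               depth = c(10, 30)))
  expect_equal(stats0$median, 20)
  expect_equal(stats0$variance, 200)
  expect_equal(gene_coverage_stats(
    tibble::tibble(gene_id = letters[1:3], depth = rep(10, 3)))$variance, 0)

  cfg <- simulation_config(n_genes = 6, error_rate = 0,
                           pcr_duplicate_rate = 0, antisense_overlap_frac = 0,
                           expression_log10_range = log10(c(40, 40)),
                           seed = 17)
  ds <- simulate_dataset(cfg)
  dep <- truth_gene_depth(ds$reads, ds$labels, ds$transcripts)
  # realized depth close to the configured 40x
  expect_true(all(abs(dep$depth - 40) < 5))
})
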
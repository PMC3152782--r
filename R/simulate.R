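#' Configuration for the synthetic transcriptome simulator
#'
#' Defaults emulate the statistical structure of deep short-read yeast
#' RNA-Seq: expression spanning orders of magnitude (log-uniform depth),
#' heavy PCR duplication, per-base substitution errors, ~34 bp reads, a
#' mixed stranded/non-stranded read pool, and a fraction of gene pairs
#' placed as overlapping antisense neighbors (UTR-scale overlaps).
#'
#' @param n_genes Number of single-exon genes.
#' @param gene_length_range Gene length range (bp), sampled uniformly.
#' @param intergenic_range Spacer length range between placed units (bp).
#' @param expression_log10_range Per-gene raw read depth is
#'   `10^U(lo, hi)` - log-uniform across genes.
#' @param antisense_overlap_frac Fraction of genes placed as overlapping
#'   antisense pairs; the number of pairs is
#'   `round(frac * n_genes / 2)`.
#' @param overlap_len_range Antisense overlap length range (bp).
#' @param error_rate Per-base substitution probability.
#' @param pcr_duplicate_rate Expected PCR copies *beyond the first* per
#'   distinct fragment. Total read yield is held fixed: the distinct-fragment
#'   count is `total / (1 + rate)` and duplicates (geometric copy counts,
#'   independent sequencing errors per copy) fill the remainder.
#' @param read_length Read length (bp).
#' @param stranded_frac Fraction of reads emitted as strand-specific
#'   (sense-orientation); the rest are non-stranded, in random orientation.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_genes = 50,
                              gene_length_range = c(500, 1500),
                              intergenic_range = c(200, 500),
                              expression_log10_range = log10(c(20, 500)),
                              antisense_overlap_frac = 0.1,
                              overlap_len_range = c(50, 150),
                              error_rate = 0.01,
                              pcr_duplicate_rate = 1.0,
                              read_length = 34,
                              stranded_frac = 0.7,
                              seed = 1L) {
  stopifnot(
    n_genes >= 1,
    diff(gene_length_range) >= 0, diff(overlap_len_range) >= 0,
    diff(expression_log10_range) >= 0,
    antisense_overlap_frac >= 0, antisense_overlap_frac <= 1,
    error_rate >= 0, error_rate <= 1,
    stranded_frac >= 0, stranded_frac <= 1,
    pcr_duplicate_rate >= 0, read_length >= 1
  )
  structure(
    list(n_genes = as.integer(n_genes),
         gene_length_range = as.integer(gene_length_range),
         intergenic_range = as.integer(intergenic_range),
         expression_log10_range = as.numeric(expression_log10_range),
         antisense_overlap_frac = antisense_overlap_frac,
         overlap_len_range = as.integer(overlap_len_range),
         error_rate = error_rate,
         pcr_duplicate_rate = pcr_duplicate_rate,
         read_length = as.integer(read_length),
         stranded_frac = stranded_frac,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic genome, gene catalog and transcriptome
#'
#' Places `n_genes` single-exon genes on one random chromosome, separated by
#' random intergenic spacers. A configured fraction of genes is placed as
#' overlapping antisense pairs: the second gene of a pair starts inside the
#' 3' end of the first, on the opposite strand, sharing `overlap_len_range`
#' bp of genomic sequence - the geometry that fuses neighboring transcripts
#' in strand-blind assemblies. Deterministic under `config$seed`.
#'
#' @param config A [simulation_config()] object.
#' @return List of class `sim_truth`: `genome` (tibble `id`, `sequence`),
#'   `genes` (gene models, 0-based half-open), `transcripts` (tibble
#'   `transcript_id`, `gene_id`, `sequence`, `strand`, `chrom`, `start`,
#'   `end`; sequence is the mRNA sense strand), `config`.
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n_pairs <- round(config$antisense_overlap_frac * config$n_genes / 2)
    n_single <- config$n_genes - 2L * n_pairs
    if (n_single < 0) abort("antisense_overlap_frac too large for n_genes")
    units <- sample(c(rep("single", n_single), rep("pair", n_pairs)))
    glen <- function() sample(config$gene_length_range[1]:
                                config$gene_length_range[2], 1)
    spacer <- function() sample(config$intergenic_range[1]:
                                  config$intergenic_range[2], 1)
    starts <- integer(); ends <- integer(); strands <- character()
    pos <- 0L
    for (u in units) {
      pos <- pos + spacer()
      if (u == "single") {
        L <- glen()
        st <- sample(c("+", "-"), 1)
        starts <- c(starts, pos); ends <- c(ends, pos + L)
        strands <- c(strands, st)
        pos <- pos + L
      } else {
        L1 <- glen(); L2 <- glen()
        ov <- sample(config$overlap_len_range[1]:config$overlap_len_range[2], 1)
        ov <- min(ov, L1 - 1L, L2 - 1L)
        starts <- c(starts, pos, pos + L1 - ov)
        ends <- c(ends, pos + L1, pos + L1 - ov + L2)
        strands <- c(strands, "+", "-")
        pos <- pos + L1 - ov + L2
      }
    }
    pos <- pos + spacer()
    genome_seq <- .random_dna(pos)
    ord <- order(starts, ends)
    genes <- tibble(
      gene_id = sprintf("g%03d", seq_along(ord)),
      chrom = "chr1",
      strand = strands[ord],
      start = starts[ord],
      end = ends[ord]
    )
    tx_seq <- substring(genome_seq, genes$start + 1, genes$end)
    neg <- genes$strand == "-"
    tx_seq[neg] <- revcomp(tx_seq[neg])
    structure(
      list(
        genome = tibble(id = "chr1", sequence = genome_seq),
        genes = genes,
        transcripts = tibble(
          transcript_id = paste0(genes$gene_id, ".t1"),
          gene_id = genes$gene_id,
          sequence = tx_seq,
          strand = genes$strand,
          chrom = genes$chrom,
          start = genes$start,
          end = genes$end
        ),
        config = config
      ),
      class = "sim_truth"
    )
  })
}

#' Simulate stranded and non-stranded reads with ground truth
#'
#' Per transcript, the raw read count is `round(depth * length /
#' read_length)` with depth drawn log-uniform from
#' `expression_log10_range`. Fragment starts are uniform along the
#' transcript; the distinct-fragment count is the raw count divided by
#' `1 + pcr_duplicate_rate`, and PCR duplicates (geometric copy counts, each
#' copy with independent sequencing errors) make up the difference, so total
#' yield is independent of the duplication rate. Stranded reads are emitted
#' in sense orientation; non-stranded reads in random orientation.
#' Transcripts shorter than the read length are skipped with a warning.
#' Deterministic under the configuration seed.
#'
#' @param truth A `sim_truth` object from [generate_transcriptome()].
#' @param config A [simulation_config()]; defaults to the one inside
#'   `truth`.
#' @return List: `reads` (read tibble, multiplicity 1) and `labels` (tibble
#'   `read_id`, `transcript_id`, `start` 0-based on the transcript,
#'   `orientation` of the read relative to the transcript, `stranded`,
#'   `fragment_id`, `is_duplicate`, `error_pos` list-column of 1-based
#'   positions in the read).
#' @export
simulate_reads <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  rl <- config$read_length
  withr::with_seed(config$seed + 1L, {
    # depths drawn up-front so the expression profile is identical across
    # configurations that only change the error/duplication model
    depths <- 10^stats::runif(nrow(truth$transcripts),
                              config$expression_log10_range[1],
                              config$expression_log10_range[2])
    per_tx <- lapply(seq_len(nrow(truth$transcripts)), function(t) {
      tx <- truth$transcripts[t, ]
      L <- nchar(tx$sequence)
      if (L < rl) {
        warn(paste0("transcript ", tx$transcript_id, " shorter than read ",
                    "length; skipped"))
        return(NULL)
      }
      depth <- depths[t]
      n_total <- max(1L, round(depth * L / rl))
      n_frag <- max(1L, round(n_total / (1 + config$pcr_duplicate_rate)))
      starts <- sample.int(L - rl + 1L, n_frag, replace = TRUE) - 1L
      # geometric extra-copy counts per fragment, clipped to the total yield
      dup_budget <- n_total - n_frag
      extra <- stats::rgeom(n_frag, 1 / (1 + config$pcr_duplicate_rate))
      cum_prev <- c(0L, cumsum(extra)[-n_frag])
      copies <- 1L + pmax(0L, pmin(extra, dup_budget - cum_prev))
      frag_id <- rep(seq_len(n_frag), copies)
      tibble(
        transcript_id = tx$transcript_id,
        start = starts[frag_id],
        fragment_id = paste0(tx$transcript_id, ".f", frag_id),
        is_duplicate = duplicated(frag_id),
        base = substring(tx$sequence, starts[frag_id] + 1,
                         starts[frag_id] + rl)
      )
    })
    per_tx <- bind_rows(per_tx[!vapply(per_tx, is.null, logical(1))])
    n <- nrow(per_tx)
    stranded <- stats::runif(n) < config$stranded_frac
    orient <- ifelse(stranded, "+",
                     ifelse(stats::runif(n) < 0.5, "+", "-"))
    seqs <- per_tx$base
    flip <- orient == "-"
    seqs[flip] <- revcomp(seqs[flip])
    mut <- cpp_mutate_seqs(seqs, config$error_rate)
    ids <- sprintf("r%07d", seq_len(n))
    list(
      reads = tibble(
        id = ids,
        sequence = mut$sequence,
        quality = strrep("I", rl),
        stranded = stranded,
        multiplicity = 1L
      ),
      labels = tibble(
        read_id = ids,
        transcript_id = per_tx$transcript_id,
        start = per_tx$start,
        orientation = orient,
        stranded = stranded,
        fragment_id = per_tx$fragment_id,
        is_duplicate = per_tx$is_duplicate,
        error_pos = mut$error_pos
      )
    )
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: [generate_transcriptome()] followed by
#' [simulate_reads()].
#'
#' @param config A [simulation_config()].
#' @return List of class `sim_dataset`: `genome`, `genes`, `transcripts`,
#'   `reads`, `labels`, `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  truth <- generate_transcriptome(config)
  rd <- simulate_reads(truth)
  structure(
    list(genome = truth$genome, genes = truth$genes,
         transcripts = truth$transcripts, reads = rd$reads,
         labels = rd$labels, config = config),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("synthetic RNA-Seq dataset:", nrow(x$genes), "genes,",
      nrow(x$reads), "reads of", x$config$read_length, "bp (",
      round(100 * mean(x$reads$stranded)), "% stranded), seed",
      x$config$seed, "\n")
  invisible(x)
}
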
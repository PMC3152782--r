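#' Align contigs to a reference genome
#'
#' Spliced-lite alignment: exact seed anchors are chained co-linearly,
#' allowing gaps on the reference (introns) of at most `max_intron` bp
#' between blocks. Alignments are scored `s = matches - mismatches`; per
#' contig, every hit attaining the maximum score is retained (multiple
#' best-scoring hits are all kept).
#'
#' @param contigs Contig tibble.
#' @param genome Reference tibble (`id`, `sequence`), e.g. from
#'   [read_fasta()].
#' @param max_intron Maximum reference gap between chained blocks (bp).
#' @param seed_k Exact seed length.
#' @param stride Seed sampling stride along the query.
#' @return Hit tibble: `query_id`, `target_id`, `strand`, `matches`,
#'   `mismatches`, `score`, and `blocks` - a list-column of integer matrices
#'   with columns `qs`, `qe`, `ts`, `te` (0-based half-open; query
#'   coordinates of `-` hits refer to the reverse-complemented query).
#' @export
align_contigs <- function(contigs, genome, max_intron = 5000, seed_k = 16,
                          stride = 8) {
  stopifnot(nrow(genome) >= 1)
  res <- cpp_align_contigs(contigs$sequence, genome$sequence,
                           as.integer(seed_k), as.integer(stride),
                           as.integer(max_intron))
  blocks <- lapply(res$blocks, function(m) {
    colnames(m) <- c("qs", "qe", "ts", "te")
    m
  })
  tibble(
    query_id = contigs$id[res$query],
    target_id = genome$id[res$target],
    strand = ifelse(res$strand > 0, "+", "-"),
    matches = res$matches,
    mismatches = res$mismatches,
    score = res$score,
    blocks = blocks
  )
}

# long table of alignment blocks
.block_table <- function(hits) {
  if (nrow(hits) == 0)
    return(tibble(query_id = character(), target_id = character(),
                  qs = integer(), qe = integer(), ts = integer(),
                  te = integer()))
  bind_rows(lapply(seq_len(nrow(hits)), function(h) {
    b <- hits$blocks[[h]]
    tibble(query_id = hits$query_id[h], target_id = hits$target_id[h],
           qs = b[, "qs"], qe = b[, "qe"], ts = b[, "ts"], te = b[, "te"])
  }))
}

#' Assembly accuracy
#'
#' The percentage of contigs whose best reference hit aligns more than
#' `aligned_frac` of the contig's own length (aligned query bases, summed
#' over the hit's blocks). Contigs with no hit count as inaccurate.
#'
#' @param contigs Contig tibble.
#' @param hits [align_contigs()] output for those contigs.
#' @param aligned_frac Alignment-fraction threshold (strict `>`).
#' @return Percentage in `[0, 100]`, with attribute `per_contig` (tibble
#'   `id`, `aligned_frac`, `accurate`).
#' @export
accuracy <- function(contigs, hits, aligned_frac = 0.95) {
  if (nrow(contigs) == 0) abort("accuracy is undefined for zero contigs")
  aligned <- vapply(seq_len(nrow(hits)), function(h) {
    b <- hits$blocks[[h]]
    sum(b[, "qe"] - b[, "qs"])
  }, numeric(1))
  per_hit <- tibble(id = hits$query_id, aligned = aligned) %>%
    group_by(.data$id) %>%
    summarise(aligned = max(.data$aligned), .groups = "drop")
  per_contig <- tibble(id = contigs$id,
                       length = nchar(contigs$sequence)) %>%
    left_join(per_hit, by = "id") %>%
    mutate(aligned = ifelse(is.na(.data$aligned), 0, .data$aligned),
           aligned_frac = .data$aligned / .data$length,
           accurate = .data$aligned_frac > !!aligned_frac)
  out <- 100 * mean(per_contig$accurate)
  attr(out, "per_contig") <- per_contig
  out
}

# covered fraction of each gene by a set of blocks; optionally per contig
.gene_cover <- function(genes, blk) {
  vapply(seq_len(nrow(genes)), function(g) {
    gb <- blk[blk$target_id == genes$chrom[g] &
                blk$te > genes$start[g] & blk$ts < genes$end[g], , drop = FALSE]
    if (nrow(gb) == 0) return(0)
    ir <- IRanges::IRanges(start = pmax(gb$ts, genes$start[g]) + 1L,
                           end = pmin(gb$te, genes$end[g]))
    sum(IRanges::width(IRanges::reduce(ir))) / (genes$end[g] - genes$start[g])
  }, numeric(1))
}

#' Gene-level completeness of an assembly
#'
#' The percentage of annotated genes whose length is covered at more than
#' `gene_frac` (strictly) by the union of all contig alignment blocks.
#' Coverage is computed on the reference coordinate system, strand-blind.
#'
#' @param genes Gene model tibble ([read_gff()]).
#' @param hits [align_contigs()] output.
#' @param gene_frac Gene-length fraction threshold (strict `>`).
#' @return Percentage, with attribute `per_gene` (tibble `gene_id`,
#'   `covered_frac`, `complete`).
#' @export
completeness <- function(genes, hits, gene_frac = 0.8) {
  blk <- .block_table(hits)
  frac <- .gene_cover(genes, blk)
  per_gene <- tibble(gene_id = genes$gene_id, covered_frac = frac,
                     complete = frac > gene_frac)
  out <- if (nrow(genes)) 100 * mean(per_gene$complete) else NA_real_
  attr(out, "per_gene") <- per_gene
  out
}

#' Gene-level contiguity of an assembly
#'
#' The percentage of genes covered at more than `gene_frac` of their length
#' by a *single* contig - the genes represented full-length by one
#' assembled transcript.
#'
#' @inheritParams completeness
#' @return Percentage, with attribute `per_gene` (tibble `gene_id`,
#'   `best_single_contig_frac`, `contiguous`).
#' @export
contiguity <- function(genes, hits, gene_frac = 0.8) {
  blk <- .block_table(hits)
  best <- vapply(seq_len(nrow(genes)), function(g) {
    gb <- blk[blk$target_id == genes$chrom[g] &
                blk$te > genes$start[g] & blk$ts < genes$end[g], , drop = FALSE]
    if (nrow(gb) == 0) return(0)
    len <- genes$end[g] - genes$start[g]
    max(vapply(split(gb, gb$query_id), function(qb) {
      ir <- IRanges::IRanges(start = pmax(qb$ts, genes$start[g]) + 1L,
                             end = pmin(qb$te, genes$end[g]))
      sum(IRanges::width(IRanges::reduce(ir))) / len
    }, numeric(1)))
  }, numeric(1))
  per_gene <- tibble(gene_id = genes$gene_id, best_single_contig_frac = best,
                     contiguous = best > gene_frac)
  out <- if (nrow(genes)) 100 * mean(per_gene$contiguous) else NA_real_
  attr(out, "per_gene") <- per_gene
  out
}

#' Detect gene-fusion contigs
#'
#' A contig and a gene overlap when the intersection of the contig's aligned
#' reference span with the gene interval exceeds `fusion_frac` of the gene's
#' length (strictly). A contig overlapping two or more genes this way
#' contains a gene fusion event - typically neighboring genes joined
#' through overlapping UTRs.
#'
#' @inheritParams completeness
#' @param n_contigs Denominator for the fusion percentage (total contigs in
#'   the assembly); defaults to the number of aligned contigs.
#' @param fusion_frac Gene-length overlap fraction (strict `>`).
#' @return List: `count`, `pct`, and `contigs` (tibble `contig_id`,
#'   `n_genes`, `genes`).
#' @export
gene_fusions <- function(genes, hits, n_contigs = NULL, fusion_frac = 0.5) {
  blk <- .block_table(hits)
  if (is.null(n_contigs)) n_contigs <- length(unique(hits$query_id))
  fused <- list()
  for (q in unique(blk$query_id)) {
    qb <- blk[blk$query_id == q, , drop = FALSE]
    hit_genes <- character()
    for (g in seq_len(nrow(genes))) {
      gb <- qb[qb$target_id == genes$chrom[g] &
                 qb$te > genes$start[g] & qb$ts < genes$end[g], , drop = FALSE]
      if (nrow(gb) == 0) next
      ir <- IRanges::IRanges(start = pmax(gb$ts, genes$start[g]) + 1L,
                             end = pmin(gb$te, genes$end[g]))
      ovl <- sum(IRanges::width(IRanges::reduce(ir)))
      if (ovl > fusion_frac * (genes$end[g] - genes$start[g]))
        hit_genes <- c(hit_genes, genes$gene_id[g])
    }
    if (length(hit_genes) >= 2)
      fused[[q]] <- tibble(contig_id = q, n_genes = length(hit_genes),
                           genes = paste(hit_genes, collapse = ","))
  }
  ftab <- if (length(fused)) bind_rows(fused) else
    tibble(contig_id = character(), n_genes = integer(), genes = character())
  list(count = nrow(ftab),
       pct = if (n_contigs > 0) 100 * nrow(ftab) / n_contigs else NA_real_,
       contigs = ftab)
}

#' Evaluate an assembly against a reference genome and gene catalog
#'
#' Computes the four assembly-quality criteria - accuracy, completeness,
#' contiguity and gene fusions - from a single contig-to-genome alignment.
#'
#' @inheritParams align_contigs
#' @param genes Gene model tibble ([read_gff()]).
#' @param aligned_frac Accuracy threshold (fraction of contig length).
#' @param gene_frac Completeness/contiguity threshold (fraction of gene
#'   length).
#' @param fusion_frac Fusion overlap threshold (fraction of gene length).
#' @return An object of class `txeval`: list with `report` (one-row tibble:
#'   `accuracy_pct`, `completeness_pct`, `contiguity_pct`, `fusion_count`,
#'   `fusion_pct`, `n_contigs`, `n_genes`), `per_gene`, `per_contig`,
#'   `fusions`, `hits`.
#' @export
evaluate_assembly <- function(contigs, genome, genes, aligned_frac = 0.95,
                              gene_frac = 0.8, fusion_frac = 0.5,
                              max_intron = 5000) {
  hits <- align_contigs(contigs, genome, max_intron = max_intron)
  acc <- accuracy(contigs, hits, aligned_frac)
  comp <- completeness(genes, hits, gene_frac)
  cont <- contiguity(genes, hits, gene_frac)
  fus <- gene_fusions(genes, hits, n_contigs = nrow(contigs),
                      fusion_frac = fusion_frac)
  per_gene <- dplyr::left_join(attr(comp, "per_gene"),
                               attr(cont, "per_gene"), by = "gene_id")
  structure(
    list(
      report = tibble(
        accuracy_pct = as.numeric(acc),
        completeness_pct = as.numeric(comp),
        contiguity_pct = as.numeric(cont),
        fusion_count = fus$count,
        fusion_pct = fus$pct,
        n_contigs = nrow(contigs),
        n_genes = nrow(genes)
      ),
      per_gene = per_gene,
      per_contig = attr(acc, "per_contig"),
      fusions = fus$contigs,
      hits = hits
    ),
    class = "txeval"
  )
}

#' @export
print.txeval <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0(
    "assembly evaluation: %d contigs vs %d genes\n",
    "  accuracy     %5.1f%%\n  completeness %5.1f%%\n",
    "  contiguity   %5.1f%%\n  gene fusions %d (%.2f%%)\n"),
    r$n_contigs, r$n_genes, r$accuracy_pct, r$completeness_pct,
    r$contiguity_pct, r$fusion_count, r$fusion_pct))
  invisible(x)
}

#' @export
glance.txeval <- function(x, ...) x$report

#' @export
tidy.txeval <- function(x, ...) x$per_gene

#' @rdname evaluate_assembly
#' @param object A `txeval` object.
#' @param ... Unused.
#' @export
autoplot.txeval <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$report[, c("accuracy_pct", "completeness_pct", "contiguity_pct",
                      "fusion_pct")],
    cols = dplyr::everything(), names_to = "criterion", values_to = "pct")
  df$criterion <- sub("_pct$", "", df$criterion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$criterion, y = .data$pct)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "percent",
                  title = "assembly evaluation") +
    ggplot2::theme_minimal()
}

#' Per-gene coverage summary
#'
#' Median and across-gene variance (sample, n-1 denominator) of per-gene
#' mean per-base read depth. Used to quantify how dereplication and rare
#' k-mer filtering flatten the orders-of-magnitude coverage unevenness of
#' RNA-Seq data.
#'
#' @param gene_depth Tibble `gene_id`, `depth` (mean per-base depth).
#' @return List: `per_gene`, `median`, `variance`.
#' @export
gene_coverage_stats <- function(gene_depth) {
  list(per_gene = gene_depth,
       median = stats::median(gene_depth$depth),
       variance = stats::var(gene_depth$depth))
}

#' Per-gene depth from simulation truth labels
#'
#' Computes each transcript's mean per-base depth from the reads attributed
#' to it by the simulator's ground truth: `reads * read_length / length`.
#' Each read record counts once (dereplication multiplicity is ignored), so
#' comparing raw and preprocessed read sets shows the coverage-flattening
#' effect of preprocessing.
#'
#' @param reads Read tibble (raw or preprocessed).
#' @param labels Truth label tibble from [simulate_reads()].
#' @param transcripts Transcript tibble from [generate_transcriptome()].
#' @return Tibble `gene_id`, `depth`, one row per transcript.
#' @export
truth_gene_depth <- function(reads, labels, transcripts) {
  lab <- labels[labels$read_id %in% reads$id, , drop = FALSE]
  cnt <- table(factor(lab$transcript_id, levels = transcripts$transcript_id))
  rl <- if (nrow(reads)) max(nchar(reads$sequence)) else 0
  tibble(
    gene_id = transcripts$gene_id,
    depth = as.numeric(cnt) * rl / nchar(transcripts$sequence)
  )
}
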
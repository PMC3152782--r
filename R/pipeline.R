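#' Pipeline configuration
#'
#' All tunable parameters of the assembly pipeline in one serializable
#' object. Unknown keys are rejected when reading a config file.
#'
#' @param stranded_fastq,unstranded_fastq Character vectors of input FASTQ
#'   paths for the strand-specific and non-strand-specific pools (either may
#'   be empty, not both).
#' @param output_dir Directory for per-stage artifacts.
#' @param strategy Preprocessing strategy (see [preprocess_reads()]).
#' @param filter_k,min_kmer_count Rare k-mer filter parameters.
#' @param k_values Assembly hash-length ladder.
#' @param cov_cutoff Minimum mean unitig coverage.
#' @param min_overlap,min_identity Contig merge parameters.
#' @param seed_k,max_mismatches Read-mapping parameters.
#' @param min_span_reads Depth below which a stretch is unsupported.
#' @param window,purity Strand-transition classification parameters.
#' @param polish_min_depth Minimum depth for consensus polishing.
#' @param min_contig_length Final output length filter (bp, inclusive).
#' @param strand_split Run the strand splitting/orientation stages?
#' @param antisense_protocol Set to `TRUE` for dUTP-style libraries whose
#'   stranded reads are the antisense of the mRNA: the strand assignment of
#'   every segment is flipped before orientation.
#' @param reference_fasta,genes_gff Optional reference genome and gene
#'   catalog; when both are set the pipeline evaluates its output.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(stranded_fastq = character(),
                            unstranded_fastq = character(),
                            output_dir = "denovotx_out",
                            strategy = "derep_then_filter",
                            filter_k = 13L,
                            min_kmer_count = 3,
                            k_values = seq(19L, 33L, by = 2L),
                            cov_cutoff = 1,
                            min_overlap = 40L,
                            min_identity = 0.94,
                            seed_k = 17L,
                            max_mismatches = 2L,
                            min_span_reads = 3,
                            window = 50L,
                            purity = 0.9,
                            polish_min_depth = 3,
                            min_contig_length = 100L,
                            strand_split = TRUE,
                            antisense_protocol = FALSE,
                            reference_fasta = NULL,
                            genes_gff = NULL) {
  structure(
    list(stranded_fastq = as.character(unlist(stranded_fastq)),
         unstranded_fastq = as.character(unlist(unstranded_fastq)),
         output_dir = output_dir, strategy = strategy,
         filter_k = as.integer(filter_k), min_kmer_count = min_kmer_count,
         k_values = as.integer(unlist(k_values)), cov_cutoff = cov_cutoff,
         min_overlap = as.integer(min_overlap), min_identity = min_identity,
         seed_k = as.integer(seed_k),
         max_mismatches = as.integer(max_mismatches),
         min_span_reads = min_span_reads, window = as.integer(window),
         purity = purity, polish_min_depth = polish_min_depth,
         min_contig_length = as.integer(min_contig_length),
         strand_split = isTRUE(strand_split),
         antisense_protocol = isTRUE(antisense_protocol),
         reference_fasta = reference_fasta, genes_gff = genes_gff),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration file (YAML)
#'
#' @param path Config file path.
#' @return [read_pipeline_config()]: a `pipeline_config`;
#'   [write_pipeline_config()]: `path`, invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  raw[vapply(raw, is.null, logical(1))] <- NULL
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Assemble a transcriptome from reads, in memory
#'
#' The full pipeline core: preprocess (dereplication + rare k-mer filter),
#' multi-k de Bruijn assembly, duplicate removal and greedy overlap merging,
#' read-back mapping, low-coverage splitting, strand-transition splitting,
#' orientation to mRNA sense, consensus polishing, and the final length
#' filter. Deterministic: identical inputs and options give identical
#' output.
#'
#' @param reads Read tibble (with `stranded` flags).
#' @param config A [pipeline_config()]; input/output fields are ignored
#'   here.
#' @param verbose Emit per-stage messages?
#' @return An object of class `txasm`: list with `contigs` (tibble `id`,
#'   `sequence`, `strand`, `oriented`, `provenance`), `stats` (per-stage
#'   counts), `stage` (list of intermediate contig tibbles), and `config`.
#' @export
assemble_transcriptome <- function(reads, config = pipeline_config(),
                                   verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stats <- list(reads_in = nrow(reads))
  if (nrow(reads) == 0) abort("empty read set")
  t0 <- Sys.time()

  pre <- preprocess_reads(reads, strategy = config$strategy,
                          k = config$filter_k,
                          min_count = config$min_kmer_count)
  ps <- attr(pre, "stats")
  stats$reads_unique <- ps$n_unique
  stats$reads_filtered_out <- ps$n_filtered_out
  stats$reads_kept <- nrow(pre)
  say("preprocess: %d reads -> %d unique -> %d kept", nrow(reads),
      ps$n_unique, nrow(pre))
  if (nrow(pre) == 0) abort("empty read set after preprocessing")

  contigs <- multi_k_assemble(pre, k_values = config$k_values,
                              cov_cutoff = config$cov_cutoff)
  stats$contigs_multi_k <- nrow(contigs)
  say("assembly: %d contigs across k = {%s}", nrow(contigs),
      paste(config$k_values, collapse = ","))
  if (nrow(contigs) == 0) abort("assembly produced no contigs")

  merged <- merge_contigs(contigs, min_overlap = config$min_overlap,
                          min_identity = config$min_identity)
  stats$contigs_merged <- nrow(merged)
  say("merge: %d contigs", nrow(merged))

  mapping <- map_reads(pre, merged, seed_k = config$seed_k,
                       max_mismatches = config$max_mismatches)
  stats$reads_mapped <- nrow(mapping$hits)
  stats$reads_ambiguous <- mapping$n_ambiguous
  say("mapping: %d hits (%d ambiguous, %d unmapped)", nrow(mapping$hits),
      mapping$n_ambiguous, mapping$n_unmapped)

  read_length <- max(nchar(pre$sequence))
  split1 <- split_low_coverage(merged, mapping,
                               min_reads = config$min_span_reads,
                               read_length = read_length,
                               min_fragment_length = config$min_contig_length)
  stats$contigs_after_lowcov_split <- nrow(split1)
  say("low-coverage split: %d fragments", nrow(split1))

  have_stranded <- any(pre$stranded)
  if (config$strand_split && have_stranded) {
    split2 <- split_strand_transitions(split1, mapping,
                                       window = config$window,
                                       purity = config$purity)
    if (config$antisense_protocol)
      split2$strand <- unname(c("+" = "-", "-" = "+")[split2$strand])
    oriented <- orient_contigs(split2)
  } else {
    if (config$strand_split && !have_stranded)
      warn("no stranded reads: strand splitting skipped, contigs unoriented")
    split1$strand <- NA_character_
    oriented <- split1
    oriented$oriented <- FALSE
  }
  stats$contigs_after_strand_split <- nrow(oriented)
  say("strand split: %d fragments", nrow(oriented))

  polished <- polish_contigs(oriented, min_depth = config$polish_min_depth)
  stats$bases_corrected <- attr(polished, "n_corrections")
  say("polish: %d bases corrected", stats$bases_corrected)

  final <- polished[nchar(polished$sequence) >= config$min_contig_length, ,
                    drop = FALSE]
  final <- dplyr::arrange(final, desc(nchar(.data$sequence)), .data$sequence,
                          .data$id)
  out <- tibble(
    id = if (nrow(final)) sprintf("tx%05d", seq_len(nrow(final)))
         else character(),
    sequence = final$sequence,
    strand = if ("strand" %in% names(final)) final$strand
             else NA_character_,
    oriented = final$oriented,
    provenance = paste0(final$id, ";", final$provenance)
  )
  stats$contigs_final <- nrow(out)
  stats$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  say("final: %d contigs >= %d bp", nrow(out), config$min_contig_length)

  structure(
    list(contigs = out, stats = stats,
         stage = list(preprocessed = pre, multi_k = contigs, merged = merged),
         config = config),
    class = "txasm"
  )
}

#' @export
print.txasm <- function(x, ...) {
  s <- x$stats
  cat("de novo transcriptome assembly:", s$reads_in, "reads ->",
      s$contigs_final, "contigs\n")
  invisible(x)
}

#' @export
glance.txasm <- function(x, ...) as_tibble(x$stats)

#' @export
tidy.txasm <- function(x, ...) x$contigs

#' Run the full pipeline from a configuration
#'
#' File-level orchestration: reads the stranded and non-stranded FASTQ
#' pools, runs [assemble_transcriptome()], writes per-stage artifacts
#' (preprocessed reads, per-stage contig FASTAs, final assembly, stats
#' JSON) under `config$output_dir`, and - when a reference genome and gene
#' GFF are configured - an evaluation report. Rerunning with identical
#' config and inputs is byte-identical.
#'
#' @param config A [pipeline_config()] with input paths set.
#' @param verbose Emit per-stage messages?
#' @return The `txasm` object, with an `evaluation` element when a
#'   reference was supplied.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(config$stranded_fastq) + length(config$unstranded_fastq) == 0)
    abort("no input FASTQ files configured")
  reads <- bind_rows(
    bind_rows(lapply(config$stranded_fastq, read_fastq, stranded = TRUE)),
    bind_rows(lapply(config$unstranded_fastq, read_fastq, stranded = FALSE))
  )
  res <- assemble_transcriptome(reads, config, verbose = verbose)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$output_dir, f)
  write_fastq(res$stage$preprocessed, p("preprocessed.fastq"))
  write_fasta(res$stage$multi_k, p("contigs_multi_k.fasta"), min_length = 0)
  write_fasta(res$stage$merged, p("contigs_merged.fasta"), min_length = 0)
  write_fasta(res$contigs, p("assembly.fasta"),
              min_length = config$min_contig_length)
  if (!is.null(config$reference_fasta) && !is.null(config$genes_gff)) {
    ev <- evaluate_assembly(res$contigs, read_fasta(config$reference_fasta),
                            read_gff(config$genes_gff))
    res$evaluation <- ev
    jsonlite::write_json(as.list(ev$report), p("evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(res$stats, p("stats.json"), auto_unbox = TRUE,
                       digits = NA)
  res
}

#' Strand-coverage plot for a contig
#'
#' Log2-scaled forward (red) and reverse (blue) stranded read coverage
#' along a contig - the diagnostic view of antisense transcript overlap
#' and strandness transitions.
#'
#' @param mapping A [map_reads()] result.
#' @param contig_id Contig to plot (default: the first).
#' @return A ggplot object.
#' @export
plot_strand_coverage <- function(mapping, contig_id = NULL) {
  cov <- mapping$coverage
  if (is.null(contig_id)) contig_id <- cov$contig_id[1]
  cov <- cov[cov$contig_id == contig_id, , drop = FALSE]
  df <- tidyr::pivot_longer(cov[, c("pos", "fwd", "rev")],
                            cols = c("fwd", "rev"),
                            names_to = "strand", values_to = "depth")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos,
                                   y = log2(.data$depth + 1),
                                   colour = .data$strand)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(fwd = "firebrick",
                                            rev = "steelblue")) +
    ggplot2::labs(x = "contig position (bp)", y = "log2(depth + 1)",
                  title = contig_id) +
    ggplot2::theme_minimal()
}
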
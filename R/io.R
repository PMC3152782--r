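#' Read a FASTQ file into a read table
#'
#' Parses a (possibly gzip-compressed) 4-line-record FASTQ file into the
#' tibble of reads used throughout the pipeline. Sequences are uppercased;
#' `N` bases are preserved.
#'
#' @param path Path to a FASTQ file, plain or gzip.
#' @param stranded Logical flag recorded on every read: `TRUE` marks reads
#'   from a strand-specific library whose sequence is the mRNA sense strand.
#' @return A tibble with columns `id`, `sequence`, `quality`, `stranded` and
#'   `multiplicity` (always 1 on input; dereplication fills it in).
#' @seealso [read_fasta()], [dereplicate()]
#' @export
read_fastq <- function(path, stranded = FALSE) {
  # structural validation of the 4-line records first: the parser below
  # silently pads a too-short quality string, so length mismatches must be
  # caught at the line level, with the offending record index
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4 != 0)
    abort(paste0("malformed FASTQ in '", path,
                 "': truncated record at end of file"))
  n_rec <- length(lines) / 4
  if (n_rec > 0) {
    hdr <- lines[seq(1, length(lines), by = 4)]
    seq_l <- lines[seq(2, length(lines), by = 4)]
    qual_l <- lines[seq(4, length(lines), by = 4)]
    bad <- which(!startsWith(hdr, "@") | nchar(seq_l) != nchar(qual_l) |
                   nchar(seq_l) == 0)
    if (length(bad))
      abort(paste0("malformed FASTQ in '", path, "': record ", bad[1]))
  } else {
    return(tibble(id = character(), sequence = character(),
                  quality = character(), stranded = logical(),
                  multiplicity = integer()))
  }
  tryCatch(suppressWarnings({
    x <- Biostrings::readQualityScaledDNAStringSet(path)
    tibble(
      id = unname(sub("\\s.*$", "", names(x))),
      sequence = unname(toupper(as.character(x))),
      quality = unname(as.character(Biostrings::quality(x))),
      stranded = stranded,
      multiplicity = 1L
    )
  }), error = function(e) {
    abort(paste0("malformed FASTQ in '", path, "': ", conditionMessage(e)))
  })
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file, plain or gzip.
#' @return A tibble with columns `id` and `sequence` (uppercased, line
#'   wrapping removed).
#' @export
read_fasta <- function(path) {
  x <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("malformed FASTA in '", path, "': ", conditionMessage(e)))
    }
  )
  tibble(
    id = unname(sub("\\s.*$", "", names(x))),
    sequence = unname(toupper(as.character(x)))
  )
}

#' Write sequences to FASTA, dropping short contigs
#'
#' Contigs below `min_length` are not written; the default mirrors the
#' pipeline's convention of reporting only contigs of at least 100 bp.
#'
#' @param x A tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @param min_length Minimum sequence length to write (inclusive).
#' @return Invisibly, the number of records written.
#' @export
write_fasta <- function(x, path, min_length = 100L) {
  keep <- x[nchar(x$sequence) >= min_length, , drop = FALSE]
  set <- Biostrings::BStringSet(keep$sequence)
  names(set) <- keep$id
  Biostrings::writeXStringSet(set, path)
  invisible(nrow(keep))
}

#' Write reads to FASTQ
#'
#' @param reads Read tibble (`id`, `sequence`, `quality`).
#' @param path Output path.
#' @return Invisibly, the number of records written.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$quality
  if (is.null(qual) || anyNA(qual)) {
    qual <- strrep("I", nchar(reads$sequence))
  }
  set <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(unname(reads$sequence)),
    Biostrings::PhredQuality(unname(qual))
  )
  names(set) <- reads$id
  suppressWarnings(Biostrings::writeQualityScaledXStringSet(set, path))
  invisible(nrow(reads))
}

#' Read gene models from a GFF3 file
#'
#' Extracts features of one type (by default `gene`) and converts their
#' coordinates from GFF's 1-based closed convention to the 0-based half-open
#' convention used internally, so that `end - start` is the gene length.
#'
#' @param path Path to a GFF3 file, plain or gzip.
#' @param feature_type Feature type to extract (GFF column 3).
#' @return A tibble of gene models: `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (0-based half-open).
#' @export
read_gff <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(seq_along(gr))
  ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
  tibble(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Write gene models to GFF3
#'
#' @param genes Gene model tibble as returned by [read_gff()].
#' @param path Output path.
#' @param source Value for the GFF source column.
#' @return Invisibly, `path`.
#' @export
write_gff <- function(genes, path, source = "denovotx") {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$source <- source
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Reverse-complement DNA sequences
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  cpp_revcomp(as.character(x))
}

# internal: empty contig tibble with the canonical columns
new_contig_tbl <- function(id = character(), sequence = character(),
                           provenance = character(), oriented = logical()) {
  tibble(id = id, sequence = sequence, provenance = provenance,
         oriented = oriented)
}
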
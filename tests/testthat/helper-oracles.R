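# Brute-force reference implementations, kept deliberately naive and
# independent of the package's data paths, for oracle-equivalence tests.

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# nested-loop k-mer counting
oracle_count_kmers <- function(seqs, mult, k, weighted = FALSE,
                               canonical = FALSE) {
  tab <- new.env()
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    w <- if (weighted) mult[i] else 1
    if (nchar(s) < k) next
    for (p in 1:(nchar(s) - k + 1)) {
      km <- substr(s, p, p + k - 1)
      if (grepl("[^ACGT]", km)) next
      if (canonical) km <- min(km, oracle_revcomp(km))
      tab[[km]] <- (if (is.null(tab[[km]])) 0 else tab[[km]]) + w
    }
  }
  keys <- sort(ls(tab))
  data.frame(kmer = keys,
             count = vapply(keys, function(k) tab[[k]], numeric(1)),
             row.names = NULL)
}

# per-read every-k-mer check against a count table
oracle_keep_reads <- function(seqs, counts, k, min_count) {
  lookup <- stats::setNames(counts$count, counts$kmer)
  vapply(seqs, function(s) {
    if (nchar(s) < k) return(TRUE)
    for (p in 1:(nchar(s) - k + 1)) {
      km <- substr(s, p, p + k - 1)
      if (grepl("[^ACGT]", km)) next
      c <- lookup[km]
      if (is.na(c) || c < min_count) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

# per-base pileup of gapless hits (hits: contig index, 0-based pos, strand)
oracle_pileup_total <- function(contig_len, hits, read_len) {
  depth <- integer(contig_len)
  for (h in seq_len(nrow(hits))) {
    idx <- (hits$pos[h] + 1):(hits$pos[h] + read_len)
    depth[idx] <- depth[idx] + 1L
  }
  depth
}

# per-base marking of gene coverage from alignment block tables
oracle_gene_covered_frac <- function(gene_start, gene_end, block_ts,
                                     block_te) {
  len <- gene_end - gene_start
  marked <- logical(len)
  for (b in seq_along(block_ts)) {
    s <- max(block_ts[b], gene_start)
    e <- min(block_te[b], gene_end)
    if (e > s) marked[(s - gene_start + 1):(e - gene_start)] <- TRUE
  }
  mean(marked)
}

# all-pairs exact containment (either orientation)
oracle_contained <- function(seqs) {
  n <- length(seqs)
  out <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      longer <- nchar(seqs[j]) > nchar(seqs[i]) ||
        (nchar(seqs[j]) == nchar(seqs[i]) && j < i)
      if (!longer) next
      if (grepl(seqs[i], seqs[j], fixed = TRUE) ||
          grepl(oracle_revcomp(seqs[i]), seqs[j], fixed = TRUE))
        out[i] <- TRUE
    }
  }
  out
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# reads tiling a transcript at the given depth: every start position is
# covered once (so error-free recovery is exact), the rest drawn uniformly
tile_reads <- function(tx, depth, read_len, prefix = "r", stranded = TRUE) {
  L <- nchar(tx)
  n <- max(L - read_len + 1L, round(depth * L / read_len))
  starts <- c(seq_len(L - read_len + 1L),
              sample.int(L - read_len + 1L, n - (L - read_len + 1L),
                         replace = TRUE))
  tibble::tibble(
    id = paste0(prefix, seq_len(n)),
    sequence = substring(tx, starts, starts + read_len - 1L),
    quality = strrep("I", read_len),
    stranded = stranded,
    multiplicity = 1L
  )
}
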
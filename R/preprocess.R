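#' Collapse identical reads into one representative
#'
#' Exact-sequence dereplication: reads with byte-identical sequences (no
#' reverse-complement collapsing) are consolidated into a single
#' representative carrying the number of collapsed reads in `multiplicity`.
#' The representative keeps the first-seen read's id, stranded flag and
#' quality, and output order is order of first appearance.
#'
#' @param reads Read tibble ([read_fastq()] columns).
#' @return Read tibble of unique sequences; `sum(multiplicity)` equals the
#'   total input multiplicity.
#' @export
dereplicate <- function(reads) {
  if (nrow(reads) == 0) return(reads)
  mult <- if ("multiplicity" %in% names(reads)) reads$multiplicity else
    rep(1L, nrow(reads))
  first <- !duplicated(reads$sequence)
  total <- rowsum(as.integer(mult), reads$sequence, reorder = FALSE)
  out <- reads[first, , drop = FALSE]
  out$multiplicity <- as.integer(total[, 1])
  out
}

#' Count k-mers across a read set
#'
#' Tallies every k-length substring of every read. With `weighted = FALSE`
#' each read contributes each k-mer position once; with `weighted = TRUE`
#' contributions are multiplied by the read's multiplicity. K-mers containing
#' `N` are never counted, and reads shorter than `k` contribute nothing.
#'
#' @param reads Read tibble.
#' @param k K-mer length (>= 1).
#' @param weighted Multiply contributions by read multiplicity?
#' @param canonical Collapse each k-mer with its reverse complement onto the
#'   lexicographically smaller of the two? Off by default because stranded
#'   libraries make forward and reverse k-mers biologically distinct.
#' @return A tibble `kmer`, `count`, sorted by k-mer, with attributes `k`,
#'   `weighted`, `canonical`.
#' @export
count_kmers <- function(reads, k, weighted = FALSE, canonical = FALSE) {
  stopifnot(k >= 1)
  mult <- if ("multiplicity" %in% names(reads)) as.integer(reads$multiplicity)
          else rep(1L, nrow(reads))
  res <- cpp_count_kmers(reads$sequence, mult, as.integer(k), weighted,
                         canonical)
  out <- tibble(kmer = res$kmer, count = as.numeric(res$count))
  attr(out, "k") <- as.integer(k)
  attr(out, "weighted") <- weighted
  attr(out, "canonical") <- canonical
  out
}

#' Drop reads containing rare k-mers
#'
#' A k-mer is rare when it occurs fewer than `min_count` times in the
#' counting source (by default fewer than three times); such k-mers are
#' treated as likely sequencing errors. A read is kept iff every one of its
#' N-free k-mers reaches `min_count`. Reads shorter than `k` carry no k-mer
#' evidence and are kept (set `drop_short = TRUE` to drop them instead).
#'
#' @param reads Read tibble.
#' @param counts K-mer count table from [count_kmers()].
#' @param min_count Minimum k-mer count for a read to survive.
#' @param drop_short Drop reads shorter than `k`?
#' @return The kept reads, with attribute `dropped_count` (number of read
#'   records removed).
#' @export
filter_rare_kmer_reads <- function(reads, counts, min_count = 3,
                                   drop_short = FALSE) {
  k <- attr(counts, "k")
  canonical <- isTRUE(attr(counts, "canonical"))
  if (is.null(k)) abort("`counts` must come from count_kmers()")
  keep <- cpp_filter_reads(reads$sequence, counts$kmer, counts$count,
                           as.integer(k), min_count, canonical, drop_short)
  out <- reads[keep, , drop = FALSE]
  attr(out, "dropped_count") <- sum(!keep)
  out
}

#' Dereplicate and rare-k-mer-filter a read pool
#'
#' Runs one of three preprocessing strategies. The order of the two steps is
#' significant: a k-mer is more likely to fall below the rarity threshold
#' after duplicate removal than before.
#'
#' * `"none"` - dereplicate only, no filter.
#' * `"derep_then_filter"` - dereplicate, count k-mers unweighted over the
#'   unique reads, then filter (rarity judged "in the set of unique reads").
#' * `"filter_then_derep"` - count k-mers over the raw reads (weighted by
#'   multiplicity, since duplicates are still present), filter, then
#'   dereplicate.
#'
#' Pools are processed independently per `stranded` flag so consolidation
#' never collapses reads across library protocols.
#'
#' @param reads Read tibble.
#' @param strategy One of `"derep_then_filter"`, `"filter_then_derep"`,
#'   `"none"`.
#' @param k Filter k-mer length. A k-mer is contained in `read_len - k + 1`
#'   read placements, so the rarity rule needs roughly `3 * read_len /
#'   (read_len - k + 1)` unique-read depth to be satisfiable; the default 13
#'   (about 0.4x a 34 bp read) keeps weakly expressed transcripts above that
#'   bar while staying far too long for chance k-mer collisions.
#' @param min_count Rarity threshold (a k-mer seen fewer than this many times
#'   is rare).
#' @param canonical Canonicalize k-mers with their reverse complements when
#'   counting filter support? The default `"auto"` canonicalizes whenever the
#'   read set contains non-stranded reads: those arrive in random
#'   orientation, so a k-mer and its reverse complement are the same
#'   evidence. For a purely stranded pool the default keeps orientations
#'   distinct. Pass `TRUE`/`FALSE` to force.
#' @return Tibble of surviving unique reads, with attribute `stats`: a list
#'   with `n_in`, `n_unique`, `n_filtered_out`, `n_out`.
#' @export
preprocess_reads <- function(reads,
                             strategy = c("derep_then_filter",
                                          "filter_then_derep", "none"),
                             k = 13, min_count = 3, canonical = "auto") {
  strategy <- match.arg(strategy)
  if (identical(canonical, "auto"))
    canonical <- "stranded" %in% names(reads) && any(!reads$stranded)
  # dereplication is per strandedness pool, so consolidation never collapses
  # reads across library protocols; k-mer counting pools all evidence
  derep_pools <- function(x) {
    if ("stranded" %in% names(x)) bind_rows(lapply(split(x, x$stranded),
                                                   dereplicate))
    else dereplicate(x)
  }
  n_in <- nrow(reads)
  if (strategy == "none") {
    res <- derep_pools(reads)
    attr(res, "stats") <- list(n_in = n_in, n_unique = nrow(res),
                               n_filtered_out = 0L, n_out = nrow(res))
    return(res)
  }
  if (strategy == "derep_then_filter") {
    u <- derep_pools(reads)
    n_unique <- nrow(u)
    tab <- count_kmers(u, k, weighted = FALSE, canonical = canonical)
    res <- filter_rare_kmer_reads(u, tab, min_count)
    n_filtered <- attr(res, "dropped_count")
  } else {
    tab <- count_kmers(reads, k, weighted = TRUE, canonical = canonical)
    kept <- filter_rare_kmer_reads(reads, tab, min_count)
    n_filtered <- attr(kept, "dropped_count")
    res <- derep_pools(kept)
    n_unique <- nrow(res)
  }
  attr(res, "stats") <- list(n_in = n_in, n_unique = n_unique,
                             n_filtered_out = n_filtered, n_out = nrow(res))
  res
}
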
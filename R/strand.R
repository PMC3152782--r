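#' Map reads back to contigs and build stranded pileups
#'
#' Gapless exact-seed-and-extend alignment of every read against the contig
#' set, allowing up to `max_mismatches` substitutions. Each read is placed at
#' its unique best position; reads with several equal-best placements
#' (multi-mappers) are discarded from both the hit list and the coverage, so
#' paralog cross-talk cannot contaminate the strand evidence. A hit's strand
#' is `+` when the read sequence matches the contig forward and `-` when its
#' reverse complement does. Forward/reverse per-base coverage is accumulated
#' from reads flagged `stranded` only; total depth and A/C/G/T base counts
#' use all mapped reads. Each mapped read contributes once, regardless of
#' its dereplication multiplicity.
#'
#' @param reads Read tibble.
#' @param contigs Contig tibble.
#' @param seed_k Exact seed length (must not exceed the shortest read).
#' @param max_mismatches Maximum substitutions in a full-length placement.
#' @return An object of class `read_mapping`: list with
#'   * `hits`: tibble `read_id`, `contig_id`, `pos` (0-based), `strand`,
#'     `mismatches`;
#'   * `coverage`: tibble `contig_id`, `pos` (0-based), `fwd`, `rev`, `total`;
#'   * `base_counts`: tibble `contig_id`, `pos`, `A`, `C`, `G`, `T`;
#'   * `n_ambiguous`, `n_unmapped`: read counts.
#' @export
map_reads <- function(reads, contigs, seed_k = 17, max_mismatches = 2) {
  if (nrow(reads) > 0 && seed_k > min(nchar(reads$sequence)))
    warn("seed_k exceeds the shortest read; such reads cannot be mapped")
  m <- cpp_map_reads(reads$sequence, contigs$sequence, as.integer(seed_k),
                     as.integer(max_mismatches))
  stranded <- if ("stranded" %in% names(reads)) reads$stranded
              else rep(FALSE, nrow(reads))
  lens <- nchar(contigs$sequence)
  pil <- cpp_pileup(as.integer(lens), m$read, m$contig, m$pos, m$strand,
                    reads$sequence, stranded)
  cov <- bind_rows(lapply(seq_along(pil), function(c) {
    tibble(contig_id = contigs$id[c], pos = seq_len(lens[c]) - 1L,
           fwd = pil[[c]]$fwd, rev = pil[[c]]$rev, total = pil[[c]]$total)
  }))
  bc <- bind_rows(lapply(seq_along(pil), function(c) {
    b <- pil[[c]]$bases
    tibble(contig_id = contigs$id[c], pos = seq_len(lens[c]) - 1L,
           A = b[, 1], C = b[, 2], G = b[, 3], T = b[, 4])
  }))
  structure(
    list(
      hits = tibble(
        read_id = reads$id[m$read], contig_id = contigs$id[m$contig],
        pos = m$pos, strand = ifelse(m$strand > 0, "+", "-"),
        mismatches = m$mismatches
      ),
      coverage = cov, base_counts = bc,
      n_ambiguous = m$n_ambiguous, n_unmapped = m$n_unmapped
    ),
    class = "read_mapping"
  )
}

#' @export
print.read_mapping <- function(x, ...) {
  cat("read mapping:", nrow(x$hits), "hits on",
      length(unique(x$coverage$contig_id)), "contigs |",
      x$n_ambiguous, "ambiguous,", x$n_unmapped, "unmapped\n")
  invisible(x)
}

# attach per-contig pileup slices (fwd/rev/total vectors, bases matrix) as
# list-columns so splits can carry their coverage along
.attach_pileup <- function(contigs, mapping) {
  if (all(c("fwd", "rev", "total", "bases") %in% names(contigs)))
    return(contigs)
  cov <- split(mapping$coverage, mapping$coverage$contig_id)
  bcs <- split(mapping$base_counts, mapping$base_counts$contig_id)
  contigs$fwd <- lapply(contigs$id, function(i) cov[[i]]$fwd)
  contigs$rev <- lapply(contigs$id, function(i) cov[[i]]$rev)
  contigs$total <- lapply(contigs$id, function(i) cov[[i]]$total)
  contigs$bases <- lapply(contigs$id, function(i)
    as.matrix(bcs[[i]][, c("A", "C", "G", "T")]))
  contigs
}

# slice one annotated contig row into [s, e) fragments (0-based half-open)
.slice_contig <- function(row, starts, ends, suffixes, reason) {
  bind_rows(lapply(seq_along(starts), function(x) {
    s <- starts[x]; e <- ends[x]
    out <- row
    out$id <- paste0(row$id, suffixes[x])
    out$sequence <- substr(row$sequence, s + 1, e)
    out$provenance <- paste0(row$provenance, ";", reason, "[", s, ",", e, ")")
    if (!is.null(row$fwd[[1]])) {
      out$fwd <- list(row$fwd[[1]][(s + 1):e])
      out$rev <- list(row$rev[[1]][(s + 1):e])
      out$total <- list(row$total[[1]][(s + 1):e])
      out$bases <- list(row$bases[[1]][(s + 1):e, , drop = FALSE])
    }
    out
  }))
}

#' Split contigs at long unsupported stretches
#'
#' Excises maximal runs of positions where the total mapped-read depth falls
#' below `min_reads`, when the run is strictly longer than one read length -
#' the signature of distinct transcripts glued together without read support.
#' Flanking fragments become separate contigs; fragments shorter than
#' `min_fragment_length` are dropped. Cut positions are recorded in the
#' provenance.
#'
#' @param contigs Contig tibble that was passed to [map_reads()].
#' @param mapping The [map_reads()] result for those contigs.
#' @param min_reads Depth threshold: positions with `total < min_reads` are
#'   unsupported.
#' @param read_length One read length; runs must exceed this to trigger a
#'   split.
#' @param min_fragment_length Fragments shorter than this are discarded.
#' @return Contig tibble of fragments, with pileup slices attached as
#'   list-columns (`fwd`, `rev`, `total`, `bases`).
#' @export
split_low_coverage <- function(contigs, mapping, min_reads = 3, read_length,
                               min_fragment_length = 100) {
  ann <- .attach_pileup(contigs, mapping)
  out <- lapply(seq_len(nrow(ann)), function(r) {
    row <- ann[r, , drop = FALSE]
    tot <- row$total[[1]]
    L <- length(tot)
    low <- tot < min_reads
    rl <- rle(low)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths  # 0-based
    cut <- rl$values & rl$lengths > read_length
    if (!any(cut)) return(row)
    keep_s <- integer(); keep_e <- integer()
    pos <- 0L
    for (x in seq_along(rl$lengths)) {
      if (!cut[x]) next
      if (starts[x] > pos) { keep_s <- c(keep_s, pos); keep_e <- c(keep_e, starts[x]) }
      pos <- ends[x]
    }
    if (pos < L) { keep_s <- c(keep_s, pos); keep_e <- c(keep_e, L) }
    if (length(keep_s) == 0) return(NULL)
    frag <- .slice_contig(row, keep_s, keep_e,
                          paste0(".", seq_along(keep_s)), "lowcov")
    frag[nchar(frag$sequence) >= min_fragment_length, , drop = FALSE]
  })
  bind_rows(out[!vapply(out, is.null, logical(1))])
}

# classify each position as fwd / rev / mixed from smoothed stranded
# coverage; zero-coverage positions inherit the nearest classified neighbor
.classify_strand <- function(fwd, rev, window, purity) {
  L <- length(fwd)
  half <- floor(window / 2)
  run <- function(x) {
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(L) - half, 1L)
    hi <- pmin(seq_len(L) + half, L)
    cs[hi + 1] - cs[lo]
  }
  f <- run(fwd); r <- run(rev)
  tot <- f + r
  cl <- rep(NA_character_, L)
  has <- tot > 0
  frac <- ifelse(has, f / tot, NA_real_)
  cl[has & frac >= purity] <- "fwd"
  cl[has & frac <= 1 - purity] <- "rev"
  cl[has & is.na(cl)] <- "mixed"
  if (!any(has)) return(cl)
  if (any(is.na(cl))) {
    idx <- which(!is.na(cl))
    nas <- which(is.na(cl))
    # nearest classified neighbor, ties to the left
    left <- idx[findInterval(nas, idx)]
    right_pos <- findInterval(nas, idx) + 1L
    right <- ifelse(right_pos <= length(idx), idx[pmin(right_pos, length(idx))],
                    NA_integer_)
    pick <- ifelse(is.na(left), right,
                   ifelse(is.na(right), left,
                          ifelse(nas - left <= right - nas, left, right)))
    cl[nas] <- cl[pick]
  }
  cl
}

#' Split contigs at strandness transitions
#'
#' Classifies every position from the stranded forward/reverse coverage
#' (smoothed over `window` bp) as forward-dominated (forward fraction >=
#' `purity`), reverse-dominated, or mixed, then emits per-strand contigs:
#' maximal runs of forward-or-mixed positions become `+` contigs and maximal
#' runs of reverse-or-mixed positions become `-` contigs. A mixed stretch -
#' reads from both orientations, indicating overlapping antisense
#' transcripts - is therefore retained on both strands and stays attached to
#' its adjacent same-strand segments, so each strand's transcript remains
#' contiguous. The transition point between a pure forward and pure reverse
#' stretch is the boundary of adjacent transcripts and becomes a cut.
#' Contigs with no stranded coverage at all are passed through with
#' `strand = NA`.
#'
#' @inheritParams split_low_coverage
#' @param window Smoothing window (bp) for the purity classification.
#' @param purity Forward-fraction threshold for calling a position
#'   strand-pure.
#' @return Contig tibble of per-strand fragments with a `strand` column
#'   (`"+"`, `"-"`, or `NA`).
#' @export
split_strand_transitions <- function(contigs, mapping, window = 50,
                                     purity = 0.9) {
  ann <- .attach_pileup(contigs, mapping)
  out <- lapply(seq_len(nrow(ann)), function(r) {
    row <- ann[r, , drop = FALSE]
    cl <- .classify_strand(row$fwd[[1]], row$rev[[1]], window, purity)
    if (all(is.na(cl))) {
      row$strand <- NA_character_
      return(row)
    }
    frags <- list()
    for (side in c("+", "-")) {
      want <- if (side == "+") c("fwd", "mixed") else c("rev", "mixed")
      inside <- cl %in% want
      rl <- rle(inside)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths
      for (x in seq_along(rl$lengths)) {
        if (!rl$values[x]) next
        # an all-mixed run flanked by the opposite strand is still emitted
        # on this side: both strands of an antisense overlap are retained
        fr <- .slice_contig(row, starts[x], ends[x],
                            paste0(if (side == "+") ".p" else ".m",
                                   length(frags) + 1L),
                            paste0("strand", side))
        fr$strand <- side
        frags[[length(frags) + 1L]] <- fr
      }
    }
    bind_rows(frags)
  })
  bind_rows(out)
}

#' Orient contigs to the mRNA sense strand
#'
#' Fragments assigned strand `-` are reverse-complemented (their pileup
#' slices are flipped accordingly) so every stranded contig reads in mRNA
#' sense orientation; `oriented` is set to `TRUE`. Fragments with no strand
#' evidence keep their assembly orientation with `oriented = FALSE`.
#'
#' @param contigs Contig tibble with a `strand` column, as produced by
#'   [split_strand_transitions()].
#' @return The contigs, oriented.
#' @export
orient_contigs <- function(contigs) {
  if (!"strand" %in% names(contigs))
    abort("orient_contigs() needs the `strand` column from split_strand_transitions()")
  if (nrow(contigs) == 0) return(contigs)
  neg <- !is.na(contigs$strand) & contigs$strand == "-"
  contigs$sequence[neg] <- revcomp(contigs$sequence[neg])
  has_pile <- "bases" %in% names(contigs)
  if (has_pile && any(neg)) {
    for (r in which(neg)) {
      f <- contigs$fwd[[r]]; v <- contigs$rev[[r]]
      contigs$fwd[[r]] <- base::rev(v)
      contigs$rev[[r]] <- base::rev(f)
      contigs$total[[r]] <- base::rev(contigs$total[[r]])
      b <- contigs$bases[[r]]
      contigs$bases[[r]] <- b[base::rev(seq_len(nrow(b))), c(4, 3, 2, 1),
                              drop = FALSE]
    }
  }
  if (has_pile && any(neg))
    for (r in which(neg)) colnames(contigs$bases[[r]]) <- c("A", "C", "G", "T")
  contigs$oriented <- !is.na(contigs$strand)
  contigs
}

#' Polish contigs to the read consensus
#'
#' At every position with mapped-read depth of at least `min_depth`, the
#' contig base is replaced by the plurality base of the A/C/G/T counts from
#' the aligned reads. Ties and positions below `min_depth` keep the original
#' base; the correction is substitution-only, so contig length never
#' changes.
#'
#' @param contigs Contig tibble carrying `bases` pileup list-columns (from
#'   the split/orient steps, or [map_reads()] via `.attach_pileup`).
#' @param mapping Optional [map_reads()] result, used when `contigs` lacks
#'   pileup columns.
#' @param min_depth Minimum depth to trust the consensus.
#' @return The polished contigs, with attribute `n_corrections`.
#' @export
polish_contigs <- function(contigs, mapping = NULL, min_depth = 3) {
  if (!"bases" %in% names(contigs)) {
    if (is.null(mapping)) abort("polish_contigs() needs base counts")
    contigs <- .attach_pileup(contigs, mapping)
  }
  letters4 <- c("A", "C", "G", "T")
  n_corr <- 0L
  for (r in seq_len(nrow(contigs))) {
    b <- contigs$bases[[r]]
    depth <- rowSums(b)
    mx <- pmax(b[, 1], b[, 2], b[, 3], b[, 4])
    n_at_max <- rowSums(b == mx)
    maj <- letters4[max.col(b, ties.method = "first")]
    orig <- strsplit(contigs$sequence[r], "")[[1]]
    fix <- depth >= min_depth & n_at_max == 1 & maj != orig & mx > 0
    if (any(fix)) {
      orig[fix] <- maj[fix]
      contigs$sequence[r] <- paste(orig, collapse = "")
      n_corr <- n_corr + sum(fix)
    }
  }
  attr(contigs, "n_corrections") <- n_corr
  contigs
}
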
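#' Remove duplicate and contained contigs
#'
#' Drops exact duplicates, exact reverse-complement duplicates, and contigs
#' contained (as an exact substring, in either orientation) in a longer
#' contig, keeping the longest representative. Ties between equal-length
#' duplicates are broken by lexicographic id, so the result is deterministic.
#'
#' @param contigs Contig tibble (`id`, `sequence`, ...).
#' @return The surviving contigs, input order preserved.
#' @export
remove_duplicate_contigs <- function(contigs, anchor_k = 16L) {
  n <- nrow(contigs)
  if (n <= 1) return(contigs)
  pr <- cpp_containment_pairs(contigs$sequence, as.integer(anchor_k))
  if (length(pr$i) == 0) return(contigs)
  len <- nchar(contigs$sequence)
  id <- contigs$id
  dominated <- rep(FALSE, n)
  ci <- pr$i; cj <- pr$j
  dom <- len[cj] > len[ci] | (len[cj] == len[ci] & id[cj] < id[ci])
  dominated[unique(ci[dom])] <- TRUE
  contigs[!dominated, , drop = FALSE]
}

#' Find dovetail overlaps between contigs
#'
#' Reports suffix-prefix overlaps: the suffix of contig `i` (in its given
#' orientation) matching the prefix of contig `j`, with `j` taken forward
#' (`orientation == "+"`) or reverse-complemented (`"-"`). Overlaps must be
#' at least `min_overlap` long with `identity = matches / overlap_len >=
#' min_identity`. Candidates are anchored on exact 16-mers at the joining
#' ends, so an overlap whose terminal 16 bp on both ends are error-ridden can
#' be missed; near-identical multi-k contigs are unaffected.
#'
#' @param contigs Contig tibble.
#' @param min_overlap Minimum overlap length (bp).
#' @param min_identity Minimum overlap identity in `[0, 1]`.
#' @return Tibble: `i`, `j` (row indices), `id_i`, `id_j`, `orientation`,
#'   `overlap_len`, `matches`, `identity`.
#' @export
find_overlaps <- function(contigs, min_overlap = 40, min_identity = 0.94) {
  stopifnot(min_overlap >= 8, min_identity >= 0, min_identity <= 1)
  res <- cpp_find_overlaps(contigs$sequence, as.integer(min_overlap),
                           min_identity, as.integer(min(16, min_overlap)))
  tibble(
    i = res$i, j = res$j,
    id_i = contigs$id[res$i], id_j = contigs$id[res$j],
    orientation = ifelse(res$orient == 0, "+", "-"),
    overlap_len = res$overlap_len,
    matches = res$matches,
    identity = res$identity
  )
}

# weight of a contig for junction consensus: number of source assemblies
# recorded in its provenance
.provenance_weight <- function(provenance) {
  lengths(strsplit(ifelse(is.na(provenance), "", provenance), "+", fixed = TRUE))
}

.merge_provenance <- function(provs) {
  parts <- unique(unlist(strsplit(provs[!is.na(provs)], "+", fixed = TRUE)))
  if (length(parts) == 0) NA_character_ else paste(sort(parts), collapse = "+")
}

# one greedy layout pass: consume overlaps in order of (overlap_len,
# identity) descending, building chains of oriented contigs; returns the
# merged contig tibble
.merge_pass <- function(contigs, min_overlap, min_identity) {
  ov <- find_overlaps(contigs, min_overlap, min_identity)
  if (nrow(ov) == 0) return(list(contigs = contigs, merged = 0L))
  ov <- dplyr::arrange(ov, desc(.data$overlap_len), desc(.data$identity),
                       .data$id_i, .data$id_j, .data$orientation)
  n <- nrow(contigs)
  # each contig starts as its own chain: members (indices), orients, juncs
  chains <- lapply(seq_len(n), function(i) {
    list(members = i, orients = "+", juncs = integer())
  })
  chain_of <- seq_len(n)
  flip <- function(ch) {
    list(members = rev(ch$members),
         orients = rev(ifelse(ch$orients == "+", "-", "+")),
         juncs = rev(ch$juncs))
  }
  n_merged <- 0L
  for (r in seq_len(nrow(ov))) {
    i <- ov$i[r]; j <- ov$j[r]; o <- ov$orientation[r]
    ci <- chain_of[i]; cj <- chain_of[j]
    if (ci == cj) next  # cycle guard
    A <- chains[[ci]]; B <- chains[[cj]]
    # expose i's forward right end at the right end of A
    ia <- match(i, A$members)
    if (ia == length(A$members) && A$orients[ia] == "+") {
      # ok
    } else if (ia == 1 && A$orients[ia] == "-") {
      A <- flip(A)
    } else next
    # expose j's o-oriented left end at the left end of B
    jb <- match(j, B$members)
    if (jb == 1 && B$orients[jb] == o) {
      # ok
    } else if (jb == length(B$members) &&
               B$orients[jb] == (if (o == "+") "-" else "+")) {
      B <- flip(B)
    } else next
    merged <- list(
      members = c(A$members, B$members),
      orients = c(A$orients, B$orients),
      juncs = c(A$juncs, ov$overlap_len[r], B$juncs)
    )
    chains[[ci]] <- merged
    chains[[cj]] <- list(members = integer(), orients = character(),
                         juncs = integer())
    chain_of[merged$members] <- ci
    n_merged <- n_merged + 1L
  }
  if (n_merged == 0L) return(list(contigs = contigs, merged = 0L))
  w <- .provenance_weight(contigs$provenance)
  out <- lapply(chains, function(ch) {
    m <- length(ch$members)
    if (m == 0) return(NULL)
    if (m == 1) return(contigs[ch$members, , drop = FALSE])
    seqs <- contigs$sequence[ch$members]
    flip_it <- ch$orients == "-"
    seqs[flip_it] <- revcomp(seqs[flip_it])
    acc <- seqs[1]
    acc_w <- w[ch$members[1]]
    for (x in 2:m) {
      ovl <- ch$juncs[x - 1]
      wx <- w[ch$members[x]]
      if (wx > acc_w) {
        # incoming contig's bases win the overlapping columns
        acc <- paste0(substr(acc, 1, nchar(acc) - ovl), seqs[x])
      } else {
        acc <- paste0(acc, substr(seqs[x], ovl + 1, nchar(seqs[x])))
      }
      acc_w <- max(acc_w, wx)
    }
    tibble(
      id = sprintf("%s.m%d", contigs$id[ch$members[1]], m),
      sequence = acc,
      mean_cov = if ("mean_cov" %in% names(contigs))
        mean(contigs$mean_cov[ch$members]) else NA_real_,
      provenance = .merge_provenance(contigs$provenance[ch$members]),
      oriented = FALSE
    )
  })
  res <- bind_rows(out[!vapply(out, is.null, logical(1))])
  list(contigs = res, merged = n_merged)
}

#' Merge multi-k contig pools into a non-redundant assembly
#'
#' Duplicate and contained contigs are removed, then dovetail overlaps are
#' consumed greedily in order of decreasing (overlap length, identity),
#' chaining contigs end to end; at each junction the overlapping columns take
#' the bases of the contig supported by more source assemblies (ties keep the
#' incumbent). An overlap that would merge a contig with itself, or re-join
#' two already-joined chains, is skipped. Passes repeat until no qualifying
#' overlap remains.
#'
#' @param contigs Contig tibble (typically the pooled [multi_k_assemble()]
#'   output).
#' @param min_overlap Minimum dovetail overlap (bp).
#' @param min_identity Minimum overlap identity.
#' @param max_rounds Safety cap on merge passes.
#' @return Merged contig tibble, sorted by decreasing length then sequence.
#' @export
merge_contigs <- function(contigs, min_overlap = 40, min_identity = 0.94,
                          max_rounds = 10L) {
  cur <- remove_duplicate_contigs(contigs)
  for (round in seq_len(max_rounds)) {
    res <- .merge_pass(cur, min_overlap, min_identity)
    cur <- remove_duplicate_contigs(res$contigs)
    if (res$merged == 0L) break
  }
  dplyr::arrange(cur, desc(nchar(.data$sequence)), .data$sequence)
}
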
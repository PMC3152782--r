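#' Build a de Bruijn graph from reads
#'
#' Nodes are (k-1)-mers; each observed k-mer is an edge from its prefix node
#' to its suffix node, with a count equal to its weighted number of
#' occurrences (read multiplicity included). K-mers containing `N` are
#' skipped, as are reads shorter than `k`. With `both_strands = TRUE`
#' (the default, for pools mixing read orientations) every k-mer is inserted
#' together with its reverse complement, so the graph is strand-symmetric
#' and strand assignment can happen downstream from stranded coverage.
#'
#' @param reads Read tibble.
#' @param k Odd hash length, >= 3.
#' @param both_strands Insert reverse-complement k-mers too?
#' @return An object of class `dbg`: list with `k`, `both_strands`, and
#'   `edges` (tibble `kmer`, `count`, lexicographically sorted).
#' @export
build_graph <- function(reads, k, both_strands = TRUE) {
  stopifnot(k >= 3)
  if (k %% 2 == 0) warn("even k: de Bruijn hash lengths are usually odd")
  if (nrow(reads) > 0 && k > min(nchar(reads$sequence)))
    warn("k exceeds the shortest read length; short reads contribute nothing")
  mult <- if ("multiplicity" %in% names(reads)) as.integer(reads$multiplicity)
          else rep(1L, nrow(reads))
  res <- cpp_build_graph(reads$sequence, mult, as.integer(k), both_strands)
  structure(
    list(k = as.integer(k), both_strands = both_strands,
         edges = tibble(kmer = res$kmer, count = as.numeric(res$count))),
    class = "dbg"
  )
}

#' @export
print.dbg <- function(x, ...) {
  cat("de Bruijn graph: k =", x$k, "|", nrow(x$edges), "edges (k-mers) |",
      if (x$both_strands) "double-stranded" else "single-stranded", "\n")
  invisible(x)
}

#' Clip low-coverage tips from a de Bruijn graph
#'
#' Removes dead-end branches of at most `max_tip_len` edges whose mean
#' coverage is strictly below the strongest competing branch at their fork -
#' the usual signature of sequencing errors near read ends. Iterates until no
#' further tip qualifies, so the operation is idempotent.
#'
#' @param graph A `dbg` object.
#' @param max_tip_len Maximum tip length in edges; defaults to `2 * k`, the
#'   conventional clip length.
#' @return A new `dbg` object.
#' @export
clip_tips <- function(graph, max_tip_len = 2 * graph$k) {
  res <- cpp_tip_clip(graph$edges$kmer, graph$edges$count, graph$k,
                      as.integer(max_tip_len))
  structure(
    list(k = graph$k, both_strands = graph$both_strands,
         edges = tibble(kmer = res$kmer, count = as.numeric(res$count))),
    class = "dbg"
  )
}

#' Extract unitigs from a de Bruijn graph
#'
#' A unitig is a maximal non-branching path: it extends while the current
#' node has exactly one outgoing edge and the next node exactly one incoming
#' edge. The unitig sequence has length (number of edges) + k - 1. Unitigs
#' whose mean edge coverage falls below `cov_cutoff` are discarded. On
#' double-stranded graphs each unitig is reported once, in its
#' lexicographically smaller orientation; nodes are processed in
#' lexicographic order, so the output is deterministic.
#'
#' @param graph A `dbg` object.
#' @param cov_cutoff Minimum mean k-mer coverage for a unitig to be reported.
#' @return Contig tibble: `id`, `sequence`, `mean_cov`, `provenance`,
#'   `oriented` (always `FALSE` at this stage).
#' @export
extract_unitigs <- function(graph, cov_cutoff = 1) {
  res <- cpp_extract_unitigs(graph$edges$kmer, graph$edges$count, graph$k,
                             cov_cutoff, graph$both_strands)
  n <- length(res$sequence)
  tibble(
    id = if (n) sprintf("k%d_u%04d", graph$k, seq_len(n)) else character(),
    sequence = res$sequence,
    mean_cov = as.numeric(res$mean_cov),
    provenance = if (n) sprintf("k=%d", graph$k) else character(),
    oriented = rep(FALSE, n)
  )
}

#' Assemble reads at a single hash length
#'
#' Composition of [build_graph()], [clip_tips()] and [extract_unitigs()].
#' Deterministic: identical inputs give identical contigs.
#'
#' @inheritParams build_graph
#' @inheritParams extract_unitigs
#' @param max_tip_len Tip clip length in edges (default `2 * k`).
#' @return Contig tibble tagged with `k` in `provenance`.
#' @export
assemble <- function(reads, k, cov_cutoff = 1, max_tip_len = 2 * k,
                     both_strands = TRUE) {
  g <- build_graph(reads, k, both_strands = both_strands)
  g <- clip_tips(g, max_tip_len = max_tip_len)
  extract_unitigs(g, cov_cutoff = cov_cutoff)
}

#' Assemble reads across a ladder of hash lengths
#'
#' Runs [assemble()] once per k and pools the contigs. Small k joins more
#' (good for low-coverage transcripts), large k resolves repeats; merging
#' the per-k pools downstream recovers contiguity no single k achieves. The
#' default ladder is the eight odd values 19-33. Runs are independent, so
#' the union is identical whatever the execution order.
#'
#' @inheritParams assemble
#' @param k_values Integer vector of hash lengths.
#' @return Contig tibble: union of the per-k assemblies, ids prefixed by k.
#' @export
multi_k_assemble <- function(reads, k_values = seq(19L, 33L, by = 2L),
                             cov_cutoff = 1, both_strands = TRUE) {
  stopifnot(length(k_values) >= 1)
  bind_rows(lapply(sort(as.integer(k_values)), function(k) {
    assemble(reads, k, cov_cutoff = cov_cutoff, both_strands = both_strands)
  }))
}
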
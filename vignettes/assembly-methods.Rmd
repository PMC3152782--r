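---
title: "De novo stranded transcriptome assembly: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De novo stranded transcriptome assembly: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

denovotx assembles transcript contigs from short stranded and non-stranded
RNA-Seq reads without a reference genome. This vignette explains the model
behind each stage, the parameters that matter and why their defaults are
what they are, what the synthetic-data generator emulates, and the known
limitations. Nothing here states an empirical result that the package's
tests and acceptance script do not themselves compute.

## The problem

RNA-Seq coverage spans orders of magnitude across transcripts, reads are
short (tens of bases), libraries carry heavy PCR duplication and per-base
sequencing errors, and neighboring genes on opposite strands frequently
overlap in their UTRs. A single de Bruijn assembly at one k-mer size
handles none of these well: low-k joins repeats and antisense neighbors,
high-k fragments weakly expressed transcripts, duplicated error reads
inflate the graph, and strand-blind graphs fuse overlapping antisense
transcripts into chimeric contigs. The pipeline addresses each failure mode
with a dedicated stage:

1. **Preprocess** — dereplicate reads and drop reads containing rare k-mers.
2. **Assemble** — de Bruijn unitig assembly at a ladder of k values
   (19, 21, ..., 33) with tip clipping and a coverage cutoff.
3. **Merge** — remove duplicate/contained contigs, then greedy dovetail
   overlap layout into a non-redundant set.
4. **Finish** — map reads back; split contigs at unsupported stretches and
   at strandness transitions; orient to mRNA sense; polish a majority-vote
   consensus; drop contigs under 100 bp.
5. **Evaluate** (optional) — accuracy, completeness, contiguity and gene
   fusions against a reference genome and gene catalog.

## Preprocessing

Dereplication collapses byte-identical reads into one representative with a
multiplicity count. It runs independently within the stranded and
non-stranded pools so consolidation can never erase the library-protocol
flag. Identity is exact and orientation-sensitive: a read and its reverse
complement are different molecules of evidence.

The rare k-mer filter drops any read containing a k-mer observed fewer than
`min_count = 3` times. Under the default `derep_then_filter` strategy,
counting is unweighted over the unique reads; under `filter_then_derep` it
runs before dereplication, weighted by (trivial) multiplicity. The order
matters: a k-mer is more likely to fall below the threshold after
duplicates are removed, so filtering after dereplication is strictly more
aggressive — every k-mer's raw weighted count dominates its unique-read
count, which is why the test suite contains a witness for one direction of
disagreement and a dominance property for the other.

Two counting details are easy to get wrong and matter a great deal:

* **Support is pooled.** K-mer counts are taken over the unique reads of
  *both* pools together. Filtering each pool against only its own k-mers
  discards a majority of the available evidence for the minority pool.
* **Support is strand-blind when orientations are mixed.** Non-stranded
  reads arrive in random orientation, so a k-mer and its reverse complement
  are the same evidence; with any non-stranded reads present the filter
  counts canonically (`canonical = "auto"`). For a purely stranded pool
  orientations stay distinct.

**Choice of the filter k (default 13).** A k-mer of length $k$ is contained
in $L_r - k + 1$ read placements for read length $L_r$. Requiring every
k-mer of a read to be seen $\ge 3$ times among unique reads therefore
demands a unique-read depth of roughly $3 L_r / (L_r - k + 1)$. At
$L_r = 34$ and $k = 21$ that is a 14-position window — weakly expressed
transcripts near the bottom of the dynamic range cannot satisfy it and are
silently erased by their own filter. The default $k = 13$ (about
$0.4 L_r$) widens the window to 22 positions, keeping ~20x transcripts
above the bar, while $4^{13} \approx 6.7\times10^7$ remains orders of
magnitude larger than the distinct k-mer count of a desk-scale library, so
chance collisions contribute negligible false support. For longer reads a
proportionally larger filter k is appropriate; the parameter is exposed
everywhere as `filter_k`.

Reads shorter than the filter k carry no k-mer evidence and pass.

## The assembler

Nodes are $(k-1)$-mers, edges are observed k-mers with occurrence counts
(multiplicity-weighted); k-mers containing `N` never enter the graph. By
default the graph is **double-stranded**: each k-mer is inserted along with
its reverse complement, because the read pool mixes orientations and strand
assignment is deferred to the finishing stage, where stranded coverage
provides direct evidence. This is also what lets overlapping antisense
transcripts assemble into one contig that the strand splitter later
separates — the intended route, not an accident.

*Tip clipping* removes dead-end branches of at most `2k` edges whose mean
coverage is strictly below the strongest competing branch at their fork —
the signature of errors near read ends. The operation iterates to
convergence and is idempotent. Bubbles (errors mid-read that reconverge)
are *not* popped; the rare error reads that survive the k-mer filter almost
never have the `k` bases of clean flank on both sides needed to form one.

*Unitigs* are maximal non-branching paths, reported deterministically
(lexicographic node order; on double-stranded graphs each unitig appears
once, in its lexicographically smaller orientation). Unitigs with mean edge
coverage below `cov_cutoff` (default 1) are dropped. Repeat resolution by
expected coverage is deliberately not implemented: the multi-k ladder plus
merging recovers most of the contiguity, and random-sequence yeast-like
transcriptomes have few k-scale repeats.

The ladder (19–33, odd) is run independently per k and pooled. Small k
tolerates thin coverage; large k resolves longer repeats. The union is
deterministic and order-independent, so the per-k runs are trivially
parallelizable.

## Merging

Exact duplicates, reverse-complement duplicates and exactly-contained
contigs are removed first (longest representative wins; ties break by id).
Remaining contigs merge by greedy dovetail layout: suffix–prefix overlaps
of at least `min_overlap = 40` bp at identity $\ge 0.94$, consumed in order
of decreasing (length, identity), chaining contigs end-to-end with a guard
against self-merges and cycles. At each junction the overlapping columns
take the bases of the contig supported by more source-k assemblies. Multi-k
contigs of one transcript are near-identical, so a full multiple-alignment
consensus would add cost without benefit; genuinely divergent overlaps are
a documented limitation of the greedy rule. Overlap detection is anchored
on exact 16-mers at the joining ends, so a dovetail whose terminal 16 bp
are error-ridden on both ends can be missed — irrelevant for the
near-identical overlaps this stage exists to consume.

## Finishing with stranded evidence

Reads are mapped back to the merged contigs with an exact-seed
(`seed_k = 17`) gapless extension allowing `max_mismatches = 2`. A read
with several equal-best placements is discarded entirely — multi-mapped
strand evidence is worse than none, because paralog cross-talk corrupts
the orientation signal. Each unique read contributes once to coverage,
regardless of its dereplication multiplicity; PCR copies should not vote.

* **Low-coverage splitting.** Maximal runs with fewer than
  `min_span_reads = 3` mapped reads, strictly longer than one read length,
  are excised; such stretches are sequence the reads never supported as a
  single transcript. Fragments below the global 100 bp floor are dropped.
* **Strand splitting.** Positions are classified from stranded coverage
  smoothed over a `window = 50` bp as forward-dominated (forward fraction
  $\ge$ `purity = 0.9`), reverse-dominated, or mixed; zero-coverage
  positions inherit their nearest classified neighbor. Maximal
  forward-or-mixed runs become `+` contigs, reverse-or-mixed runs become
  `-` contigs: a mixed stretch — both orientations present, the signature
  of overlapping antisense transcripts — is therefore retained on *both*
  strands and stays attached to its flanking same-strand segments, so each
  strand's transcript remains contiguous. The transition point between
  pure stretches marks the boundary of adjacent opposite-strand
  transcripts and becomes a cut. The window/purity parameterization is this
  package's own operational definition of the transition point; the
  smoothing can displace a pure/mixed boundary by up to about half a
  window, which only widens the doubly-kept region and never eats into a
  pure segment.
* **Orientation.** `-` segments are reverse-complemented; stranded reads
  are assumed sense-strand. For dUTP-style chemistry, where the stranded
  read is the antisense of the mRNA, `antisense_protocol = TRUE` flips the
  strand assignment of every segment before orientation. Contigs with no
  stranded evidence pass through unoriented.
* **Polishing.** At every position with depth $\ge 3$, the contig base is
  replaced by the plurality base of the mapped-read pileup; ties and thin
  positions keep the assembly base. Substitution-only, so length is
  invariant. The `min_depth = 3` reuses the pipeline-wide three-read
  evidence threshold.

The stage order — low-coverage split, strand split, orient, polish — means
base counts are reoriented alongside their contigs, and the final length
filter (`min_contig_length = 100`, inclusive) runs last.

## Evaluation

Contigs are aligned to the reference by a spliced-lite aligner: exact-seed
diagonal blocks, extended through isolated mismatches, chained co-linearly
with reference gaps up to `max_intron = 5000` bp, scored
$s = \mathrm{matches} - \mathrm{mismatches}$; all best-scoring placements
are kept. Gene intervals are the annotated spans (no exon substructure —
appropriate for intron-poor yeast-like annotations). The four criteria:

* **Accuracy**: fraction of contigs whose best hit aligns $> 95\%$ of the
  contig's length.
* **Completeness**: fraction of genes covered $> 80\%$ of their length by
  the union of all contig blocks.
* **Contiguity**: fraction of genes covered $> 80\%$ by a *single* contig.
* **Gene fusions**: contigs overlapping $\ge 2$ genes, each by $> 50\%$ of
  that gene's length.

All thresholds are strict inequalities and configurable; contiguity can
never exceed completeness. Coverage is strand-blind, matching the
genome-coordinate comparison the criteria are defined on.

## The synthetic-data generator

`simulation_config()` defaults describe the study conditions the package is
tested under, chosen once to emulate deep short-read yeast RNA-Seq at desk
scale:

| parameter | default | what it emulates |
|---|---|---|
| `n_genes` | 50 | enough genes for stable percentages at seconds-scale runtime |
| `gene_length_range` | 500–1500 bp | yeast-like single-exon transcripts |
| `expression_log10_range` | 20–500x | orders-of-magnitude expression spread |
| `antisense_overlap_frac` | 0.1 | ~10% of genes in overlapping antisense pairs |
| `overlap_len_range` | 50–150 bp | UTR-scale antisense overlaps |
| `error_rate` | 1% | substitution-dominant short-read errors |
| `pcr_duplicate_rate` | 1.0 | one PCR copy per fragment on average |
| `read_length` | 34 bp | short early-generation reads |
| `stranded_frac` | 0.7 | mixed stranded / non-stranded pools |

Depth is the *raw* read depth: total yield per transcript is fixed at
`depth x length / read_length` reads, of which `1/(1 + pcr_duplicate_rate)`
are distinct fragments and the rest are PCR copies (geometric copy counts)
with independent per-copy sequencing errors. Holding yield fixed is both
how sequencing actually behaves and what makes the unique-read count fall
monotonically as duplication rises. Per-transcript depths are drawn before
any read sampling so that configurations differing only in the error or
duplication model share an identical expression profile.

What the generator does **not** emulate — and therefore what passing tests
cannot certify about real data: spliced transcripts, indel errors,
quality-score structure, sequence-composition bias, paralogous gene
families, and non-uniform fragment start positions. Random genomes are
repeat-free at k-mer scale, so repeat resolution is exercised only by the
constructed-repeat unit tests, not by the harness.

## Numerical and tie-break decisions

* All internal coordinates are 0-based half-open; GFF's 1-based closed
  convention is converted at the boundary.
* Determinism everywhere: graph nodes and unitigs in lexicographic order;
  merge overlaps in (length, identity, id) order; final contigs sorted by
  length then sequence; a fixed seed makes the whole pipeline and the
  generator byte-identical across runs.
* Rarity boundary: "fewer than three" means a count of 2 is rare and 3
  survives. Low-coverage runs split only when *strictly* longer than one
  read length. The 100 bp output floor is inclusive.
* Polishing ties keep the original base; best-hit ties in alignment keep
  all hits; containment ties keep the lexicographically smaller id.
* Reads shorter than the mapping seed cannot be placed and are counted
  unmapped.

## Problem sizes

The test suite and acceptance script run the full pipeline on datasets of
20–50 genes (1–3 x 10^5 reads), three replicate seeds for the
heterogeneous-conditions check, with oracle-equivalence checks on inputs up
to ~10^3 reads and ~10^5 bp of reference. These sizes give stable
percentages while keeping any single run under a minute on one CPU.

## Known limitations

* No paired-end information; mates are independent single-end reads.
* No bubble popping or coverage-based repeat resolution; highly similar
  paralogs and polymorphic alleles will collapse to one contig, with the
  minority allele polished away.
* Greedy two-contig junction consensus, not a column-wise multiple
  alignment.
* The strand-transition definition (window + purity) is an operational
  choice; pathological coverage (e.g., rapidly alternating orientations
  within a window) will classify as mixed and be kept on both strands.
* The internal mapper is gapless; indel-bearing reads map only if their
  mismatch budget survives, and polishing is substitution-only.
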
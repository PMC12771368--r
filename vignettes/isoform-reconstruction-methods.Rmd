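---
title: "Methods: replicate-concordant isoform reconstruction from long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replicate-concordant isoform reconstruction from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`isoforge` reconstructs full-length transcript isoforms from uniquely
aligned long cDNA reads of two or more biological replicates. An isoform is
the triple *(TSS peak, intron chain, PA peak)*; a gene is a connected
component of isoforms under a span-overlap relation. The pipeline assumes:

* reads are orientation-unified (mRNA sense), so a `+` alignment has its
  biological 5' end at the leftmost reference position and a `-` alignment
  at the rightmost;
* each retained read has exactly one linear alignment — reads with
  secondary alignments (ambiguous locus) or supplementary alignments
  (chimeric placement) are excluded, since chimeric artifacts are a known
  failure mode of long-read libraries;
* biological replicates are independent libraries from the same condition,
  so evidence reproduced across replicates is signal and evidence private
  to one replicate is (mostly) noise.

All internal coordinates are 0-based half-open; 1-based inclusive
coordinates exist only at the GTF and junction-file boundaries, converted
at a single point each, which keeps off-by-one drift out of the core.

# Stages and their parameters

## Read-level filtering

*Mean quality* (`quality_min`, default 7, Phred units). "Trimming by
quality" for nanopore reads is interpreted as whole-read pass/fail on the
mean error probability, re-expressed on the Phred scale
(−10·log10(mean p)). A per-base trim at Q7 would shred typical nanopore
reads, whereas read-level mean-Q7 is the established pass/fail convention;
the mean is taken in probability space because averaging Phred scores
overweights good bases.

*Poly(A) trimming* (`polya_adapter_len` 100, `polya_error_rate` 0.1,
`polya_min_overlap` 3). The trimmer implements 3'-adapter semantics for the
adapter A×100: among all tail start positions whose suffix has at most 10%
non-A bases, the one maximizing the number of matched A's wins (ties go to
the fewest errors, i.e. the latest start), and everything from there to the
3' end is removed. This mirrors the behaviour of standard adapter trimmers
given an `A{100}` adapter, including their willingness to bridge short
non-A islands when the error budget allows it.

## Alignment and intron candidates

Alignment is delegated to an external splice-aware aligner (default
`minimap2 -ax splice -k14 -uf -G 10k`, passed verbatim); pipelines starting
from existing SAM/BAM skip it. Intron candidates are the `N` operations of
each CIGAR, extracted in reference space (`M`, `D`, `N`, `=`, `X` advance
the reference; `I`, `S`, `H`, `P` do not).

## Splice-site correction (`splice_tolerance_bp`, default 10)

The reference junction set keeps junctions seen in at least
`junction_min_samples` (default 2) distinct samples; an annotation can also
serve as a junction source, treated as a single sample that always passes.
Each alignment gap is corrected independently: candidate reference introns
must match **both** boundaries within the tolerance of the **same**
reference intron. The per-intron reading was chosen over per-boundary
matching because replacement substitutes one coordinated object (a known
intron), not two independent boundaries; the alternative could stitch a
donor of one intron to the acceptor of another. Among candidates the one
with minimal total displacement wins; ties break to the smaller donor, then
smaller acceptor, making correction deterministic. Gaps with no admissible
candidate are treated as deletions and removed. Matching is
coordinate-based (strand-agnostic), and a corrected chain is re-checked for
sortedness: a replacement that would overlap its neighbour is dropped and
counted. With an empty reference set every gap is removed — correction
should therefore only be enabled when a junction resource exists.

## Downsampling (`downsample_cap` 1000, `min_gene_reads` 5)

Highly expressed genes yield many degraded fragments whose 5' ends mimic
alternative TSSs, so read counts are optionally capped per replicate. In
annotated mode each read is attributed to at most one gene — the gene with
the largest span overlap, ties broken by overlap fraction of the read and
then lexicographic gene id; the attribution rule is a design choice (the
cap is only meaningful if a read cannot count against two genes). Genes
with fewer than `min_gene_reads` reads are ignored; genes above the cap
keep exactly `cap` uniformly drawn reads. In annotation-free mode per-base
coverage is computed per (replicate, chromosome, strand), maximal runs of
positions above the cap are found, and reads are removed one at a time —
drawn uniformly among reads covering the current maximum-coverage position
(leftmost on ties) — until the run is at the cap. Drawing from the maximum
position (rather than from all reads of the run) targets removal where the
excess actually is. Coverage is stranded so antisense genes do not trigger
each other's downsampling. Every RNG stream is derived from the global seed
and a (replicate, gene) or (replicate, chromosome, strand) key by a stable
hash, so results are reproducible and independent of processing order.

## End peak calling (`support_min_replicates` 2, `pooled_cutoff` 2, `merge_dist` 10)

Four tracks per chromosome (5'/3' × strand) are built at single-nucleotide
resolution; each read contributes exactly one position per track.
Positions covered in fewer than `support_min_replicates` replicates are
discarded before pooling; pooled counts are raw sums (no TPM-style
normalization — peak calling needs absolute evidence, and the replicate
filter already handles library-size asymmetry). Candidates are positions
with pooled count **strictly greater** than `pooled_cutoff`; the strict
comparison is a deliberate choice (declared in the configuration docs,
switchable via `strict_cutoff = FALSE`), meaning a position needs pooled
count ≥ 3 under the defaults. Unidirectional clustering merges consecutive
candidates when the number of intervening non-candidate positions is
smaller than `merge_dist` — positions 100 and 110 merge (gap 9), 100 and
111 do not (gap 10); this off-by-one is stated explicitly because it
changes every peak. The summit is the candidate with the maximal pooled
count, ties resolved toward the transcription-direction 5'-most candidate
(smallest coordinate on `+`, largest on `-`) for determinism.

## Isoform and gene assembly

Reads whose strand-aware 5' position falls in no TSS peak (or 3' position
in no PA peak) are rejected with a reason code; rejected plus assigned
reads always partition the input. Assigned reads group by the exact triple
(TSS peak id, encoded chain, PA peak id); single-exon reads group by end
peaks alone. The concordance filter keeps a candidate iff some replicate
has ≥ `high_count` (5) reads **and a different** replicate has ≥
`low_count` (1). For gene clustering the isoform span is the outer bounds
of its two peak regions — the "right minus left" length is applied to
regions, since summits alone would understate the isoform's footprint;
two same-strand isoforms join when their overlap reaches
`gene_overlap_frac` (0.8) of the shorter span, and genes are the connected
components (union-find) of that relation. Gene clustering is
strand-separate — merging antisense overlapping genes would contradict the
stranded peak calling. Annotation naming uses the same 80%-of-shorter rule
with maximal absolute overlap (ties lexicographic); unnamed genes get
stable coordinate-derived ids (`IFG_<chrom>_<start>_<strand>`). The
optional minor-isoform filter keeps an isoform iff its total count
(summed over replicates — the per-replicate alternative is not taken, as
the filter models within-gene expression share) strictly exceeds
`minor_frac` (0.01) of the gene's major isoform; exact ties for major are
all kept. Emitted exon structures run summit-to-summit around the chain;
an isoform whose summits are inconsistent with its chain (e.g. a TSS
summit inside the first intron) is dropped with a warning rather than
emitted malformed.

# The simulator

`make_toy_genome()` / `simulate_reads()` emulate the features the pipeline
is sensitive to: multi-isoform genes sharing introns but differing in TSS,
PA or a skipped exon (alternative ends at least 40 bp apart so their peaks
are separable at `merge_dist` 10); negative-binomial expression (defaults
n = 1, p = 0.004, mean ≈ 249 reads per isoform) or fixed counts;
5'/3' truncation by a completeness mixture (full length with probability
`prob_full`, otherwise a Beta-distributed retained fraction); integer
Gaussian end jitter that never extends a read beyond the transcript;
substitution and indel errors injected consistently into both the read
sequence and the ground-truth CIGAR; and an appended poly(A) tail in the
FASTQ output. Transcript-terminal bases are set to a CG run long enough
that tail trimming cannot bridge into genomic sequence, so the
trimming-exactness invariant is testable. The truth SAM carries the
error-free alignment geometry, letting every downstream stage run without
an aligner.

What the simulator does **not** model: base-composition bias, homopolymer
error clustering, template switching/chimeras, internal poly(A) priming,
antisense transcription, overlapping genes, or expression-dependent
truncation. Passing tests on these fixtures therefore demonstrate
correctness of the algorithmic contracts, not performance on real tissue
libraries.

The distorted-annotation generator draws one of seven boundary
modifications per transcript (5'/3' × upstream/downstream, both ends
together, or none) uniformly — the source procedure gives no weights —
with upstream/downstream taken in transcription direction, shifts applied
to terminal exons only, and contractions stopping 1 bp short of the first
splice junction.

# Evaluation

Points mode scores a prediction as correct iff chain, 5' point and 3'
point are all identical to an etalon transcript (no slack; exactness is
the stated contract). Peaks mode requires the etalon points to fall inside
the predicted end regions. Matching is greedy in prediction order with
each etalon consumable once, so exact duplicates become false positives
while the true-positive count is order-invariant. When predictions carry
replicate information, only isoforms detected in at least two replicates
are evaluated; point-only predictions (from other tools' GTFs) are
expanded to regions using the per-gene maximal peak length N from a
reference reconstruction (`peak_halfwidths()`), genes assigned by >10%
span intersection, with halfwidth 0 when no gene matches. Precision,
recall and F1 use the 0-when-undefined convention.

# Problem sizes and numerical behaviour

The shipped test fixtures use 2 × 100 kb chromosomes with 20 genes (1–4
isoforms each) at 30–50 reads per isoform in 3 replicates — small enough
for a laptop run of the whole suite, large enough that every filter and
clustering rule is exercised at its boundary. Oracle tests compare the
unidirectional clustering, gene clustering and junction index against
brute-force re-implementations over 10^4 random tracks, 100 × 200 random
spans and 10^4 random queries respectively. Determinism is asserted at the
byte level on all written outputs for a fixed seed.

Known limitations: the read→gene attribution and the strand conventions
above are reasonable choices where the underlying procedure is silent; the
annotation-free downsampler is O(excess × run length) per run and will be
slow on pathological million-fold stacks; isoforms whose alternative ends
lie within `merge_dist` of each other collapse into one peak and are
indistinguishable by construction; and single-exon isoforms on opposite
strands of the same locus are only separated if the input alignments are
correctly stranded.
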
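# isoforge

Full-length transcript isoform reconstruction from long cDNA reads.

## The problem

Long-read cDNA sequencing (nanopore, PacBio) can in principle read a
transcript end to end, but turning raw reads into a trustworthy isoform
catalogue is hard: reads are truncated by RNA degradation and incomplete
synthesis, alignment around splice junctions is error-prone, chimeric reads
fake trans-splicing, and transcriptional noise blurs the true transcription
start sites (TSS) and polyadenylation (PA) sites. Most reconstruction tools
treat transcript termini as single points inherited from an annotation,
which makes them fragile when the annotation is wrong or absent.

`isoforge` takes the opposite, data-centred route. An isoform is defined as
a triple

    (TSS region)  --  intron chain  --  (PA region)

and each component is inferred from the reads themselves:

* **Peak calling on read ends.** Strand-specific single-nucleotide coverage
  of read 5' and 3' ends is built per biological replicate; positions
  covered in at least 2 replicates are pooled (raw sums, no normalization),
  and positions whose pooled count exceeds 2 are merged into peaks by
  unidirectional clustering (gap < 10 bp), each with a summit.
* **Splice-site correction.** Intron candidates are the `N` gaps of the
  spliced alignments; a gap whose boundaries lie within 10 bp of a
  reference junction (e.g. from short-read data, seen in >= 2 samples) is
  snapped to it, otherwise it is treated as a deletion and discarded.
* **Replicate concordance.** Reads with identical (TSS peak, corrected
  chain, PA peak) form an isoform candidate; a candidate is kept only with
  >= 5 reads in one replicate and >= 1 read in another.
* **Genes by overlap.** Isoforms sharing >= 80% of the shorter span are
  joined into genes (connected components); optionally, isoforms below 1%
  of the gene's major isoform are dropped, and genes are named from an
  annotation by the same 80% rule.

Optional modules cap coverage of highly expressed genes (annotated or
annotation-free downsampling at 1000 reads) so tattered high-abundance
transcripts do not drown TSS signal. A built-in simulator generates toy
genomes, truth annotations and reads with truncation/jitter/error models,
and the evaluator scores reconstructions against a truth annotation with
transcript ends treated either as **points** (summits must match exactly) or
as **peaks** (the truth point must fall inside the predicted region).

## Worked example

Simulate a small experiment (4 genes, 10 error-free full-length reads per
isoform in 3 replicates), reconstruct, and score:

```r
library(isoforge)

sim <- sim_config(n_chroms = 1, chrom_len = 40000, n_genes = 4,
                  reads_per_isoform = 10, seed = 5)
toy <- make_toy_genome(sim)
rd  <- simulate_reads(toy$genome, toy$transcripts, sim)
res <- run_pipeline(rd$reads)
print(res)
#> Isoform reconstruction result
#>   input reads:     450 in 3 replicate(s)
#>   TSS / PA peaks:  8 / 8
#>   assigned reads:  450 (0 rejected)
#>   isoforms:        15 in 4 gene(s)

evaluate_isoforms(res, toy$transcripts, mode = "points")
#> evaluation: TP 15, FP 0, FN 0 | precision 1.000 recall 1.000 F1 1.000

head(res$tss_peaks[, c("peak_id", "start", "end", "summit", "pooled_count")], 3)
#>           peak_id start  end summit pooled_count
#> 1 TSS_chr1_-_3793  3793 3794   3793           30
#> 2 TSS_chr1_-_3833  3833 3834   3833           90
#> 3 TSS_chr1_-_7170  7170 7171   7170           30
```

All 450 reads land in a TSS and a PA region, the 15 truth isoforms are
recovered exactly (15 true positives, no false calls), and each clean TSS
peak is a single-nucleotide region whose pooled count is the read count
summed over replicates (3 x 10 per isoform; 90 where three isoforms share a
start). `write_models(res, "out/", genome = toy$genome)` emits `models.gtf`,
`isoforms.fa`, `genes.fa`, per-isoform `counts.tsv`, `rejects.tsv` and
per-gene text pseudo-alignments.

A shell front end with `run`, `simulate` and `evaluate` subcommands is
installed at `inst/cli/isoforge`, mirroring the same functions
(`--make_downsampling`, `--extra_filter_iso`, `--splice_sites`, `--bam`,
`--annotation`, ...).

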
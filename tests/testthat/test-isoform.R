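# Read-to-peak assignment, isoform grouping and filtering, gene clustering
# and naming, and exon-structure assembly.

peak_row <- function(peak_id, chrom, strand, end_type, start, end,
                     summit = start) {
  data.frame(peak_id = peak_id, chrom = chrom, strand = strand,
             end_type = end_type, start = as.integer(start),
             end = as.integer(end), summit = as.integer(summit),
             pooled_count = 10L, n_candidates = 1L, stringsAsFactors = FALSE)
}

std_peaks <- function() {
  list(tss = peak_row("T1", "chr1", "+", "five_prime", 100, 110),
       pa = peak_row("P1", "chr1", "+", "three_prime", 495, 505, 500))
}

test_that("reads are assigned when both ends fall inside peak regions", {
  pk <- std_peaks()
  reads <- make_reads("chr1", c(105, 95), c(500, 500), "+")
  out <- assign_ends(reads, pk$tss, pk$pa)
  expect_equal(out$tss_peak, c("T1", NA))
  expect_equal(out$reject_reason, c(NA, "no_tss"))
  # conservation: assigned + no_tss + no_pa = input
  reads2 <- make_reads("chr1", c(105, 95, 105), c(500, 500, 400), "+")
  out2 <- assign_ends(reads2, pk$tss, pk$pa)
  expect_equal(sum(is.na(out2$reject_reason)) +
               sum(out2$reject_reason == "no_tss", na.rm = TRUE) +
               sum(out2$reject_reason == "no_pa", na.rm = TRUE),
               nrow(reads2))
})

test_that("minus-strand reads check their biological 5' end", {
  tss <- peak_row("T1", "chr1", "-", "five_prime", 195, 205, 199)
  pa <- peak_row("P1", "chr1", "-", "three_prime", 95, 105, 100)
  out <- assign_ends(make_reads("chr1", 100, 200, "-"), tss, pa)
  expect_equal(out$tss_peak, "T1")  # 5' position 199 in [195, 205)
  expect_equal(out$pa_peak, "P1")   # 3' position 100 in [95, 105)
})

assigned_reads <- function(tss, chain, pa, replicate, strand = "+") {
  n <- max(length(tss), length(replicate))
  df <- make_reads("chr1", 100, 500, strand, replicate = replicate,
                   read_id = sprintf("q%03d", seq_len(n)))
  df$introns <- lapply(rep_len(chain, n), isoforge:::decode_chain)
  df$tss_peak <- rep_len(tss, n)
  df$pa_peak <- rep_len(pa, n)
  df$reject_reason <- NA_character_
  df
}

test_that("grouping key is (TSS peak, exact chain, PA peak)", {
  reads <- assigned_reads("T1", "150-250", "P1", c("r1", "r1"))
  g <- group_reads(reads, replicates = c("r1", "r2"))
  expect_equal(nrow(g), 1L)
  expect_equal(unname(g$counts[1, ]), c(2L, 0L))
  # a 1 bp donor difference separates isoforms
  reads2 <- assigned_reads("T1", c("150-250", "151-250"), "P1",
                           c("r1", "r1"))
  expect_equal(nrow(group_reads(reads2, c("r1", "r2"))), 2L)
  # a different TSS peak separates isoforms with identical chains
  reads3 <- assigned_reads(c("T1", "T2"), "150-250", "P1", c("r1", "r1"))
  expect_equal(nrow(group_reads(reads3, c("r1", "r2"))), 2L)
  # single-exon reads group by end peaks alone
  reads4 <- assigned_reads("T1", "", "P1", c("r1", "r2", "r2"))
  g4 <- group_reads(reads4, c("r1", "r2"))
  expect_equal(nrow(g4), 1L)
  expect_equal(unname(g4$counts[1, ]), c(1L, 2L))
})

test_that("the replicate-concordance filter follows the count table", {
  cand <- data.frame(tss_peak = "T", pa_peak = "P", chrom = "chr1",
                     strand = "+", chain = c("a", "b", "c"),
                     stringsAsFactors = FALSE)
  cand$counts <- matrix(c(6L, 1L, 0L,
                          5L, 0L, 0L,
                          4L, 4L, 4L), nrow = 3, byrow = TRUE,
                        dimnames = list(NULL, c("r1", "r2", "r3")))
  cand$total <- as.integer(rowSums(cand$counts))
  kept <- filter_by_replicates(cand, high_count = 5L, low_count = 1L)
  expect_equal(kept$chain, "a")   # (6,1,0) kept; (5,0,0) and (4,4,4) dropped
  # with no high threshold, any single supported replicate suffices
  kept0 <- filter_by_replicates(cand, high_count = 0L, low_count = 1L)
  expect_equal(nrow(kept0), 3L)
})

span_iso <- function(chrom, strand, s, e) {
  data.frame(chrom = chrom, strand = strand, span_start = as.integer(s),
             span_end = as.integer(e), stringsAsFactors = FALSE)
}

test_that("isoforms sharing 80% of the shorter span join a gene", {
  iso <- span_iso("chr1", "+", c(0, 10), c(100, 120))
  cl <- cluster_genes(iso, 0.8)          # overlap 90 >= 0.8 * 100
  expect_equal(cl$membership, c(1L, 1L))
  iso2 <- span_iso("chr1", "+", c(0, 90), c(100, 200))
  cl2 <- cluster_genes(iso2, 0.8)        # overlap 10 < 80
  expect_equal(length(unique(cl2$membership)), 2L)
  # transitivity: A~B, B~C, not A~C -> one gene
  iso3 <- span_iso("chr1", "+", c(0, 80, 160), c(100, 180, 260))
  cl3 <- cluster_genes(iso3, 0.2)
  expect_equal(length(unique(cl3$membership)), 1L)
  expect_equal(cl3$genes$start, 0L)
  expect_equal(cl3$genes$end, 260L)
})

test_that("gene clustering matches transitive closure on random spans", {
  set.seed(41)
  for (trial in 1:30) {
    n <- sample(10:60, 1)
    s <- sample(0:3000, n, replace = TRUE)
    e <- s + sample(50:500, n, replace = TRUE)
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    iso <- data.frame(chrom = chrom, strand = strand, span_start = s,
                      span_end = e, stringsAsFactors = FALSE)
    got <- cluster_genes(iso, 0.8)$membership
    want <- oracle_components(chrom, strand, s, e, 0.8)
    # same partition up to relabelling
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(v) length(unique(v))) == 1L))
  }
})

test_that("genes take annotated ids by the 80%-of-shorter rule", {
  genes <- data.frame(gene_idx = 1:3, chrom = "chr1",
                      start = c(0L, 0L, 5000L), end = c(1000L, 1000L, 6000L),
                      strand = "+", n_isoforms = 1L, stringsAsFactors = FALSE)
  ann <- data.frame(gene_id = c("G1", "G2"), chrom = "chr1",
                    start = c(0L, 900L), end = c(1000L, 2000L), strand = "+",
                    stringsAsFactors = FALSE)
  out <- assign_gene_ids(genes[1, ], ann, 0.8)
  expect_equal(out$gene_id, "G1")                 # identical span
  out2 <- assign_gene_ids(genes[3, ], ann, 0.8)
  expect_match(out2$gene_id, "^IFG_chr1_5000")    # overlap 0: novel id
  # reconstructed gene overlapping two annotated genes: larger overlap wins
  ann3 <- data.frame(gene_id = c("A", "B"), chrom = "chr1",
                     start = c(0L, 600L), end = c(700L, 1000L), strand = "+",
                     stringsAsFactors = FALSE)
  out3 <- assign_gene_ids(genes[1, ], ann3, 0.8)
  expect_equal(out3$gene_id, "A")                 # 700 vs 400
  # strand mismatch blocks naming
  ann4 <- ann
  ann4$strand <- "-"
  out4 <- assign_gene_ids(genes[1, ], ann4, 0.8)
  expect_match(out4$gene_id, "^IFG_")
})

test_that("minor isoforms are dropped strictly below 1% of the major", {
  iso <- data.frame(total = c(1000L, 11L, 10L), stringsAsFactors = FALSE)
  keep <- filter_minor_isoforms(iso, membership = c(1L, 1L, 1L),
                                minor_frac = 0.01)
  expect_equal(keep, c(TRUE, TRUE, FALSE))  # 11 > 10 kept, 10 not
  # single-isoform genes and exact ties are always kept
  iso2 <- data.frame(total = c(7L, 7L, 3L))
  expect_equal(filter_minor_isoforms(iso2, c(1L, 1L, 2L), 0.01),
               rep(TRUE, 3))
})

test_that("exon structures run summit-to-summit around the chain", {
  iso <- data.frame(chain = c("150-250", "", "150-250"),
                    tss_summit = c(100L, 100L, 200L),
                    pa_summit = c(300L, 200L, 300L),
                    chrom = "chr1", strand = "+", stringsAsFactors = FALSE)
  expect_warning(out <- build_exon_structures(iso), "dropped")
  expect_equal(nrow(out), 2L)
  expect_equal(out$exons[[1]], chain_mat(100, 150, 250, 301))
  expect_equal(out$exons[[2]], chain_mat(100, 201))
  # minus strand: PA summit is the genomic left end
  iso_m <- data.frame(chain = "150-250", tss_summit = 300L, pa_summit = 100L,
                      chrom = "chr1", strand = "-", stringsAsFactors = FALSE)
  out_m <- build_exon_structures(iso_m)
  expect_equal(out_m$exons[[1]], chain_mat(100, 150, 250, 301))
})
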
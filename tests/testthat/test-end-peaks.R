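# Strand-specific end coverage, replicate-support pooling, and
# unidirectional peak clustering.

test_that("read ends land on strand-aware single-nucleotide positions", {
  plus <- make_reads("chr1", 100, 200, "+")
  expect_equal(end_coverage(plus, "five_prime")$pos, 100L)
  expect_equal(end_coverage(plus, "three_prime")$pos, 199L)
  minus <- make_reads("chr1", 100, 200, "-")
  expect_equal(end_coverage(minus, "five_prime")$pos, 199L)
  expect_equal(end_coverage(minus, "three_prime")$pos, 100L)
  three <- make_reads("chr1", c(100, 100, 103), c(200, 210, 220), "+")
  cov <- end_coverage(three, "five_prime")
  expect_equal(cov$pos, c(100L, 103L))
  expect_equal(cov$count, c(2L, 1L))
})

test_that("each read contributes exactly one end per track", {
  set.seed(31)
  reads <- make_reads("chr1", s <- sample(0:5000, 300, replace = TRUE),
                      s + sample(100:900, 300, replace = TRUE),
                      sample(c("+", "-"), 300, replace = TRUE),
                      replicate = sample(c("r1", "r2"), 300, replace = TRUE))
  for (et in c("five_prime", "three_prime")) {
    cov <- end_coverage(reads, et)
    sums <- tapply(cov$count, cov$replicate, sum)
    expect_equal(as.integer(sums[c("r1", "r2")]),
                 as.integer(table(reads$replicate)[c("r1", "r2")]))
  }
})

cov_row <- function(rep, pos, count, chrom = "chr1", strand = "+") {
  data.frame(replicate = rep, chrom = chrom, strand = strand,
             pos = as.integer(pos), count = as.integer(count),
             stringsAsFactors = FALSE)
}

test_that("pooling keeps positions covered in enough replicates", {
  cov <- rbind(cov_row("r1", 100, 3), cov_row("r1", 200, 3),
               cov_row("r2", 200, 1))
  pooled <- pool_with_support(cov, 2L, replicates = c("r1", "r2", "r3"))
  expect_equal(pooled$pos, 200L)         # (3,0,0) removed
  expect_equal(pooled$pooled, 4L)        # raw sum, no normalization
  expect_error(pool_with_support(cov, 2L, replicates = "r1"),
               "number of replicates")
})

test_that("unidirectional clustering merges candidates by gap", {
  pooled <- data.frame(chrom = "chr1", strand = "+",
                       pos = c(100L, 103L, 140L),
                       pooled = c(5L, 4L, 3L), support = 2L,
                       stringsAsFactors = FALSE)
  peaks <- call_clusters(pooled, pooled_cutoff = 2L, merge_dist = 10L)
  expect_equal(nrow(peaks), 2L)
  expect_equal(peaks$start, c(100L, 140L))
  expect_equal(peaks$end, c(104L, 141L))
  expect_equal(peaks$summit, c(100L, 140L))
  expect_equal(peaks$pooled_count, c(9L, 3L))
})

test_that("the pooled cutoff is strict and gap semantics are exact", {
  single <- data.frame(chrom = "chr1", strand = "+", pos = 100L,
                       pooled = 2L, support = 2L, stringsAsFactors = FALSE)
  expect_equal(nrow(call_clusters(single, 2L, 10L)), 0L)
  expect_equal(nrow(call_clusters(single, 2L, 10L, strict = FALSE)), 1L)
  # positions 100 and 110: 9 intervening -> merge; 100 and 111: 10 -> split
  two <- function(p2) data.frame(chrom = "chr1", strand = "+",
                                 pos = c(100L, p2), pooled = 5L,
                                 support = 2L, stringsAsFactors = FALSE)
  expect_equal(nrow(call_clusters(two(110L), 2L, 10L)), 1L)
  expect_equal(nrow(call_clusters(two(111L), 2L, 10L)), 2L)
  # empty track
  empty <- single[0, ]
  expect_equal(nrow(call_clusters(empty, 2L, 10L)), 0L)
})

test_that("summit ties break to the transcription-direction 5' end", {
  tied <- function(strand) data.frame(chrom = "chr1", strand = strand,
                                      pos = c(100L, 102L), pooled = 7L,
                                      support = 2L, stringsAsFactors = FALSE)
  expect_equal(call_clusters(tied("+"), 2L, 10L)$summit, 100L)
  expect_equal(call_clusters(tied("-"), 2L, 10L)$summit, 102L)
})

test_that("clustering equals all-pairs merging on random sparse tracks", {
  set.seed(32)
  for (i in 1:300) {
    pos <- sort(sample(0:200, sample(1:12, 1)))
    md <- sample(1:15, 1)
    pooled <- data.frame(chrom = "chr1", strand = "+", pos = pos,
                         pooled = sample(3:9, length(pos), replace = TRUE),
                         support = 2L, stringsAsFactors = FALSE)
    peaks <- call_clusters(pooled, 2L, md)
    want <- oracle_merge_clusters(pos, md)
    expect_equal(nrow(peaks), length(want))
    expect_equal(peaks$start, vapply(want, min, double(1)))
    expect_equal(peaks$end, vapply(want, max, double(1)) + 1L)
    # disjointness and minimum separation between emitted peaks
    if (nrow(peaks) > 1L) {
      expect_true(all(peaks$start[-1] - peaks$end[-nrow(peaks)] >= md))
    }
    # pooled conservation
    expect_true(sum(peaks$pooled_count) <= sum(pooled$pooled))
  }
})

test_that("per-replicate peak counts sum raw counts over candidates", {
  cov <- rbind(cov_row("r1", c(100, 101), c(4, 1)),
               cov_row("r2", c(100, 150), c(2, 9)))
  pooled <- pool_with_support(cov, 1L, replicates = c("r1", "r2"))
  peaks <- call_clusters(pooled, 2L, 10L, raw = cov)
  p1 <- peaks[peaks$start == 100L, ]
  expect_equal(p1$per_replicate[[1]], c(r1 = 4L, r2 = 2L))
})

test_that("peak and track exports are plain text", {
  reads <- make_reads("chr1", c(100, 100, 100, 100), 200, "+",
                      replicate = c("r1", "r1", "r2", "r2"))
  peaks <- call_end_peaks(reads, "five_prime",
                          config = pipeline_config(pooled_cutoff = 2L))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_peaks_bed(peaks, bed)
  expect_match(readLines(bed)[1], "^chr1\t100\t101\tTSS_")
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(end_coverage(reads, "five_prime"), bg)
  expect_equal(length(readLines(bg)), 2L)
})
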
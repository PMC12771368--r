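# Simulator structure, truth alignments, annotation distortion, and the
# points/peaks evaluation protocol.

small_sim <- function(...) {
  args <- list(n_chroms = 2L, chrom_len = 30000L, n_genes = 6L,
               reads_per_isoform = 5L, seed = 101L)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(sim_config, args)
}

test_that("the toy genome is deterministic, non-overlapping and GT..AG", {
  sim <- small_sim()
  t1 <- make_toy_genome(sim)
  t2 <- make_toy_genome(sim)
  expect_identical(as.character(t1$genome), as.character(t2$genome))
  expect_identical(t1$transcripts$tx_id, t2$transcripts$tx_id)
  expect_identical(t1$transcripts$exons, t2$transcripts$exons)
  # gene spans do not overlap within a chromosome
  genes <- isoforge:::annotation_genes(t1$transcripts)
  for (cn in unique(genes$chrom)) {
    g <- genes[genes$chrom == cn, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  # canonical dinucleotides at every intron boundary, strand-aware
  seqs <- as.character(t1$genome)
  for (i in seq_len(nrow(t1$transcripts))) {
    ex <- t1$transcripts$exons[[i]]
    if (nrow(ex) < 2) next
    s <- seqs[[t1$transcripts$chrom[i]]]
    for (j in seq_len(nrow(ex) - 1)) {
      donor <- substr(s, ex[j, 2] + 1, ex[j, 2] + 2)
      accept <- substr(s, ex[j + 1, 1] - 1, ex[j + 1, 1])
      if (t1$transcripts$strand[i] == "+") {
        expect_equal(paste0(donor, accept), "GTAG")
      } else {
        expect_equal(paste0(donor, accept), "CTAC")
      }
    }
  }
})

test_that("error-free full-length reads reproduce the truth exactly", {
  sim <- small_sim()
  toy <- make_toy_genome(sim)
  rd <- simulate_reads(toy$genome, toy$transcripts, sim)
  expect_equal(length(unique(rd$reads$replicate)), 3L)
  truth_by_tx <- split(seq_len(nrow(toy$transcripts)),
                       toy$transcripts$tx_id)
  for (i in seq_len(nrow(rd$reads))) {
    tx_id <- sub("^rep\\d+_(.*)_\\d+$", "\\1", rd$reads$read_id[i])
    t <- toy$transcripts[truth_by_tx[[tx_id]], ]
    expect_equal(rd$reads$start[i], t$start)
    expect_equal(rd$reads$end[i], t$end)
    ex <- t$exons[[1]]
    want <- if (nrow(ex) > 1) {
      cbind(start = ex[-nrow(ex), 2], end = ex[-1, 1])
    } else {
      matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
    }
    expect_equal(rd$reads$introns[[i]], want)
  }
  # CIGAR reference width is consistent with the recorded span
  widths <- vapply(rd$reads$cigar, oracle_cigar_ref_width, numeric(1))
  expect_equal(unname(widths), rd$reads$end - rd$reads$start)
})

test_that("truth SAM round-trips through the alignment reader", {
  sim <- small_sim()
  toy <- make_toy_genome(sim)
  dir <- withr::local_tempdir()
  rd <- simulate_reads(toy$genome, toy$transcripts, sim, out_dir = dir)
  reads <- unique_alignment_filter(
    read_alignments(file.path(dir, "rep1.truth.sam"), "rep1"))
  ours <- rd$reads[rd$reads$replicate == "rep1", ]
  m <- match(reads$read_id, ours$read_id)
  expect_false(any(is.na(m)))
  expect_equal(reads$start, ours$start[m])
  expect_equal(reads$end, ours$end[m])
  expect_equal(reads$strand, ours$strand[m])
})

test_that("poly(A) trimming removes exactly the simulated tail", {
  sim <- small_sim()
  toy <- make_toy_genome(sim)
  rd <- simulate_reads(toy$genome, toy$transcripts, sim)
  fq <- rd$fastq$rep1
  trimmed <- trim_polya(fq$seq)
  ours <- rd$reads[rd$reads$replicate == "rep1", ]
  m <- match(fq$id, ours$read_id)
  spliced_len <- ours$end[m] - ours$start[m] -
    vapply(ours$introns[m], function(ch) sum(ch[, 2] - ch[, 1]), integer(1))
  expect_equal(nchar(trimmed), spliced_len)
})

test_that("5' truncation shifts the truth alignment start", {
  sim <- small_sim(n_genes = 2L, isoforms_per_gene = c(1L, 1L),
                   exons_per_isoform = c(1L, 1L),
                   prob_full_5p = 0, beta_5p = c(1e9, 1e9))
  # Beta(1e9,1e9) concentrates at 0.5: reads lack the 5' half
  toy <- make_toy_genome(sim)
  rd <- simulate_reads(toy$genome, toy$transcripts, sim)
  tx <- toy$transcripts[match(sub("^rep\\d+_(.*)_\\d+$", "\\1",
                                  rd$reads$read_id), toy$transcripts$tx_id), ]
  L <- tx$end - tx$start
  plus <- rd$reads$strand == "+"
  offset5 <- ifelse(plus, rd$reads$start - tx$start,
                    tx$end - rd$reads$end)
  expect_true(all(abs(offset5 - floor(L / 2)) <= 1))
})

test_that("negative-binomial expression has the textbook mean", {
  sim <- sim_config(reads_per_isoform = NULL, nb_n = 1, nb_p = 0.004)
  set.seed(51)
  counts <- isoforge:::draw_read_counts(500L, sim)
  mu <- 1 * (1 - 0.004) / 0.004
  se <- sqrt(1 * (1 - 0.004) / 0.004^2 / 500)
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("distortion shifts terminal exons strand-awarely", {
  base <- data.frame(tx_id = c("p", "m"), gene_id = c("p", "m"),
                     chrom = "chr1", start = 1000L, end = 2000L,
                     strand = c("+", "-"), stringsAsFactors = FALSE)
  base$exons <- list(chain_mat(1000, 2000), chain_mat(1000, 2000))
  # force each case by searching the seeded draw
  for (want in c("5u", "5d", "3u", "none")) {
    seed <- 0L
    repeat {
      seed <- seed + 1L
      out <- distort_annotation(base, 100L, seed = seed)
      if (attr(out, "cases")[1] == want && attr(out, "cases")[2] == want)
        break
      if (seed > 5000L) stop("case not drawn")
    }
    if (want == "5u") {
      expect_equal(c(out$start[1], out$end[1]), c(900L, 2000L))
      expect_equal(c(out$start[2], out$end[2]), c(1000L, 2100L))
    } else if (want == "5d") {
      expect_equal(c(out$start[1], out$end[1]), c(1100L, 2000L))
      expect_equal(c(out$start[2], out$end[2]), c(1000L, 1900L))
    } else if (want == "3u") {
      expect_equal(c(out$start[1], out$end[1]), c(1000L, 1900L))
      expect_equal(c(out$start[2], out$end[2]), c(1100L, 2000L))
    } else {
      expect_equal(c(out$start[1], out$end[1]), c(1000L, 2000L))
      expect_equal(c(out$start[2], out$end[2]), c(1000L, 2000L))
    }
  }
})

test_that("contractions stop one base short of the first junction", {
  tx <- data.frame(tx_id = "t", gene_id = "t", chrom = "chr1",
                   start = 1000L, end = 1400L, strand = "+",
                   stringsAsFactors = FALSE)
  tx$exons <- list(chain_mat(1000, 1050, 1200, 1400))
  seed <- 0L
  repeat {
    seed <- seed + 1L
    out <- distort_annotation(tx, 100L, seed = seed)
    if (attr(out, "cases")[1] == "5d") break
  }
  expect_equal(unname(out$exons[[1]][1, 1]), 1049L)  # 1 bp short of junction
  expect_equal(unname(out$exons[[1]][2, ]), c(1200L, 1400L))
})

pred_row <- function(chain, p5, p3, chrom = "chr1", strand = "+", id = "x",
                     n_replicates = 3L) {
  data.frame(id = id, chrom = chrom, strand = strand, chain = chain,
             p5 = as.integer(p5), p3 = as.integer(p3),
             n_replicates = n_replicates, stringsAsFactors = FALSE)
}

truth_row <- function(chain, p5, p3, id = "e", chrom = "chr1",
                      strand = "+") {
  data.frame(id = id, chrom = chrom, strand = strand, chain = chain,
             p5 = as.integer(p5), p3 = as.integer(p3),
             stringsAsFactors = FALSE)
}

test_that("points mode requires identity of chain and both ends", {
  truth <- rbind(truth_row("150-250", 100, 300, "e1"),
                 truth_row("150-251", 400, 600, "e2"))
  exact <- pred_row("150-250", 100, 300)
  expect_equal(match_points(exact, truth)$tp, 1L)
  off <- pred_row("150-249", 100, 300)   # one intron boundary off by 1
  r <- match_points(off, truth)
  expect_equal(r$tp, 0L)
  expect_equal(r$fp, 1L)
  both <- rbind(exact, pred_row("9-10", 0, 20, id = "y"))
  r2 <- match_points(both, truth)
  expect_equal(c(r2$precision, r2$recall, r2$f1), c(0.5, 0.5, 0.5))
})

test_that("duplicate predictions become false positives, tp unchanged", {
  truth <- truth_row("150-250", 100, 300, "e1")
  dup <- rbind(pred_row("150-250", 100, 300, id = "a"),
               pred_row("150-250", 100, 300, id = "b"))
  r <- match_points(dup, truth)
  expect_equal(r$tp, 1L)
  expect_equal(r$fp, 1L)
  r_rev <- match_points(dup[2:1, ], truth)
  expect_equal(r_rev$tp, 1L)
})

test_that("the two-replicate restriction applies when counts are present", {
  truth <- truth_row("150-250", 100, 300, "e1")
  p <- pred_row("150-250", 100, 300, n_replicates = 1L)
  r <- match_points(p, truth, min_replicates = 2L)
  expect_equal(r$tp, 0L)
  expect_equal(r$fp, 0L)   # prediction excluded from evaluation entirely
  expect_equal(r$fn, 1L)
})

test_that("peaks mode tests containment of etalon points in regions", {
  truth <- truth_row("150-250", 100, 300, "e1")
  p <- pred_row("150-250", 105, 299)
  p$r5_start <- 95L; p$r5_end <- 110L
  p$r3_start <- 295L; p$r3_end <- 305L
  expect_equal(match_peaks(p, truth)$tp, 1L)
  # chain mismatch with perfect regions is still a false positive
  p2 <- p
  p2$chain <- "150-251"
  expect_equal(match_peaks(p2, truth)$tp, 0L)
  # peaks mode never scores below points mode on the same input
  pt <- match_points(pred_row("150-250", 100, 300), truth)
  pk <- match_peaks(within(pred_row("150-250", 100, 300), {
    r5_start <- 100L; r5_end <- 101L; r3_start <- 300L; r3_end <- 301L
  }), truth)
  expect_gte(pk$tp, pt$tp)
})

test_that("point-only predictions expand by per-gene N/2 halfwidths", {
  truth <- truth_row("150-250", 100, 300, "e1")
  genes <- data.frame(gene_id = "G1", chrom = "chr1", start = 90L,
                      end = 310L, strand = "+", stringsAsFactors = FALSE)
  p <- pred_row("150-250", 108, 300)
  r <- match_peaks(p, truth, halfwidth_by_gene = c(G1 = 20L), genes = genes)
  expect_equal(r$tp, 1L)   # [98, 119) contains 100
  r0 <- match_peaks(p, truth, halfwidth_by_gene = c(G1 = 10L), genes = genes)
  expect_equal(r0$tp, 0L)  # [103, 114) misses 100
})

test_that("peak-set comparison classifies overlap, proximity, support", {
  a <- data.frame(chrom = "chr1", strand = "+", start = 100L, end = 110L,
                  stringsAsFactors = FALSE)
  b1 <- data.frame(chrom = "chr1", strand = "+", start = 105L, end = 120L,
                   stringsAsFactors = FALSE)
  r1 <- compare_peak_sets(a, b1)
  expect_equal(r1$peaks$label, "intersecting")
  expect_equal(r1$peaks$rate, 0.5)
  b2 <- data.frame(chrom = "chr1", strand = "+", start = 115L, end = 130L,
                   stringsAsFactors = FALSE)
  r2 <- compare_peak_sets(a, b2, proximity = 10L)
  expect_equal(r2$peaks$label, "proximal")
  expect_equal(r2$peaks$distance, 5L)
  r3 <- compare_peak_sets(a, b2[0, ])
  expect_equal(r3$peaks$label, "unsupported")
  expect_equal(r3$summary$frac_unsupported, 1)
})
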
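#' Downsample reads over highly expressed annotated genes
#'
#' Each read is attributed to at most one gene: the gene whose span overlaps
#' the read most (ties: larger overlap as a fraction of the read, then
#' lexicographic gene id). Genes attributed fewer than `min_gene_reads` reads
#' are ignored; for genes with more than `cap` reads, exactly `cap` reads are
#' kept, drawn uniformly without replacement with a seeded RNG. Reads
#' overlapping no gene are untouched. Replicates are processed independently.
#'
#' @param reads AlignedRead table.
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`), e.g. from
#'   [annotation_genes()].
#' @param cap Maximum reads per gene.
#' @param min_gene_reads Genes below this count are not considered.
#' @param seed Base seed; per-(replicate, gene) streams are derived from it.
#' @return The surviving subset of `reads` (row order preserved).
#' @export
downsample_annotated <- function(reads, genes, cap = 1000L,
                                 min_gene_reads = 5L, seed = 1L) {
  if (nrow(reads) == 0L) return(reads)
  gene_of <- attribute_reads_to_genes(reads, genes)
  drop <- rep(FALSE, nrow(reads))
  for (rep_id in unique(reads$replicate)) {
    idx_rep <- which(reads$replicate == rep_id & !is.na(gene_of))
    tab <- split(idx_rep, gene_of[idx_rep])
    for (g in names(tab)) {
      idx <- tab[[g]]
      if (length(idx) < min_gene_reads || length(idx) <= cap) next
      set.seed(derive_seed(seed, c("ds_gene", rep_id, g)))
      keep <- sample(idx, cap)
      drop[setdiff(idx, keep)] <- TRUE
    }
  }
  message("downsample_annotated: removed ", sum(drop), " of ", nrow(reads),
          " reads")
  reads[!drop, , drop = FALSE]
}

# Attribute each read to the gene with maximal span overlap; ties by overlap
# fraction of the read then lexicographic gene_id. Returns gene_id or NA.
attribute_reads_to_genes <- function(reads, genes) {
  res <- rep(NA_character_, nrow(reads))
  for (chrom in unique(reads$chrom)) {
    ri <- which(reads$chrom == chrom)
    gi <- which(genes$chrom == chrom)
    if (length(gi) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(reads$start[ri] + 1L, reads$end[ri]),
      IRanges::IRanges(genes$start[gi] + 1L, genes$end[gi]))
    if (length(hits) == 0L) next
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- overlap_len(reads$start[ri][q], reads$end[ri][q],
                      genes$start[gi][s], genes$end[gi][s])
    ord <- order(q, -ov, genes$gene_id[gi][s])
    first <- !duplicated(q[ord])
    res[ri[q[ord][first]]] <- genes$gene_id[gi][s[ord][first]]
  }
  res
}

#' Downsample reads in high-coverage regions (annotation-free)
#'
#' Per (replicate, chromosome, strand): per-base coverage of read spans is
#' computed and maximal runs of positions with coverage above `cap` are
#' found. Within each run, reads are removed iteratively — at each step one
#' read is drawn uniformly among the reads covering the position of current
#' maximum coverage — until no position in the run exceeds `cap`. Reads
#' outside all runs are untouched.
#'
#' @inheritParams downsample_annotated
#' @param cap Maximum per-base coverage.
#' @return The surviving subset of `reads` (row order preserved).
#' @export
downsample_annotation_free <- function(reads, cap = 1000L, seed = 1L) {
  if (nrow(reads) == 0L) return(reads)
  drop <- rep(FALSE, nrow(reads))
  keys <- unique(reads[, c("replicate", "chrom", "strand")])
  for (k in seq_len(nrow(keys))) {
    ri <- which(reads$replicate == keys$replicate[k] &
                reads$chrom == keys$chrom[k] &
                reads$strand == keys$strand[k])
    ir <- IRanges::IRanges(reads$start[ri] + 1L, reads$end[ri])
    cov <- IRanges::coverage(ir)
    runs <- IRanges::slice(cov, lower = cap + 1L, rangesOnly = TRUE)
    if (length(runs) == 0L) next
    set.seed(derive_seed(seed, c("ds_free", keys$replicate[k],
                                 keys$chrom[k], keys$strand[k])))
    for (r in seq_along(runs)) {
      ws <- IRanges::start(runs)[r]; we <- IRanges::end(runs)[r]
      alive <- ri[!drop[ri]]
      over <- alive[reads$start[alive] + 1L <= we & reads$end[alive] >= ws]
      # local coverage vector over the run window [ws, we] (1-based)
      local <- integer(we - ws + 1L)
      for (i in over) {
        a <- max(reads$start[i] + 1L, ws) - ws + 1L
        b <- min(reads$end[i], we) - ws + 1L
        local[a:b] <- local[a:b] + 1L
      }
      while (max(local) > cap) {
        pos <- which.max(local) + ws - 1L
        covering <- over[!drop[over] &
                         reads$start[over] + 1L <= pos &
                         reads$end[over] >= pos]
        victim <- covering[sample.int(length(covering), 1L)]
        drop[victim] <- TRUE
        a <- max(reads$start[victim] + 1L, ws) - ws + 1L
        b <- min(reads$end[victim], we) - ws + 1L
        local[a:b] <- local[a:b] - 1L
      }
    }
  }
  message("downsample_annotation_free: removed ", sum(drop), " of ",
          nrow(reads), " reads")
  reads[!drop, , drop = FALSE]
}
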
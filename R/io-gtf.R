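#' Read transcript models from a GTF file
#'
#' Builds the internal transcript table from the `exon` features of a GTF
#' (other feature types are ignored; transcripts are reassembled from their
#' exons). Coordinates are converted to the internal 0-based half-open
#' convention.
#'
#' @param path GTF file.
#' @param feature_types Feature types whose grouped ranges define transcripts.
#' @return Transcript data.frame: `tx_id`, `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, and list-column `exons` (n x 2 integer matrices, 0-based
#'   half-open, sorted by start).
#' @export
read_gtf <- function(path, feature_types = "exon") {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% feature_types]
  if (length(gr) == 0L) stop("no ", paste(feature_types, collapse = "/"),
                             " features in ", path)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    tx_id = gr$transcript_id,
    gene_id = gr$gene_id,
    stringsAsFactors = FALSE
  )
  transcript_table(df)
}

# Assemble the transcript table from a per-exon data.frame.
transcript_table <- function(exon_df) {
  ord <- order(exon_df$tx_id, exon_df$start)
  exon_df <- exon_df[ord, , drop = FALSE]
  idx <- split(seq_len(nrow(exon_df)), exon_df$tx_id)
  tx_id <- names(idx)
  first <- vapply(idx, `[`, integer(1), 1L)
  exons <- lapply(idx, function(i) {
    m <- cbind(start = as.integer(exon_df$start[i]),
               end = as.integer(exon_df$end[i]))
    check_interval(m[, 1], m[, 2], "exon")
    if (nrow(m) > 1 && any(m[-1, 1] < m[-nrow(m), 2])) {
      stop("overlapping exons in transcript ", exon_df$tx_id[i[1]])
    }
    m
  })
  out <- data.frame(
    tx_id = tx_id,
    gene_id = exon_df$gene_id[first],
    chrom = exon_df$chrom[first],
    start = vapply(exons, function(m) m[1, 1], integer(1)),
    end = vapply(exons, function(m) m[nrow(m), 2], integer(1)),
    strand = exon_df$strand[first],
    stringsAsFactors = FALSE
  )
  out$exons <- unname(exons)
  out <- out[order(out$chrom, out$start, out$tx_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write transcript models to GTF
#'
#' Emits `gene`, `transcript` and `exon` features with `gene_id` and
#' `transcript_id` attributes, 1-based inclusive coordinates and exons in
#' ascending genomic order regardless of strand. Transcripts are sorted by
#' chromosome then start, so output is byte-stable for a given model set.
#' Re-reading the file with [read_gtf()] reproduces the models.
#'
#' @param transcripts Transcript table (as from [read_gtf()]).
#' @param path Output file.
#' @param source Value of the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path, source = "isoforge") {
  n_ex <- vapply(transcripts$exons, nrow, integer(1))
  if (any(n_ex == 0L)) {
    stop("transcript without exons: ",
         transcripts$tx_id[which(n_ex == 0L)[1]])
  }
  tx <- transcripts[order(transcripts$chrom, transcripts$start,
                          transcripts$tx_id), , drop = FALSE]
  lines <- character(0)
  gene_first <- !duplicated(tx$gene_id)
  fmt <- function(chrom, feat, s, e, strand, attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, source, feat, s + 1L, e, strand, attrs)
  }
  # gene features: span over that gene's transcripts
  gspan <- lapply(split(seq_len(nrow(tx)), tx$gene_id), function(i) {
    c(min(tx$start[i]), max(tx$end[i]), i[1])
  })
  out <- vector("list", nrow(tx))
  for (i in seq_len(nrow(tx))) {
    blk <- character(0)
    if (gene_first[i]) {
      g <- gspan[[tx$gene_id[i]]]
      blk <- fmt(tx$chrom[i], "gene", g[1], g[2], tx$strand[i],
                 sprintf('gene_id "%s";', tx$gene_id[i]))
    }
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     tx$gene_id[i], tx$tx_id[i])
    blk <- c(blk, fmt(tx$chrom[i], "transcript", tx$start[i], tx$end[i],
                      tx$strand[i], attrs))
    ex <- tx$exons[[i]]
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    blk <- c(blk, fmt(tx$chrom[i], "exon", ex[, 1], ex[, 2],
                      tx$strand[i], attrs))
    out[[i]] <- blk
  }
  writeLines(unlist(out), path)
  invisible(path)
}

# Gene spans implied by a transcript table: one row per gene_id with the
# union span of its transcripts (0-based half-open).
annotation_genes <- function(transcripts) {
  idx <- split(seq_len(nrow(transcripts)), transcripts$gene_id)
  out <- data.frame(
    gene_id = names(idx),
    chrom = vapply(idx, function(i) transcripts$chrom[i[1]], character(1)),
    start = vapply(idx, function(i) min(transcripts$start[i]), integer(1)),
    end = vapply(idx, function(i) max(transcripts$end[i]), integer(1)),
    strand = vapply(idx, function(i) transcripts$strand[i[1]], character(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
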
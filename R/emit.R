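# Model assembly and output writers: exon structures from peak summits and
# intron chains, then GTF / FASTA / counts / pseudo-alignment emission.

#' Derive exon structures for retained isoforms
#'
#' Terminal coordinates are the TSS and PA peak summits; internal boundaries
#' come from the corrected intron chain. Isoforms whose summits are not
#' consistent with their chain (TSS summit not 5' of the first intron, PA
#' summit not 3' of the last) are dropped with a warning.
#'
#' @param isoforms Isoform table with `chain`, `tss_summit`, `pa_summit`,
#'   `chrom`, `strand`.
#' @return `isoforms` subset with list-column `exons` (0-based half-open,
#'   ascending) added.
#' @export
build_exon_structures <- function(isoforms) {
  n <- nrow(isoforms)
  exons <- vector("list", n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    chain <- decode_chain(isoforms$chain[i])
    left <- if (isoforms$strand[i] == "+") isoforms$tss_summit[i]
            else isoforms$pa_summit[i]
    right <- if (isoforms$strand[i] == "+") isoforms$pa_summit[i]
             else isoforms$tss_summit[i]
    if (nrow(chain) == 0L) {
      if (right < left) next
      exons[[i]] <- cbind(start = left, end = right + 1L)
      ok[i] <- TRUE
      next
    }
    if (left >= chain[1, 1] || right < chain[nrow(chain), 2]) next
    starts <- unname(c(left, chain[, 2]))
    ends <- unname(c(chain[, 1], right + 1L))
    m <- cbind(start = starts, end = ends)
    storage.mode(m) <- "integer"
    exons[[i]] <- m
    ok[i] <- TRUE
  }
  if (any(!ok)) {
    warning(sum(!ok), " isoform(s) dropped: peak summits inconsistent with ",
            "intron chain")
  }
  out <- isoforms[ok, , drop = FALSE]
  out$exons <- exons[ok]
  out
}

#' Write all pipeline outputs for a reconstruction result
#'
#' Emits `models.gtf`, `counts.tsv` (isoform x replicate read counts),
#' `rejects.tsv` (read id and rejection reason), `pseudo_alignments.txt`
#' (per-gene text rendering of isoform structures), and — when a genome is
#' supplied — `isoforms.fa` and `genes.fa`.
#'
#' @param result An `isoforge_result` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @param genome Optional `DNAStringSet` or FASTA path.
#' @return `out_dir`, invisibly.
#' @export
write_models <- function(result, out_dir, genome = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tx <- result$transcripts
  write_gtf(tx, file.path(out_dir, "models.gtf"))
  counts <- as.data.frame(result$isoforms$counts)
  counts <- cbind(isoform_id = result$isoforms$isoform_id,
                  gene_id = result$isoforms$gene_id, counts)
  counts <- counts[order(counts$isoform_id), , drop = FALSE]
  utils::write.table(counts, file.path(out_dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$rejects, file.path(out_dir, "rejects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(pseudo_alignments(result), file.path(out_dir,
                                                  "pseudo_alignments.txt"))
  if (!is.null(genome)) {
    write_isoform_fasta(tx, genome, file.path(out_dir, "isoforms.fa"))
    write_gene_fasta(result$genes, genome, file.path(out_dir, "genes.fa"))
  }
  invisible(out_dir)
}

#' Per-gene pseudo-alignment rendering
#'
#' One text block per gene: each isoform drawn over the gene span at a fixed
#' character width, exon blocks as `=`, introns as `-`, positions outside the
#' isoform blank, followed by the total read count.
#'
#' @param result An `isoforge_result`.
#' @param width Characters per gene span.
#' @return Character vector of output lines.
#' @export
pseudo_alignments <- function(result, width = 80L) {
  lines <- character(0)
  iso <- result$isoforms
  for (g in seq_len(nrow(result$genes))) {
    gene <- result$genes[g, ]
    at <- which(iso$gene_id == gene$gene_id)
    lines <- c(lines, sprintf("# gene %s %s:%d-%d(%s)", gene$gene_id,
                              gene$chrom, gene$start + 1L, gene$end,
                              gene$strand))
    scale <- width / max(1L, gene$end - gene$start)
    for (i in at) {
      row <- rep(" ", width)
      px <- function(p) {
        min(width, max(1L, as.integer(floor((p - gene$start) * scale)) + 1L))
      }
      ex <- iso$exons[[i]]
      row[px(ex[1, 1]):px(ex[nrow(ex), 2] - 1L)] <- "-"
      for (e in seq_len(nrow(ex))) row[px(ex[e, 1]):px(ex[e, 2] - 1L)] <- "="
      lines <- c(lines, sprintf("%s %s n=%d", paste(row, collapse = ""),
                                iso$isoform_id[i], iso$total[i]))
    }
  }
  lines
}
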
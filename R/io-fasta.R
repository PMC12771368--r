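# FASTA writers for reconstructed models. Sequences come from a
# Biostrings::DNAStringSet (or a FASTA path); minus-strand models are
# reverse-complemented so emitted sequences read 5'->3' in mRNA sense.

load_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  # headers may carry descriptions after the first token
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

spliced_sequence <- function(genome, chrom, exons, strand) {
  if (!chrom %in% names(genome)) {
    stop("chromosome absent from genome: ", chrom)
  }
  seq <- genome[[chrom]]
  parts <- Biostrings::DNAStringSet(Biostrings::Views(
    seq, start = exons[, 1] + 1L, end = exons[, 2]))
  res <- Biostrings::DNAString(paste(as.character(parts), collapse = ""))
  if (strand == "-") res <- Biostrings::reverseComplement(res)
  as.character(res)
}

#' Write isoform sequences to FASTA
#'
#' One record per transcript model: exon sequences concatenated in
#' transcription order (minus-strand models reverse-complemented). Headers
#' carry the isoform and gene identifiers.
#'
#' @param transcripts Transcript table (`tx_id`, `gene_id`, `chrom`,
#'   `strand`, list-column `exons`).
#' @param genome `DNAStringSet` or FASTA path containing every referenced
#'   chromosome.
#' @param path Output FASTA.
#' @return `path`, invisibly.
#' @export
write_isoform_fasta <- function(transcripts, genome, path) {
  genome <- load_genome(genome)
  seqs <- vapply(seq_len(nrow(transcripts)), function(i) {
    spliced_sequence(genome, transcripts$chrom[i], transcripts$exons[[i]],
                     transcripts$strand[i])
  }, character(1))
  names(seqs) <- paste0(transcripts$tx_id, " gene=", transcripts$gene_id)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write gene-span sequences to FASTA
#'
#' One record per gene: the unspliced genomic sequence of the gene span,
#' reverse-complemented for minus-strand genes.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @inheritParams write_isoform_fasta
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(genes, genome, path) {
  genome <- load_genome(genome)
  seqs <- vapply(seq_len(nrow(genes)), function(i) {
    spliced_sequence(genome, genes$chrom[i],
                     cbind(genes$start[i], genes$end[i]), genes$strand[i])
  }, character(1))
  names(seqs) <- genes$gene_id
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
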
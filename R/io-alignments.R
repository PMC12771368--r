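#' Read long-read alignments from SAM/BAM
#'
#' Streams raw alignment records, preserving read name, flags, mapping
#' position and CIGAR. Unmapped records are kept and flagged; mapped records
#' without a CIGAR string are skipped with a warning. SAM input is converted
#' on the fly.
#'
#' @param path SAM or BAM file.
#' @param replicate Replicate label attached to every record.
#' @return A data.frame with one row per alignment record: `read_id`,
#'   `replicate`, `chrom`, `pos` (0-based leftmost reference position, `NA`
#'   for unmapped), `strand`, `cigar`, `unmapped`, `secondary`,
#'   `supplementary`.
#' @export
read_alignments <- function(path, replicate = "rep1") {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- tryCatch(
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("failed to read SAM file ", path, ": ",
                               conditionMessage(e))
    )
  }
  res <- tryCatch(
    Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "strand", "pos", "cigar")))[[1]],
    error = function(e) stop("failed to read alignment file ", path, ": ",
                             conditionMessage(e))
  )
  flag <- res$flag
  out <- data.frame(
    read_id = res$qname,
    replicate = rep(replicate, length(res$qname)),
    chrom = as.character(res$rname),
    pos = ifelse(is.na(res$pos), NA_integer_, res$pos - 1L),
    strand = as.character(res$strand),
    cigar = res$cigar,
    unmapped = bitwAnd(flag, 0x4L) != 0L,
    secondary = bitwAnd(flag, 0x100L) != 0L,
    supplementary = bitwAnd(flag, 0x800L) != 0L,
    stringsAsFactors = FALSE
  )
  bad <- !out$unmapped & (is.na(out$cigar) | !nzchar(out$cigar))
  if (any(bad)) {
    warning(sum(bad), " mapped record(s) without CIGAR skipped in ", path)
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Keep reads with a single linear alignment
#'
#' A read survives iff it produced exactly one mapped record counting primary
#' and supplementary alignments together (no chimeric placement) and no
#' secondary records (no ambiguous locus). Survivors are converted to the
#' internal aligned-read table with strand taken from alignment orientation.
#'
#' @param alignments Record table from [read_alignments()] (several inputs may
#'   be `rbind`ed; read ids are treated per replicate).
#' @return AlignedRead data.frame: `read_id`, `replicate`, `chrom`, `start`,
#'   `end` (0-based half-open reference span), `strand`, `cigar`. Attribute
#'   `n_dropped` records the number of excluded reads.
#' @export
unique_alignment_filter <- function(alignments) {
  aln <- alignments[!alignments$unmapped, , drop = FALSE]
  if (nrow(aln) == 0L) {
    out <- empty_reads()
    out$cigar <- character(0)
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  key <- paste(aln$replicate, aln$read_id, sep = "\r")
  linear <- !aln$secondary          # primary + supplementary records
  n_linear <- tapply(linear, key, sum)
  n_secondary <- tapply(aln$secondary, key, sum)
  good_keys <- names(n_linear)[n_linear == 1L & n_secondary == 0L]
  keep <- key %in% good_keys & !aln$secondary & !aln$supplementary
  kept <- aln[keep, , drop = FALSE]
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(kept$cigar)
  out <- data.frame(
    read_id = kept$read_id, replicate = kept$replicate, chrom = kept$chrom,
    start = kept$pos, end = kept$pos + width, strand = kept$strand,
    cigar = kept$cigar, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_dropped") <- length(unique(key)) - length(good_keys)
  message("unique_alignment_filter: ", nrow(out), " of ",
          length(unique(key)), " reads retained")
  out
}

#' Align reads with an external splice-aware aligner
#'
#' Thin contract wrapper around the configured aligner: arguments are passed
#' verbatim, exit status is checked, and the SAM path is returned. Pipelines
#' that already have alignments skip this step.
#'
#' @param fastq Character vector of FASTQ paths.
#' @param genome Reference genome FASTA path.
#' @param out Output SAM path.
#' @param config A [pipeline_config()] (fields `aligner`, `aligner_args`).
#' @return `out`, invisibly.
#' @export
align_reads <- function(fastq, genome, out = tempfile(fileext = ".sam"),
                        config = pipeline_config()) {
  exe <- Sys.which(config$aligner)
  if (!nzchar(exe)) {
    stop("aligner executable not found on PATH: ", config$aligner)
  }
  args <- c(strsplit(config$aligner_args, "[[:space:]]+")[[1]], genome, fastq)
  err <- tempfile()
  status <- system2(exe, args, stdout = out, stderr = err)
  if (status != 0L) {
    stop(config$aligner, " exited with status ", status, ": ",
         paste(readLines(err, warn = FALSE), collapse = "\n"))
  }
  invisible(out)
}
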
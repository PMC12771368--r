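#' Assign read ends to TSS and PA peaks
#'
#' The strand-aware 5' position of each read is located in a five-prime peak
#' region and its 3' position in a three-prime peak region of the same
#' (chromosome, strand). Peak regions of one track are disjoint, so
#' membership is unambiguous. Reads whose 5' end falls in no TSS region are
#' rejected with reason `"no_tss"`; reads whose 3' end falls in no PA region
#' with reason `"no_pa"`.
#'
#' @param reads AlignedRead table.
#' @param tss_peaks Five-prime peak table from [call_clusters()].
#' @param pa_peaks Three-prime peak table.
#' @return `reads` with added columns `tss_peak`, `pa_peak`, `reject_reason`
#'   (`NA` for assigned reads).
#' @export
assign_ends <- function(reads, tss_peaks, pa_peaks) {
  p5 <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)
  p3 <- ifelse(reads$strand == "+", reads$end - 1L, reads$start)
  reads$tss_peak <- locate_in_peaks(reads$chrom, reads$strand, p5, tss_peaks)
  reads$pa_peak <- locate_in_peaks(reads$chrom, reads$strand, p3, pa_peaks)
  reads$reject_reason <- ifelse(is.na(reads$tss_peak), "no_tss",
                                ifelse(is.na(reads$pa_peak), "no_pa",
                                       NA_character_))
  n_rej <- sum(!is.na(reads$reject_reason))
  message("assign_ends: ", nrow(reads) - n_rej, " assigned, ", n_rej,
          " rejected")
  reads
}

# Peak id containing each position, or NA; peaks disjoint per (chrom,strand).
locate_in_peaks <- function(chrom, strand, pos, peaks) {
  res <- rep(NA_character_, length(pos))
  keys <- paste(chrom, strand, sep = "\r")
  pkeys <- paste(peaks$chrom, peaks$strand, sep = "\r")
  for (k in unique(keys)) {
    pi <- which(pkeys == k)
    qi <- which(keys == k)
    if (length(pi) == 0L) next
    pi <- pi[order(peaks$start[pi])]
    j <- findInterval(pos[qi], peaks$start[pi])
    inside <- j > 0L & pos[qi] < peaks$end[pi][pmax(j, 1L)]
    res[qi[inside]] <- peaks$peak_id[pi][j[inside]]
  }
  res
}

#' Group assigned reads into isoform candidates
#'
#' Grouping key: (TSS peak, exact intron chain, PA peak). Single-exon reads
#' have empty chains and group by end peaks alone. Per-replicate read counts
#' are tallied over the full replicate set of the input.
#'
#' @param reads Output of [assign_ends()] (rejected reads are ignored) with
#'   corrected intron chains in list-column `introns`.
#' @param replicates Replicate labels defining the count columns (defaults to
#'   labels present in `reads`).
#' @return Isoform-candidate data.frame: `tss_peak`, `pa_peak`, `chrom`,
#'   `strand`, `chain` (encoded intron chain), a `counts` matrix column
#'   (candidates x replicates), and `total`.
#' @export
group_reads <- function(reads, replicates = sort(unique(reads$replicate))) {
  ok <- reads[is.na(reads$reject_reason), , drop = FALSE]
  if (nrow(ok) == 0L) {
    out <- data.frame(tss_peak = character(0), pa_peak = character(0),
                      chrom = character(0), strand = character(0),
                      chain = character(0), stringsAsFactors = FALSE)
    out$counts <- matrix(integer(0), 0, length(replicates),
                         dimnames = list(NULL, replicates))
    out$total <- integer(0)
    return(out)
  }
  chains <- vapply(ok$introns, chain_key, character(1))
  key <- paste(ok$tss_peak, chains, ok$pa_peak, sep = "\r")
  idx <- split(seq_len(nrow(ok)), key)
  counts <- t(vapply(idx, function(i) {
    tab <- table(factor(ok$replicate[i], levels = replicates))
    as.integer(tab)
  }, integer(length(replicates))))
  colnames(counts) <- replicates
  first <- vapply(idx, `[`, integer(1), 1L)
  out <- data.frame(
    tss_peak = ok$tss_peak[first], pa_peak = ok$pa_peak[first],
    chrom = ok$chrom[first], strand = ok$strand[first],
    chain = chains[first], stringsAsFactors = FALSE
  )
  out$counts <- counts
  out$total <- as.integer(rowSums(counts))
  out <- out[order(out$chrom, out$strand, out$tss_peak, out$chain,
                   out$pa_peak), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replicate-concordance filter for isoform candidates
#'
#' A candidate is retained iff some replicate supports it with at least
#' `high_count` reads and a different replicate with at least `low_count`
#' reads.
#'
#' @param candidates Candidate table from [group_reads()].
#' @param high_count Read threshold for the anchor replicate.
#' @param low_count Read threshold for the confirming replicate.
#' @return The retained subset of `candidates`.
#' @export
filter_by_replicates <- function(candidates, high_count = 5L,
                                 low_count = 1L) {
  counts <- candidates$counts
  keep <- apply(counts, 1L, function(cc) {
    a <- which(cc >= high_count)
    b <- which(cc >= low_count)
    length(a) >= 1L && length(b) >= 1L &&
      !(length(a) == 1L && length(b) == 1L && a == b)
  })
  message("filter_by_replicates: ", sum(keep), " of ", nrow(candidates),
          " candidates retained")
  candidates[keep, , drop = FALSE]
}

# Span of an isoform for gene clustering: outer bounds of its two peak
# regions (leftmost region start to rightmost region end).
isoform_spans <- function(isoforms, tss_peaks, pa_peaks) {
  t_i <- match(isoforms$tss_peak, tss_peaks$peak_id)
  p_i <- match(isoforms$pa_peak, pa_peaks$peak_id)
  data.frame(
    start = pmin(tss_peaks$start[t_i], pa_peaks$start[p_i]),
    end = pmax(tss_peaks$end[t_i], pa_peaks$end[p_i]),
    tss_summit = tss_peaks$summit[t_i],
    pa_summit = pa_peaks$summit[p_i],
    tss_start = tss_peaks$start[t_i], tss_end = tss_peaks$end[t_i],
    pa_start = pa_peaks$start[p_i], pa_end = pa_peaks$end[p_i]
  )
}
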
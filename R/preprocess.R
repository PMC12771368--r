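#' Mean read quality on the Phred scale
#'
#' Per-base Phred+33 qualities are converted to error probabilities, averaged
#' over the read, and converted back to the Phred scale
#' (`-10 * log10(mean(p_err))`) — the whole-read pass/fail convention used for
#' nanopore reads.
#'
#' @param qual Character vector of Phred+33 quality strings.
#' @return Numeric vector of mean read qualities.
#' @export
mean_read_quality <- function(qual) {
  vapply(qual, function(q) {
    p <- 10^(-(utf8ToInt(q) - 33) / 10)
    -10 * log10(mean(p))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Filter a FASTQ file by whole-read mean quality
#'
#' Retains exactly the reads whose [mean_read_quality()] is at least
#' `quality_min`. The operation is idempotent.
#'
#' @param input Input FASTQ path.
#' @param output Output FASTQ path.
#' @param quality_min Minimum mean quality (Phred scale).
#' @return Invisibly, a list with `n_in`, `n_kept`, `output`.
#' @export
filter_reads_by_quality <- function(input, output,
                                    quality_min = pipeline_config()$quality_min) {
  fq <- read_fastq(input)
  keep <- mean_read_quality(fq$qual) >= quality_min
  write_fastq(fq$id[keep], fq$seq[keep], fq$qual[keep], output)
  message("filter_reads_by_quality: ", sum(keep), " of ", length(keep),
          " reads kept")
  invisible(list(n_in = length(keep), n_kept = sum(keep), output = output))
}

# Minimal 4-line FASTQ reader/writer (uncompressed, one fixture-scale file).
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
  id <- sub("^@", "", sub("\\s.*$", "", lines[c(TRUE, FALSE, FALSE, FALSE)]))
  seq <- lines[c(FALSE, TRUE, FALSE, FALSE)]
  qual <- lines[c(FALSE, FALSE, FALSE, TRUE)]
  bad <- nchar(seq) != nchar(qual)
  if (any(bad)) {
    stop("sequence/quality length mismatch for read ", id[which(bad)[1]])
  }
  list(id = id, seq = seq, qual = qual)
}

write_fastq <- function(id, seq, qual, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(id)) {
    writeLines(paste0("@", id, "\n", seq, "\n+\n", qual), con, sep = "\n")
  }
  invisible(path)
}

#' Trim poly(A) tails
#'
#' Implements 3'-adapter semantics for an adapter of `adapter_len` A's: the
#' best semi-global match of an A-run ending at (or overhanging) the 3' end
#' with per-length error rate at most `error_rate` and overlap at least
#' `min_overlap` is removed together with everything 3' of it. Among
#' admissible matches the one maximizing the number of matched A's is chosen;
#' ties go to the match with fewest errors (i.e. the latest start). Reads
#' without an admissible match are returned unchanged; the operation is
#' idempotent.
#'
#' @param seq Character vector of read sequences (mRNA sense, poly(A) at the
#'   3' end by the orientation-unified input contract).
#' @param adapter_len Adapter length (caps the match length).
#' @param error_rate Maximum fraction of non-A positions in the match.
#' @param min_overlap Minimum match length.
#' @return Character vector of trimmed sequences.
#' @export
trim_polya <- function(seq, adapter_len = 100L, error_rate = 0.1,
                       min_overlap = 3L) {
  vapply(seq, function(s) {
    L <- nchar(s)
    if (L < min_overlap) return(s)
    is_a <- strsplit(s, "", fixed = TRUE)[[1]] == "A"
    # suffix_a[i] = number of A's in s[i..L] (1-based)
    suffix_a <- rev(cumsum(rev(is_a)))
    starts <- max(1L, L - adapter_len + 1L):(L - min_overlap + 1L)
    len <- L - starts + 1L
    errs <- len - suffix_a[starts]
    ok <- errs <= error_rate * len
    if (!any(ok)) return(s)
    cand <- starts[ok]
    best_a <- max(suffix_a[cand])
    i <- max(cand[suffix_a[cand] == best_a])
    substr(s, 1L, i - 1L)
  }, character(1), USE.NAMES = FALSE)
}

#' Trim poly(A) tails in a FASTQ file
#'
#' Applies [trim_polya()] to every read, trimming quality strings to match;
#' reads left empty by trimming are dropped.
#'
#' @inheritParams filter_reads_by_quality
#' @inheritParams trim_polya
#' @return Invisibly, a list with `n_in`, `n_trimmed`, `n_kept`, `output`.
#' @export
trim_polya_fastq <- function(input, output, adapter_len = 100L,
                             error_rate = 0.1, min_overlap = 3L) {
  fq <- read_fastq(input)
  trimmed <- trim_polya(fq$seq, adapter_len, error_rate, min_overlap)
  qual <- substr(fq$qual, 1L, nchar(trimmed))
  keep <- nchar(trimmed) > 0L
  write_fastq(fq$id[keep], trimmed[keep], qual[keep], output)
  invisible(list(n_in = length(keep), n_trimmed = sum(trimmed != fq$seq),
                 n_kept = sum(keep), output = output))
}
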
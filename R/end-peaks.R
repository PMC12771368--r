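#' Strand-specific single-nucleotide read-end coverage
#'
#' For each read, exactly one position contributes per end type: on `+`
#' reads the 5' end is `start` and the 3' end is `end - 1`; on `-` reads the
#' 5' end is `end - 1` and the 3' end is `start`. Counts are aggregated per
#' (replicate, chromosome, strand, position); zero positions are absent.
#'
#' @param reads AlignedRead table.
#' @param end_type `"five_prime"` or `"three_prime"`.
#' @return data.frame `replicate`, `chrom`, `strand`, `pos`, `count`.
#' @export
end_coverage <- function(reads, end_type = c("five_prime", "three_prime")) {
  end_type <- match.arg(end_type)
  if (nrow(reads) == 0L) {
    return(data.frame(replicate = character(0), chrom = character(0),
                      strand = character(0), pos = integer(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  check_strand(reads$strand)
  five <- end_type == "five_prime"
  pos <- ifelse((reads$strand == "+") == five, reads$start, reads$end - 1L)
  key <- paste(reads$replicate, reads$chrom, reads$strand, pos, sep = "\r")
  agg <- table(key)
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  out <- data.frame(
    replicate = parts[, 1], chrom = parts[, 2], strand = parts[, 3],
    pos = as.integer(parts[, 4]), count = as.integer(agg),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$strand, out$pos, out$replicate), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pool replicate end-coverage tracks with a replicate-support filter
#'
#' A position survives iff it has nonzero count in at least
#' `support_min_replicates` replicates; surviving positions get pooled count
#' equal to the raw sum over replicates (no normalization). All other
#' positions are absent from the output.
#'
#' @param coverage Track from [end_coverage()] covering all replicates.
#' @param support_min_replicates Minimum number of supporting replicates.
#' @param replicates Replicate labels supplied to the experiment (defaults to
#'   the labels present in `coverage`); supplying fewer labels than
#'   `support_min_replicates` is a configuration error.
#' @return data.frame `chrom`, `strand`, `pos`, `pooled`, `support`.
#' @export
pool_with_support <- function(coverage, support_min_replicates = 2L,
                              replicates = unique(coverage$replicate)) {
  if (length(replicates) < support_min_replicates) {
    stop("support_min_replicates (", support_min_replicates,
         ") exceeds the number of replicates supplied (",
         length(replicates), ")")
  }
  if (nrow(coverage) == 0L) {
    return(data.frame(chrom = character(0), strand = character(0),
                      pos = integer(0), pooled = integer(0),
                      support = integer(0), stringsAsFactors = FALSE))
  }
  key <- paste(coverage$chrom, coverage$strand, coverage$pos, sep = "\r")
  pooled <- tapply(coverage$count, key, sum)
  support <- tapply(coverage$count > 0L, key, sum)
  parts <- do.call(rbind, strsplit(names(pooled), "\r", fixed = TRUE))
  out <- data.frame(
    chrom = parts[, 1], strand = parts[, 2], pos = as.integer(parts[, 3]),
    pooled = as.integer(pooled), support = as.integer(support),
    stringsAsFactors = FALSE
  )
  out <- out[out$support >= support_min_replicates, , drop = FALSE]
  out <- out[order(out$chrom, out$strand, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call end peaks by unidirectional clustering
#'
#' Candidate positions are those whose pooled count exceeds `pooled_cutoff`
#' (strictly, by default). Walking each (chromosome, strand) track
#' left-to-right, two consecutive candidates join the same cluster iff the
#' number of intervening non-candidate positions is smaller than
#' `merge_dist`. Each cluster becomes a peak spanning its first to last
#' candidate, with pooled count the sum over its candidate positions and
#' summit the candidate with maximal pooled count (ties: the 5'-most position
#' in transcription direction — smallest coordinate on `+`, largest on `-`).
#'
#' @param pooled Pooled track from [pool_with_support()].
#' @param pooled_cutoff Candidate cutoff on the pooled count.
#' @param merge_dist Maximum gap (non-candidate positions) inside a cluster.
#' @param end_type `"five_prime"` or `"three_prime"` (annotates peak ids).
#' @param raw Optional raw track from [end_coverage()]; when given,
#'   per-replicate counts over candidate positions are attached as a
#'   list-column `per_replicate`.
#' @param strict If `FALSE`, candidates use `>=` against the cutoff.
#' @return Peak data.frame: `peak_id`, `chrom`, `strand`, `end_type`,
#'   `start`, `end` (0-based half-open region), `summit`, `pooled_count`,
#'   `n_candidates`, and optionally `per_replicate`.
#' @export
call_clusters <- function(pooled, pooled_cutoff = 2L, merge_dist = 10L,
                          end_type = "five_prime", raw = NULL,
                          strict = TRUE) {
  cand <- if (strict) pooled[pooled$pooled > pooled_cutoff, , drop = FALSE]
          else pooled[pooled$pooled >= pooled_cutoff, , drop = FALSE]
  prefix <- if (end_type == "five_prime") "TSS" else "PA"
  if (nrow(cand) == 0L) return(empty_peaks(end_type, !is.null(raw)))
  cand <- cand[order(cand$chrom, cand$strand, cand$pos), , drop = FALSE]
  track <- paste(cand$chrom, cand$strand, sep = "\r")
  new_track <- track != c("", track[-length(track)])
  gap <- c(0L, diff(cand$pos)) - 1L
  cluster <- cumsum(new_track | gap >= merge_dist)
  idx <- split(seq_len(nrow(cand)), cluster)
  rows <- lapply(idx, function(i) {
    pos <- cand$pos[i]; val <- cand$pooled[i]
    strand <- cand$strand[i[1]]
    at_max <- pos[val == max(val)]
    summit <- if (strand == "+") min(at_max) else max(at_max)
    data.frame(chrom = cand$chrom[i[1]], strand = strand,
               end_type = end_type, start = min(pos), end = max(pos) + 1L,
               summit = summit, pooled_count = sum(val),
               n_candidates = length(i), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$peak_id <- paste0(prefix, "_", out$chrom, "_", out$strand, "_",
                        out$start)
  out <- out[, c("peak_id", "chrom", "strand", "end_type", "start", "end",
                 "summit", "pooled_count", "n_candidates")]
  if (!is.null(raw)) {
    reps <- sort(unique(raw$replicate))
    cand_key <- paste(cand$chrom, cand$strand, cand$pos, sep = "\r")
    raw_key <- paste(raw$chrom, raw$strand, raw$pos, sep = "\r")
    out$per_replicate <- lapply(idx, function(i) {
      sel <- raw_key %in% cand_key[i]
      v <- tapply(raw$count[sel], factor(raw$replicate[sel], levels = reps),
                  sum, default = 0L)
      as.integer(v) |> stats::setNames(reps)
    })
  }
  rownames(out) <- NULL
  out
}

empty_peaks <- function(end_type, with_reps = FALSE) {
  out <- data.frame(peak_id = character(0), chrom = character(0),
                    strand = character(0), end_type = character(0),
                    start = integer(0), end = integer(0), summit = integer(0),
                    pooled_count = integer(0), n_candidates = integer(0),
                    stringsAsFactors = FALSE)
  if (with_reps) out$per_replicate <- list()
  out
}

#' End-to-end peak calling for one end type
#'
#' Convenience wrapper: [end_coverage()] per replicate, replicate-support
#' pooling, then [call_clusters()], independently per (chromosome, strand).
#'
#' @inheritParams end_coverage
#' @param config A [pipeline_config()].
#' @param replicates Replicate labels supplied to the experiment.
#' @return Peak table (see [call_clusters()]).
#' @export
call_end_peaks <- function(reads, end_type, config = pipeline_config(),
                           replicates = unique(reads$replicate)) {
  cov <- end_coverage(reads, end_type)
  pooled <- pool_with_support(cov, config$support_min_replicates, replicates)
  call_clusters(pooled, config$pooled_cutoff, config$merge_dist,
                end_type = end_type, raw = cov, strict = config$strict_cutoff)
}

#' Write a peak table as BED6
#'
#' name = peak id, score = pooled count, and the summit recorded via the
#' thickStart/thickEnd columns.
#'
#' @param peaks Peak table from [call_clusters()].
#' @param path Output BED file.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  tab <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                    peaks$pooled_count, peaks$strand, peaks$summit,
                    peaks$summit + 1L)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an end-coverage or pooled track as bedGraph
#'
#' @param track Track from [end_coverage()] (column `count`) or
#'   [pool_with_support()] (column `pooled`); one (replicate, strand)
#'   selection per file is the caller's responsibility.
#' @param path Output bedGraph file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  val <- if ("count" %in% names(track)) track$count else track$pooled
  tab <- data.frame(track$chrom, track$pos, track$pos + 1L, val)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
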
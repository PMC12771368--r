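#' Extract intron candidates from a CIGAR string
#'
#' Returns one 0-based half-open reference interval per `N` operation.
#' `M`, `D`, `=`, `X` and `N` advance the reference cursor; `I`, `S`, `H`, `P`
#' do not.
#'
#' @param cigar CIGAR string.
#' @param pos 0-based reference start of the alignment.
#' @return n x 2 integer matrix (`start`, `end`), possibly 0-row.
#' @export
extract_introns <- function(cigar, pos) {
  introns_from_cigar(cigar, pos)[[1]]
}

# Vectorized N-gap extraction; returns a list of n x 2 matrices.
introns_from_cigar <- function(cigars, starts) {
  ok <- grepl("^([0-9]+[MIDNSHP=X])+$", cigars)
  if (any(!ok)) {
    stop("malformed CIGAR string: '", cigars[which(!ok)[1]], "'")
  }
  rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigars, pos = as.integer(starts) + 1L, ops = "N")
  st <- IRanges::start(rl)
  en <- IRanges::end(rl)
  lapply(seq_along(cigars), function(i) {
    m <- cbind(start = st[[i]] - 1L, end = en[[i]])
    storage.mode(m) <- "integer"
    m
  })
}

# Attach intron chains (from CIGAR) to an aligned-read table.
add_intron_chains <- function(reads) {
  if (nrow(reads) == 0L) {
    reads$introns <- list()
    return(reads)
  }
  reads$introns <- introns_from_cigar(reads$cigar, reads$start)
  reads
}

#' Build the reference junction set
#'
#' Junctions present in at least `min_samples` distinct source samples are
#' retained (duplicates within one sample count once) and indexed by
#' chromosome, sorted by donor coordinate, for tolerance queries.
#'
#' @param junctions Junction table from [read_star_junctions()] (columns
#'   `chrom`, `start`, `end`, `strand`, `sample`).
#' @param min_samples Minimum number of distinct supporting samples.
#' @return An object of class `junction_set`.
#' @export
build_junction_reference <- function(junctions, min_samples = 2L) {
  key <- paste(junctions$chrom, junctions$start, junctions$end, sep = "\r")
  dedup <- !duplicated(paste(key, junctions$sample, sep = "\r"))
  support <- table(key[dedup])
  first <- junctions[!duplicated(key), , drop = FALSE]
  first_key <- key[!duplicated(key)]
  first$support <- as.integer(support[first_key])
  keep <- first$support >= min_samples
  introns <- first[keep, c("chrom", "start", "end", "strand", "support"),
                   drop = FALSE]
  introns <- introns[order(introns$chrom, introns$start, introns$end), ,
                     drop = FALSE]
  rownames(introns) <- NULL
  by_chrom <- split(seq_len(nrow(introns)), introns$chrom)
  structure(list(introns = introns, by_chrom = by_chrom),
            class = "junction_set")
}

#' @export
print.junction_set <- function(x, ...) {
  cat("junction_set:", nrow(x$introns), "reference introns on",
      length(x$by_chrom), "chromosome(s)\n")
  invisible(x)
}

#' Derive a junction set from annotated transcripts
#'
#' The implied introns (gaps between consecutive exons) of an annotation are
#' treated as a single source sample that always passes the support rule.
#'
#' @param transcripts Transcript table (as from [read_gtf()]).
#' @return A `junction_set`.
#' @export
junctions_from_annotation <- function(transcripts) {
  rows <- lapply(seq_len(nrow(transcripts)), function(i) {
    ex <- transcripts$exons[[i]]
    if (nrow(ex) < 2L) return(NULL)
    data.frame(chrom = transcripts$chrom[i],
               start = ex[-nrow(ex), 2], end = ex[-1, 1],
               strand = transcripts$strand[i], sample = "annotation",
               stringsAsFactors = FALSE)
  })
  build_junction_reference(do.call(rbind, rows), min_samples = 1L)
}

# All reference introns on `chrom` with |donor - start| <= tol and
# |acceptor - end| <= tol; returns row indices into jset$introns.
junction_candidates <- function(jset, chrom, start, end, tol) {
  idx <- jset$by_chrom[[chrom]]
  if (is.null(idx)) return(integer(0))
  donors <- jset$introns$start[idx]
  lo <- findInterval(start - tol - 0.5, donors) + 1L
  hi <- findInterval(start + tol + 0.5, donors)
  if (lo > hi) return(integer(0))
  cand <- idx[lo:hi]
  cand[abs(jset$introns$end[cand] - end) <= tol]
}

#' Correct an intron chain against reference junctions
#'
#' Each gap is considered independently: reference introns on the same
#' chromosome with both boundaries within `tolerance` of the gap's boundaries
#' are candidates; the candidate minimizing total boundary displacement
#' (ties: smaller donor, then smaller acceptor) replaces the gap. Gaps with no
#' candidate are treated as deletions and removed from the chain. Finally the
#' chain is re-checked for sortedness/non-overlap and any replacement that
#' would overlap its neighbour is dropped.
#'
#' @param chain n x 2 integer matrix of gap intervals, sorted by start.
#' @param chrom Chromosome of the chain.
#' @param jset A `junction_set` from [build_junction_reference()].
#' @param tolerance Maximum per-boundary displacement (bp).
#' @return The corrected chain, with attributes `n_replaced`, `n_removed`,
#'   `n_overlap_dropped`.
#' @export
correct_introns <- function(chain, chrom, jset, tolerance = 10L) {
  n_replaced <- 0L; n_removed <- 0L; n_overlap <- 0L
  out <- matrix(integer(0), ncol = 2)
  if (!is.null(chain) && nrow(chain) > 0L) {
    res <- vector("list", nrow(chain))
    for (g in seq_len(nrow(chain))) {
      cand <- junction_candidates(jset, chrom, chain[g, 1], chain[g, 2],
                                  tolerance)
      if (length(cand) == 0L) {
        n_removed <- n_removed + 1L
        next
      }
      cs <- jset$introns$start[cand]
      ce <- jset$introns$end[cand]
      disp <- abs(cs - chain[g, 1]) + abs(ce - chain[g, 2])
      best <- cand[order(disp, cs, ce)][1]
      if (jset$introns$start[best] != chain[g, 1] ||
          jset$introns$end[best] != chain[g, 2]) {
        n_replaced <- n_replaced + 1L
      }
      res[[g]] <- c(jset$introns$start[best], jset$introns$end[best])
    }
    res <- res[!vapply(res, is.null, logical(1))]
    if (length(res)) {
      m <- do.call(rbind, res)
      keep <- logical(nrow(m))
      last_end <- -1L
      for (g in seq_len(nrow(m))) {
        if (m[g, 1] >= last_end) {
          keep[g] <- TRUE
          last_end <- m[g, 2]
        } else {
          n_overlap <- n_overlap + 1L
        }
      }
      out <- m[keep, , drop = FALSE]
    }
  }
  colnames(out) <- c("start", "end")
  storage.mode(out) <- "integer"
  structure(out, n_replaced = n_replaced, n_removed = n_removed,
            n_overlap_dropped = n_overlap)
}

#' Correct the intron chains of an aligned-read table
#'
#' Applies [correct_introns()] to every read; correction statistics are
#' aggregated and reported.
#'
#' @param reads AlignedRead table with list-column `introns`.
#' @inheritParams correct_introns
#' @return `reads` with corrected `introns`; attribute `correction_stats`
#'   holds the totals.
#' @export
correct_read_introns <- function(reads, jset, tolerance = 10L) {
  stats <- c(n_gaps = 0L, n_replaced = 0L, n_removed = 0L,
             n_overlap_dropped = 0L)
  if (nrow(reads)) {
    for (i in seq_len(nrow(reads))) {
      ch <- reads$introns[[i]]
      stats["n_gaps"] <- stats["n_gaps"] + NROW(ch)
      cc <- correct_introns(ch, reads$chrom[i], jset, tolerance)
      stats["n_replaced"] <- stats["n_replaced"] + attr(cc, "n_replaced")
      stats["n_removed"] <- stats["n_removed"] + attr(cc, "n_removed")
      stats["n_overlap_dropped"] <-
        stats["n_overlap_dropped"] + attr(cc, "n_overlap_dropped")
      attributes(cc) <- attributes(cc)["dim"]
      colnames(cc) <- c("start", "end")
      reads$introns[[i]] <- cc
    }
  }
  message("correct_read_introns: ", stats["n_replaced"], " replaced, ",
          stats["n_removed"], " removed of ", stats["n_gaps"], " gaps")
  attr(reads, "correction_stats") <- stats
  reads
}
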
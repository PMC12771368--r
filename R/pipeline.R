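#' Reconstruct full-length isoforms from aligned long reads
#'
#' Runs the core reconstruction on uniquely aligned reads: optional splice
#' correction against a reference junction set, optional downsampling of
#' highly expressed genes/regions, strand-specific TSS and PA peak calling
#' with a replicate-support filter, read-to-peak assignment, grouping into
#' isoforms, the replicate-concordance filter, gene clustering, gene naming
#' from the annotation, and (optionally) the minor-isoform filter.
#'
#' @param reads AlignedRead table (columns `read_id`, `replicate`, `chrom`,
#'   `start`, `end`, `strand` and either `cigar` or list-column `introns`),
#'   e.g. from [unique_alignment_filter()] or [simulate_reads()].
#' @param config A [pipeline_config()].
#' @param annotation Optional transcript table (from [read_gtf()]); used for
#'   annotated downsampling and gene naming.
#' @param junctions Optional reference junctions: a `junction_set`, a
#'   junction table (from [read_star_junctions()]), or `NULL` to skip splice
#'   correction.
#' @param downsample Enable the downsampling module (annotated mode when an
#'   annotation is given, else annotation-free).
#' @param extra_filter_iso Enable the minor-isoform (1 percent of major)
#'   filter.
#' @param seed Seed for the downsampling RNG streams.
#' @return An object of class `isoforge_result`: list with `isoforms`,
#'   `transcripts`, `genes`, `tss_peaks`, `pa_peaks`, `rejects`, `stats`,
#'   `config`.
#' @export
run_pipeline <- function(reads, config = pipeline_config(),
                         annotation = NULL, junctions = NULL,
                         downsample = FALSE, extra_filter_iso = FALSE,
                         seed = 1L) {
  stopifnot(is.data.frame(reads))
  check_strand(reads$strand)
  replicates <- sort(unique(reads$replicate))
  stats <- list(n_reads = nrow(reads), n_replicates = length(replicates))

  if (!"introns" %in% names(reads)) reads <- add_intron_chains(reads)

  if (!is.null(junctions)) {
    jset <- if (inherits(junctions, "junction_set")) junctions
            else build_junction_reference(junctions,
                                          config$junction_min_samples)
    reads <- correct_read_introns(reads, jset, config$splice_tolerance_bp)
    stats$correction <- attr(reads, "correction_stats")
  }

  if (downsample) {
    reads <- if (!is.null(annotation)) {
      downsample_annotated(reads, annotation_genes(annotation),
                           cap = config$downsample_cap,
                           min_gene_reads = config$min_gene_reads,
                           seed = seed)
    } else {
      downsample_annotation_free(reads, cap = config$downsample_cap,
                                 seed = seed)
    }
    stats$n_after_downsample <- nrow(reads)
  }

  tss_peaks <- call_end_peaks(reads, "five_prime", config, replicates)
  pa_peaks <- call_end_peaks(reads, "three_prime", config, replicates)
  stats$n_tss_peaks <- nrow(tss_peaks)
  stats$n_pa_peaks <- nrow(pa_peaks)

  assigned <- assign_ends(reads, tss_peaks, pa_peaks)
  rejects <- data.frame(
    read_id = assigned$read_id[!is.na(assigned$reject_reason)],
    replicate = assigned$replicate[!is.na(assigned$reject_reason)],
    reason = assigned$reject_reason[!is.na(assigned$reject_reason)],
    stringsAsFactors = FALSE
  )
  stats$n_assigned <- nrow(assigned) - nrow(rejects)
  stats$n_rejected <- nrow(rejects)

  cands <- group_reads(assigned, replicates)
  stats$n_candidates <- nrow(cands)
  iso <- filter_by_replicates(cands, config$high_count, config$low_count)
  stats$n_isoforms_concordant <- nrow(iso)

  spans <- isoform_spans(iso, tss_peaks, pa_peaks)
  iso$span_start <- spans$start
  iso$span_end <- spans$end
  iso$tss_summit <- spans$tss_summit
  iso$pa_summit <- spans$pa_summit

  cl <- cluster_genes(iso, config$gene_overlap_frac)
  genes <- assign_gene_ids(cl$genes,
                           if (!is.null(annotation))
                             annotation_genes(annotation) else NULL,
                           config$gene_overlap_frac)
  iso$gene_id <- genes$gene_id[cl$membership]

  if (extra_filter_iso) {
    keep <- filter_minor_isoforms(iso, cl$membership, config$minor_frac)
    iso <- iso[keep, , drop = FALSE]
    membership <- cl$membership[keep]
    # recompute gene spans and isoform counts after the filter
    genes <- genes[genes$gene_id %in% iso$gene_id, , drop = FALSE]
    for (g in seq_len(nrow(genes))) {
      at <- iso$gene_id == genes$gene_id[g]
      genes$start[g] <- min(iso$span_start[at])
      genes$end[g] <- max(iso$span_end[at])
      genes$n_isoforms[g] <- sum(at)
    }
  }
  stats$n_isoforms <- nrow(iso)
  stats$n_genes <- nrow(genes)

  # stable isoform ids: per gene, descending total count then coordinates
  iso <- iso[order(iso$gene_id, -iso$total, iso$tss_summit, iso$chain,
                   iso$pa_summit), , drop = FALSE]
  rank <- stats::ave(seq_len(nrow(iso)), iso$gene_id, FUN = seq_along)
  iso$isoform_id <- paste0(iso$gene_id, ".i", rank)

  iso <- build_exon_structures(iso)
  transcripts <- data.frame(
    tx_id = iso$isoform_id, gene_id = iso$gene_id, chrom = iso$chrom,
    start = vapply(iso$exons, function(m) m[1, 1], integer(1)),
    end = vapply(iso$exons, function(m) m[nrow(m), 2], integer(1)),
    strand = iso$strand, stringsAsFactors = FALSE
  )
  transcripts$exons <- iso$exons
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  rownames(iso) <- NULL

  structure(list(isoforms = iso, transcripts = transcripts, genes = genes,
                 tss_peaks = tss_peaks, pa_peaks = pa_peaks,
                 rejects = rejects, stats = stats, config = config),
            class = "isoforge_result")
}

#' @export
print.isoforge_result <- function(x, ...) {
  s <- x$stats
  cat("Isoform reconstruction result\n")
  cat("  input reads:     ", s$n_reads, " in ", s$n_replicates,
      " replicate(s)\n", sep = "")
  cat("  TSS / PA peaks:  ", s$n_tss_peaks, " / ", s$n_pa_peaks, "\n",
      sep = "")
  cat("  assigned reads:  ", s$n_assigned, " (", s$n_rejected,
      " rejected)\n", sep = "")
  cat("  isoforms:        ", s$n_isoforms, " in ", s$n_genes, " gene(s)\n",
      sep = "")
  invisible(x)
}

#' Summits and chains of reconstructed isoforms for evaluation
#'
#' Flattens an `isoforge_result` into the prediction table consumed by
#' [match_points()] and [match_peaks()]: summits as boundary points, native
#' peak regions, and the number of replicates in which each isoform was
#' detected.
#'
#' @param result An `isoforge_result`.
#' @return Prediction data.frame (`id`, `chrom`, `strand`, `chain`, `p5`,
#'   `p3`, `r5_start`, `r5_end`, `r3_start`, `r3_end`, `n_replicates`).
#' @export
as_predictions <- function(result) {
  iso <- result$isoforms
  spans <- isoform_spans(iso, result$tss_peaks, result$pa_peaks)
  data.frame(
    id = iso$isoform_id, chrom = iso$chrom, strand = iso$strand,
    chain = iso$chain, p5 = iso$tss_summit, p3 = iso$pa_summit,
    r5_start = spans$tss_start, r5_end = spans$tss_end,
    r3_start = spans$pa_start, r3_end = spans$pa_end,
    n_replicates = as.integer(rowSums(iso$counts > 0L)),
    stringsAsFactors = FALSE
  )
}
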
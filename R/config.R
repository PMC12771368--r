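#' Pipeline configuration
#'
#' Collects every tunable threshold of the reconstruction pipeline in one
#' validated object. All coordinates handled by the package are 0-based
#' half-open internally; 1-based inclusive coordinates appear only at GTF and
#' junction-file boundaries.
#'
#' @param splice_tolerance_bp Maximum distance (bp) between an alignment gap
#'   boundary and a reference junction boundary for the gap to be corrected.
#' @param downsample_cap Maximum read count per gene (annotated mode) or
#'   maximum per-base coverage (annotation-free mode) before random removal.
#' @param min_gene_reads Genes with fewer attributed reads are ignored by the
#'   annotated downsampling module.
#' @param support_min_replicates A read-end position must be covered in at
#'   least this many replicates to enter the pooled track.
#' @param pooled_cutoff Pooled-count cutoff for peak candidate positions; the
#'   comparison is strict (count must exceed the cutoff).
#' @param merge_dist Two candidate positions join the same peak when the
#'   number of intervening non-candidate positions is smaller than this.
#' @param high_count An isoform needs at least this many reads in one
#'   replicate.
#' @param low_count ...and at least this many reads in a second replicate.
#' @param gene_overlap_frac Fraction of the shorter span that must be shared
#'   for two isoforms (or a gene and an annotated gene) to be joined.
#' @param minor_frac An isoform is kept only if its read count exceeds this
#'   fraction of the gene's major isoform count (when the extra isoform
#'   filter is enabled).
#' @param quality_min Minimum whole-read mean quality (Phred scale, mean taken
#'   in error-probability space).
#' @param polya_adapter_len Length of the poly(A) adapter used for 3' tail
#'   trimming.
#' @param polya_error_rate Maximum per-length error rate of a poly(A) match.
#' @param polya_min_overlap Minimum matched tail length.
#' @param junction_min_samples A junction must appear in at least this many
#'   distinct samples to enter the reference junction set.
#' @param aligner External aligner executable name.
#' @param aligner_args Arguments passed verbatim to the aligner.
#' @param strict_cutoff If `FALSE`, peak candidates use `>=` instead of the
#'   default strict `>` comparison against `pooled_cutoff`.
#'
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(splice_tolerance_bp = 10L,
                            downsample_cap = 1000L,
                            min_gene_reads = 5L,
                            support_min_replicates = 2L,
                            pooled_cutoff = 2L,
                            merge_dist = 10L,
                            high_count = 5L,
                            low_count = 1L,
                            gene_overlap_frac = 0.8,
                            minor_frac = 0.01,
                            quality_min = 7,
                            polya_adapter_len = 100L,
                            polya_error_rate = 0.1,
                            polya_min_overlap = 3L,
                            junction_min_samples = 2L,
                            aligner = "minimap2",
                            aligner_args = "-ax splice -k14 -uf -G 10k",
                            strict_cutoff = TRUE) {
  cfg <- list(
    splice_tolerance_bp = as.integer(splice_tolerance_bp),
    downsample_cap = as.integer(downsample_cap),
    min_gene_reads = as.integer(min_gene_reads),
    support_min_replicates = as.integer(support_min_replicates),
    pooled_cutoff = as.integer(pooled_cutoff),
    merge_dist = as.integer(merge_dist),
    high_count = as.integer(high_count),
    low_count = as.integer(low_count),
    gene_overlap_frac = gene_overlap_frac,
    minor_frac = minor_frac,
    quality_min = quality_min,
    polya_adapter_len = as.integer(polya_adapter_len),
    polya_error_rate = polya_error_rate,
    polya_min_overlap = as.integer(polya_min_overlap),
    junction_min_samples = as.integer(junction_min_samples),
    aligner = aligner,
    aligner_args = aligner_args,
    strict_cutoff = isTRUE(strict_cutoff)
  )
  counts <- c("splice_tolerance_bp", "downsample_cap", "min_gene_reads",
              "support_min_replicates", "pooled_cutoff", "merge_dist",
              "high_count", "low_count", "polya_adapter_len",
              "polya_min_overlap", "junction_min_samples")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0L) {
      stop("configuration field '", nm, "' must be a non-negative integer")
    }
  }
  for (nm in c("gene_overlap_frac", "minor_frac", "polya_error_rate")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop("configuration field '", nm, "' must be a fraction in [0, 1]")
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Isoform reconstruction pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read key=value overrides for a configuration
#'
#' Lines of the form `key = value` (or `key=value`) override the matching
#' [pipeline_config()] default; blank lines and `#` comments are skipped.
#'
#' @param path Path to a plain-text configuration file.
#' @param base Configuration to override (defaults from [pipeline_config()]).
#' @return A `pipeline_config` object.
#' @export
read_config_file <- function(path, base = pipeline_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- as.list(base)
  class(args) <- NULL
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed configuration line: '", ln, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(args)) stop("unknown configuration key: '", key, "'")
    args[[key]] <- if (is.character(args[[key]])) val else as.numeric(val)
  }
  do.call(pipeline_config, args)
}
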
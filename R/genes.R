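#' Cluster isoforms into genes
#'
#' Two isoforms on the same chromosome and strand are related when their span
#' overlap is at least `gene_overlap_frac` of the shorter span; genes are the
#' connected components of this relation (union-find), with gene span the
#' componentwise min/max.
#'
#' @param isoforms Isoform table carrying `chrom`, `strand`, `span_start`,
#'   `span_end` columns.
#' @param gene_overlap_frac Required fraction of the shorter span.
#' @return A list: `gene` (data.frame `gene_idx`, `chrom`, `start`, `end`,
#'   `strand`, `n_isoforms`) and `membership` (gene index per isoform row).
#' @export
cluster_genes <- function(isoforms, gene_overlap_frac = 0.8) {
  n <- nrow(isoforms)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keys <- paste(isoforms$chrom, isoforms$strand, sep = "\r")
  for (k in unique(keys)) {
    idx <- which(keys == k)
    if (length(idx) < 2L) next
    s <- isoforms$span_start[idx]; e <- isoforms$span_end[idx]
    len <- e - s
    for (a in seq_along(idx)[-1]) {
      for (b in seq_len(a - 1L)) {
        ov <- overlap_len(s[a], e[a], s[b], e[b])
        if (ov >= gene_overlap_frac * min(len[a], len[b])) {
          ra <- find(idx[a]); rb <- find(idx[b])
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  gene_idx <- match(roots, unique(roots))
  comp <- split(seq_len(n), gene_idx)
  gene <- data.frame(
    gene_idx = seq_along(comp),
    chrom = vapply(comp, function(i) isoforms$chrom[i[1]], character(1)),
    start = vapply(comp, function(i) min(isoforms$span_start[i]), integer(1)),
    end = vapply(comp, function(i) max(isoforms$span_end[i]), integer(1)),
    strand = vapply(comp, function(i) isoforms$strand[i[1]], character(1)),
    n_isoforms = lengths(comp),
    stringsAsFactors = FALSE
  )
  rownames(gene) <- NULL
  list(genes = gene, membership = gene_idx)
}

#' Name reconstructed genes from an annotation
#'
#' A reconstructed gene takes the id of an annotated gene on the same strand
#' when their overlap is at least `gene_overlap_frac` of the shorter gene;
#' among several such candidates the one with maximal absolute overlap wins
#' (ties: lexicographic id). Genes without a candidate get a stable
#' coordinate-derived novel id.
#'
#' @param genes Gene table from [cluster_genes()].
#' @param annotation Annotated gene table ([annotation_genes()]) or `NULL`.
#' @param gene_overlap_frac Required fraction of the shorter gene.
#' @return `genes` with columns `gene_id` and `annotation_id` (NA when
#'   novel).
#' @export
assign_gene_ids <- function(genes, annotation = NULL,
                            gene_overlap_frac = 0.8) {
  novel <- paste0("IFG_", genes$chrom, "_", genes$start, "_",
                  ifelse(genes$strand == "+", "p", "m"))
  genes$annotation_id <- NA_character_
  if (!is.null(annotation) && nrow(annotation) > 0L) {
    for (i in seq_len(nrow(genes))) {
      cand <- which(annotation$chrom == genes$chrom[i] &
                    annotation$strand == genes$strand[i])
      if (length(cand) == 0L) next
      ov <- overlap_len(genes$start[i], genes$end[i],
                        annotation$start[cand], annotation$end[cand])
      shorter <- pmin(genes$end[i] - genes$start[i],
                      annotation$end[cand] - annotation$start[cand])
      pass <- ov >= gene_overlap_frac * shorter & ov > 0L
      if (!any(pass)) next
      cand <- cand[pass]; ov <- ov[pass]
      best <- cand[order(-ov, annotation$gene_id[cand])][1]
      genes$annotation_id[i] <- annotation$gene_id[best]
    }
  }
  genes$gene_id <- ifelse(is.na(genes$annotation_id), novel,
                          genes$annotation_id)
  # several reconstructed genes may map to one annotated gene; disambiguate
  dup <- duplicated(genes$gene_id) | duplicated(genes$gene_id, fromLast = TRUE)
  if (any(dup)) {
    for (g in unique(genes$gene_id[dup])) {
      at <- which(genes$gene_id == g)
      genes$gene_id[at] <- paste0(g, ".", seq_along(at))
    }
  }
  genes
}

#' Drop minor isoforms of each gene
#'
#' Within a gene, the isoform with the highest total read count is major
#' (ties: all tied isoforms are major); every other isoform is kept only if
#' its total count strictly exceeds `minor_frac` of the major count.
#'
#' @param isoforms Isoform table with `total` counts.
#' @param membership Gene index per isoform row (from [cluster_genes()]).
#' @param minor_frac Minor-isoform fraction of the major count.
#' @return Logical keep vector over isoform rows.
#' @export
filter_minor_isoforms <- function(isoforms, membership, minor_frac = 0.01) {
  keep <- logical(nrow(isoforms))
  for (g in unique(membership)) {
    at <- which(membership == g)
    major <- max(isoforms$total[at])
    keep[at] <- isoforms$total[at] == major |
      isoforms$total[at] > minor_frac * major
  }
  keep
}
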
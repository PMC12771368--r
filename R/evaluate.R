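#' Etalon boundary points and intron chains of an annotation
#'
#' Converts a truth transcript table to the evaluation layout: strand-aware
#' 5'/3' boundary points and the encoded intron chain.
#'
#' @param transcripts Transcript table.
#' @return data.frame `id`, `chrom`, `strand`, `chain`, `p5`, `p3`.
#' @export
etalon_points <- function(transcripts) {
  chains <- vapply(seq_len(nrow(transcripts)), function(i) {
    ex <- transcripts$exons[[i]]
    if (nrow(ex) < 2L) return("")
    chain_key(cbind(ex[-nrow(ex), 2], ex[-1, 1]))
  }, character(1))
  plus <- transcripts$strand == "+"
  data.frame(
    id = transcripts$tx_id, chrom = transcripts$chrom,
    strand = transcripts$strand, chain = chains,
    p5 = ifelse(plus, transcripts$start, transcripts$end - 1L),
    p3 = ifelse(plus, transcripts$end - 1L, transcripts$start),
    stringsAsFactors = FALSE
  )
}

eval_report <- function(tp, fp, fn, matches) {
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, matches = matches),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "evaluation: TP %d, FP %d, FN %d | precision %.3f recall %.3f F1 %.3f\n",
    x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

filter_min_replicates <- function(pred, min_replicates) {
  if ("n_replicates" %in% names(pred) && min_replicates > 0L) {
    pred[pred$n_replicates >= min_replicates, , drop = FALSE]
  } else {
    if (min_replicates > 0L && !"n_replicates" %in% names(pred)) {
      warning("predictions carry no replicate information; ",
              "the two-replicate restriction is skipped")
    }
    pred
  }
}

#' Points-mode transcript evaluation
#'
#' A prediction is a true positive iff some etalon transcript on the same
#' chromosome and strand has the identical intron chain and identical 5' and
#' 3' points. Each etalon matches at most one prediction (greedy in
#' prediction order; exact duplicates become false positives). When the
#' prediction table carries per-replicate detection counts, only predictions
#' detected in at least `min_replicates` replicates are evaluated.
#'
#' @param pred Prediction table (`chrom`, `strand`, `chain`, `p5`, `p3`,
#'   optionally `id`, `n_replicates`), e.g. from [as_predictions()].
#' @param truth Etalon table from [etalon_points()].
#' @param min_replicates Replicate-detection restriction (0 disables).
#' @return An `eval_report`: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`
#'   and the per-prediction match table.
#' @export
match_points <- function(pred, truth, min_replicates = 2L) {
  pred <- filter_min_replicates(pred, min_replicates)
  tkey <- paste(truth$chrom, truth$strand, truth$chain, truth$p5, truth$p3,
                sep = "\r")
  pkey <- paste(pred$chrom, pred$strand, pred$chain, pred$p5, pred$p3,
                sep = "\r")
  avail <- lapply(split(seq_len(nrow(truth)), tkey), as.list)
  matched <- rep(NA_character_, nrow(pred))
  for (i in seq_along(pkey)) {
    slot <- avail[[pkey[i]]]
    if (!is.null(slot) && length(slot) > 0L) {
      matched[i] <- truth$id[slot[[1]]]
      avail[[pkey[i]]] <- slot[-1]
    }
  }
  tp <- sum(!is.na(matched))
  matches <- data.frame(
    pred_id = if ("id" %in% names(pred)) pred$id else as.character(seq_along(pkey)),
    etalon_id = matched, mode = rep("points", length(matched)),
    stringsAsFactors = FALSE)
  eval_report(tp, nrow(pred) - tp, nrow(truth) - tp, matches)
}

#' Peaks-mode transcript evaluation
#'
#' A prediction is a true positive iff some etalon transcript on the same
#' chromosome and strand has the identical intron chain, its 5' point inside
#' the predicted 5' region and its 3' point inside the predicted 3' region.
#' Predictions with native peak regions (`r5_start`..`r3_end` columns) are
#' used as-is; point-only predictions are expanded to `[point - N/2,
#' point + N/2]` where `N` is the per-gene maximal peak length from a
#' reference reconstruction (`halfwidth_by_gene`), the gene being the one
#' whose span intersects more than 10 percent of the prediction's span.
#' Predictions overlapping no gene get halfwidth 0.
#'
#' @inheritParams match_points
#' @param halfwidth_by_gene Named vector of per-gene maximal peak lengths
#'   (see [peak_halfwidths()]); only needed for point-only predictions.
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`, `strand`)
#'   used for the >10 percent span assignment of point-only predictions.
#' @return An `eval_report`.
#' @export
match_peaks <- function(pred, truth, min_replicates = 2L,
                        halfwidth_by_gene = NULL, genes = NULL) {
  pred <- filter_min_replicates(pred, min_replicates)
  if (!all(c("r5_start", "r5_end", "r3_start", "r3_end") %in% names(pred))) {
    pred <- expand_point_predictions(pred, halfwidth_by_gene, genes)
  }
  grp_t <- paste(truth$chrom, truth$strand, truth$chain, sep = "\r")
  grp_p <- paste(pred$chrom, pred$strand, pred$chain, sep = "\r")
  used <- rep(FALSE, nrow(truth))
  tidx <- split(seq_len(nrow(truth)), grp_t)
  matched <- rep(NA_character_, nrow(pred))
  for (i in seq_len(nrow(pred))) {
    cand <- tidx[[grp_p[i]]]
    if (is.null(cand)) next
    for (j in cand) {
      if (used[j]) next
      if (truth$p5[j] >= pred$r5_start[i] && truth$p5[j] < pred$r5_end[i] &&
          truth$p3[j] >= pred$r3_start[i] && truth$p3[j] < pred$r3_end[i]) {
        used[j] <- TRUE
        matched[i] <- truth$id[j]
        break
      }
    }
  }
  tp <- sum(!is.na(matched))
  matches <- data.frame(
    pred_id = if ("id" %in% names(pred)) pred$id else as.character(seq_len(nrow(pred))),
    etalon_id = matched, mode = rep("peaks", length(matched)),
    stringsAsFactors = FALSE)
  eval_report(tp, nrow(pred) - tp, nrow(truth) - tp, matches)
}

# Expand point-only predictions to peak regions via per-gene halfwidths.
expand_point_predictions <- function(pred, halfwidth_by_gene, genes) {
  n <- rep(0L, nrow(pred))
  if (!is.null(halfwidth_by_gene) && !is.null(genes) && nrow(pred) > 0L) {
    ps <- pmin(pred$p5, pred$p3)
    pe <- pmax(pred$p5, pred$p3) + 1L
    for (i in seq_len(nrow(pred))) {
      cand <- which(genes$chrom == pred$chrom[i] &
                    genes$strand == pred$strand[i])
      if (length(cand) == 0L) next
      ov <- overlap_len(ps[i], pe[i], genes$start[cand], genes$end[cand])
      frac <- ov / (pe[i] - ps[i])
      cand <- cand[frac > 0.1]
      if (length(cand) == 0L) {
        message("prediction ", i, " overlaps no gene; halfwidth 0 used")
        next
      }
      best <- cand[which.max(overlap_len(ps[i], pe[i], genes$start[cand],
                                         genes$end[cand]))]
      hw <- halfwidth_by_gene[genes$gene_id[best]]
      if (!is.na(hw)) n[i] <- as.integer(hw)
    }
  }
  half <- n %/% 2L
  pred$r5_start <- pred$p5 - half
  pred$r5_end <- pred$p5 + half + 1L
  pred$r3_start <- pred$p3 - half
  pred$r3_end <- pred$p3 + half + 1L
  pred
}

#' Per-gene maximal peak length of a reconstruction
#'
#' For each reconstructed gene, the largest TSS/PA peak region length over
#' all of its isoforms — the `N` used to expand point-only predictions in
#' peaks mode.
#'
#' @param result An `isoforge_result`.
#' @return Named integer vector (gene id -> N).
#' @export
peak_halfwidths <- function(result) {
  iso <- result$isoforms
  spans <- isoform_spans(iso, result$tss_peaks, result$pa_peaks)
  len <- pmax(spans$tss_end - spans$tss_start, spans$pa_end - spans$pa_start)
  out <- tapply(len, iso$gene_id, max)
  stats::setNames(as.integer(out), names(out))
}

#' Evaluate a reconstruction against a truth annotation
#'
#' Convenience dispatcher over [match_points()] and [match_peaks()] taking
#' the pipeline result directly.
#'
#' @param result An `isoforge_result`.
#' @param truth Truth transcript table.
#' @param mode `"points"` or `"peaks"`.
#' @param min_replicates Replicate-detection restriction.
#' @return An `eval_report`.
#' @export
evaluate_isoforms <- function(result, truth, mode = c("points", "peaks"),
                              min_replicates = 2L) {
  mode <- match.arg(mode)
  pred <- as_predictions(result)
  truth_pts <- etalon_points(truth)
  if (mode == "points") match_points(pred, truth_pts, min_replicates)
  else match_peaks(pred, truth_pts, min_replicates)
}

#' Classify one peak set against another
#'
#' Each peak of set A is labelled `intersecting` (at least 1 bp overlap with
#' a B peak on the same chromosome/strand; the intersection rate is the
#' overlap divided by the A peak length), `proximal` (nearest B peak edge at
#' most `proximity` bp away) or `unsupported`.
#'
#' @param a,b Peak tables (columns `chrom`, `strand`, `start`, `end`).
#' @param proximity Maximum edge distance (bp) for the proximal class.
#' @return list with `peaks` (A with `label`, `rate`, `distance`) and
#'   `summary` (label fractions and median distance of proximal peaks).
#' @export
compare_peak_sets <- function(a, b, proximity = 10L) {
  label <- character(nrow(a))
  rate <- rep(NA_real_, nrow(a))
  dist <- rep(NA_integer_, nrow(a))
  for (i in seq_len(nrow(a))) {
    cand <- which(b$chrom == a$chrom[i] & b$strand == a$strand[i])
    if (length(cand) == 0L) {
      label[i] <- "unsupported"
      next
    }
    ov <- overlap_len(a$start[i], a$end[i], b$start[cand], b$end[cand])
    if (max(ov) >= 1L) {
      label[i] <- "intersecting"
      rate[i] <- max(ov) / (a$end[i] - a$start[i])
    } else {
      gaps <- pmax(b$start[cand] - a$end[i], a$start[i] - b$end[cand])
      dist[i] <- min(gaps)
      label[i] <- if (dist[i] <= proximity) "proximal" else "unsupported"
    }
  }
  peaks <- cbind(a, label = label, rate = rate, distance = dist)
  frac <- function(l) if (nrow(a)) mean(label == l) else 0
  list(peaks = peaks,
       summary = list(
         frac_intersecting = frac("intersecting"),
         frac_proximal = frac("proximal"),
         frac_unsupported = frac("unsupported"),
         median_proximal_distance =
           if (any(label == "proximal"))
             stats::median(dist[label == "proximal"]) else NA_real_))
}
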
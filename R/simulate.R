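#' Simulation configuration
#'
#' Parameters of the toy-scale read simulator used for fixtures and
#' benchmarking. Expression per isoform follows a negative binomial
#' (`nb_n`, `nb_p`), emulating common long-read simulator settings, unless a
#' fixed `reads_per_isoform` is given. End completeness (fraction of the
#' transcript retained after 5'/3' truncation) is a mixture: full length with
#' probability `prob_full_*`, otherwise a Beta draw — mimicking the
#' completeness profiles of long-read library preparations.
#'
#' @param n_chroms,chrom_len Number and length (bp) of random chromosomes.
#' @param n_genes Genes placed without overlap, alternating strand.
#' @param isoforms_per_gene,exons_per_isoform Integer ranges `c(min, max)`.
#' @param exon_len,intron_len,terminal_exon_len bp ranges for drawn
#'   exon/intron lengths (terminal exons are longer so alternative start/end
#'   variants stay inside them).
#' @param nb_n,nb_p Negative-binomial size and probability for per-isoform
#'   read counts (mean `nb_n (1 - nb_p) / nb_p`).
#' @param reads_per_isoform Fixed per-isoform read count (scalar or vector
#'   recycled over isoforms); overrides the negative binomial when non-NULL.
#' @param prob_full_5p,prob_full_3p Probability a read is complete at that
#'   end.
#' @param beta_5p,beta_3p Beta shape parameters `c(a, b)` for incomplete
#'   reads' retained fraction.
#' @param end_jitter_sd SD (bp) of integer Gaussian end jitter; jitter never
#'   extends a read beyond the transcript (truncated at the boundary).
#' @param subst_rate,indel_rate Per-base substitution and indel rates.
#' @param polya_len Range of appended poly(A) tail lengths (FASTQ output
#'   only).
#' @param min_read_len Reads shorter than this after truncation are skipped.
#' @param n_replicates Number of simulated biological replicates.
#' @param seed Base seed; all simulator streams derive from it, so outputs
#'   are byte-identical for a fixed seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2L, chrom_len = 100000L, n_genes = 20L,
                       isoforms_per_gene = c(1L, 4L),
                       exons_per_isoform = c(2L, 5L),
                       exon_len = c(120L, 300L), intron_len = c(60L, 300L),
                       terminal_exon_len = c(200L, 300L),
                       nb_n = 1, nb_p = 0.004, reads_per_isoform = NULL,
                       prob_full_5p = 1, prob_full_3p = 1,
                       beta_5p = c(6, 2), beta_3p = c(6, 2),
                       end_jitter_sd = 0, subst_rate = 0, indel_rate = 0,
                       polya_len = c(20L, 60L), min_read_len = 30L,
                       n_replicates = 3L, seed = 1L) {
  cfg <- as.list(environment())
  for (nm in c("subst_rate", "indel_rate", "prob_full_5p", "prob_full_3p")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop(nm, " must be in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a toy genome with a multi-isoform truth annotation
#'
#' Random-sequence chromosomes with genes placed without overlap on
#' alternating strands. Each gene draws a master exon/intron layout; its
#' isoforms share introns and differ by alternative TSS, alternative PA
#' (offsets of at least 40 bp, so end peaks of different isoforms stay
#' separable) and/or a skipped internal exon. Canonical GT..AG dinucleotides
#' are written at every intron boundary in the transcribed orientation.
#'
#' @param sim A [sim_config()].
#' @return list with `genome` (named `DNAStringSet`) and `transcripts`
#'   (truth transcript table in [read_gtf()] layout).
#' @export
make_toy_genome <- function(sim = sim_config()) {
  set.seed(derive_seed(sim$seed, "genome"))
  rint <- function(rng) if (rng[1] >= rng[2]) rng[1] else
    sample(rng[1]:rng[2], 1L)
  chrom_names <- sprintf("chr%d", seq_len(sim$n_chroms))
  seqs <- lapply(chrom_names, function(cn) {
    sample(c("A", "C", "G", "T"), sim$chrom_len, replace = TRUE)
  })
  names(seqs) <- chrom_names
  cursor <- stats::setNames(rep(500L, sim$n_chroms), chrom_names)
  rows <- list()
  for (g in seq_len(sim$n_genes)) {
    chrom <- chrom_names[(g - 1L) %% sim$n_chroms + 1L]
    strand <- if (g %% 2L == 1L) "+" else "-"
    gene_id <- sprintf("G%03d", g)
    k <- rint(sim$exons_per_isoform)
    ex_len <- integer(k)
    for (e in seq_len(k)) {
      ex_len[e] <- if (e == 1L || e == k) rint(sim$terminal_exon_len)
                   else rint(sim$exon_len)
    }
    in_len <- if (k > 1L) vapply(seq_len(k - 1L), function(i)
      rint(sim$intron_len), integer(1)) else integer(0)
    gstart <- cursor[chrom]
    starts <- gstart + c(0L, cumsum(ex_len[-k] + in_len))
    master <- cbind(start = starts, end = starts + ex_len)
    span <- master[k, 2] - gstart
    if (gstart + span + 100L > sim$chrom_len) {
      stop("genes do not fit on ", chrom, ": increase chrom_len or reduce ",
           "n_genes")
    }
    cursor[chrom] <- master[k, 2] + rint(c(300L, 800L))
    n_iso <- rint(sim$isoforms_per_gene)
    variants <- list(master)
    shift_tss <- function(ex, off) {      # move TSS inward (3'-ward)
      if (strand == "+") ex[1, 1] <- ex[1, 1] + off
      else ex[nrow(ex), 2] <- ex[nrow(ex), 2] - off
      ex
    }
    shift_pa <- function(ex, off) {       # move PA inward (5'-ward)
      if (strand == "+") ex[nrow(ex), 2] <- ex[nrow(ex), 2] - off
      else ex[1, 1] <- ex[1, 1] + off
      ex
    }
    for (v in seq_len(n_iso - 1L)) {
      variants[[v + 1L]] <- switch(((v - 1L) %% 3L) + 1L,
        shift_tss(master, 40L * ceiling(v / 3)),
        shift_pa(master, 40L * ceiling(v / 3)),
        if (k >= 3L) master[-ceiling(k / 2), , drop = FALSE]
        else shift_tss(shift_pa(master, 40L), 40L))
    }
    for (v in seq_along(variants)) {
      ex <- variants[[v]]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = ex[, 1], end = ex[, 2], strand = strand,
        tx_id = sprintf("%s.%d", gene_id, v), gene_id = gene_id,
        stringsAsFactors = FALSE)
    }
  }
  transcripts <- transcript_table(do.call(rbind, rows))
  # canonical splice dinucleotides at every implied intron boundary
  for (i in seq_len(nrow(transcripts))) {
    ex <- transcripts$exons[[i]]
    if (nrow(ex) < 2L) next
    s <- seqs[[transcripts$chrom[i]]]
    donor <- if (transcripts$strand[i] == "+") c("G", "T") else c("C", "T")
    accept <- if (transcripts$strand[i] == "+") c("A", "G") else c("A", "C")
    for (j in seq_len(nrow(ex) - 1L)) {
      s[(ex[j, 2] + 1L):(ex[j, 2] + 2L)] <- donor
      s[(ex[j + 1L, 1] - 1L):ex[j + 1L, 1]] <- accept
    }
    seqs[[transcripts$chrom[i]]] <- s
  }
  # non-A transcript-final bases (self-complementary CG run, long enough that
  # a poly(A) match at 10% errors cannot bridge it) so that tail trimming of
  # simulated reads removes exactly the appended tail
  block <- rep(c("C", "G"), 6)
  for (i in seq_len(nrow(transcripts))) {
    s <- seqs[[transcripts$chrom[i]]]
    if (transcripts$strand[i] == "+") {
      s[(transcripts$end[i] - 11L):transcripts$end[i]] <- block
    } else {
      s[(transcripts$start[i] + 1L):(transcripts$start[i] + 12L)] <- block
    }
    seqs[[transcripts$chrom[i]]] <- s
  }
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                            collapse = ""))
  list(genome = genome, transcripts = transcripts)
}

# Per-isoform read counts for one replicate.
draw_read_counts <- function(n_iso, sim) {
  if (!is.null(sim$reads_per_isoform)) {
    rep_len(as.integer(sim$reads_per_isoform), n_iso)
  } else {
    stats::rnbinom(n_iso, size = sim$nb_n, prob = sim$nb_p)
  }
}

draw_completeness <- function(n, prob_full, beta) {
  full <- stats::runif(n) < prob_full
  out <- rep(1, n)
  if (any(!full)) out[!full] <- stats::rbeta(sum(!full), beta[1], beta[2])
  out
}

# Map a transcript-coordinate interval [a, b) onto ascending genomic blocks.
transcript_blocks <- function(exons, strand, a, b) {
  w <- exons[, 2] - exons[, 1]
  order_tx <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  cum <- c(0L, cumsum(w[order_tx]))
  blocks <- list()
  for (j in seq_along(order_tx)) {
    lo <- max(a, cum[j]); hi <- min(b, cum[j + 1L])
    if (lo >= hi) next
    e <- order_tx[j]
    blk <- if (strand == "+") {
      c(exons[e, 1] + (lo - cum[j]), exons[e, 1] + (hi - cum[j]))
    } else {
      c(exons[e, 2] - (hi - cum[j]), exons[e, 2] - (lo - cum[j]))
    }
    blocks[[length(blocks) + 1L]] <- blk
  }
  m <- do.call(rbind, blocks)
  m <- m[order(m[, 1]), , drop = FALSE]
  storage.mode(m) <- "integer"
  colnames(m) <- c("start", "end")
  m
}

BASES <- c("A", "C", "G", "T")

# Apply substitutions and indels to a forward-strand aligned read; returns
# list(seq = character scalar, ops = data.frame(len, type)) with a CIGAR
# consistent with the sequence.
inject_errors <- function(bases, ops_len, ops_type, subst_rate, indel_rate) {
  n <- length(bases)
  if (subst_rate > 0) {
    hit <- which(stats::runif(n) < subst_rate)
    for (p in hit) {
      bases[p] <- sample(BASES[BASES != bases[p]], 1L)
    }
  }
  if (indel_rate > 0 && n > 2L) {
    n_del <- stats::rbinom(1L, n, indel_rate / 2)
    n_ins <- stats::rbinom(1L, n, indel_rate / 2)
    events <- rbind(
      if (n_del) cbind(pos = sample.int(n, n_del), type = 1L),
      if (n_ins) cbind(pos = sample.int(n, n_ins), type = 2L))
    if (!is.null(events)) {
      events <- events[order(-events[, "pos"]), , drop = FALSE]
      for (ev in seq_len(nrow(events))) {
        p <- events[ev, "pos"]
        edit <- if (events[ev, "type"] == 1L) "D" else "I"
        # locate the M op containing read base p
        read_cum <- cumsum(ifelse(ops_type %in% c("M", "I"), ops_len, 0L))
        op <- which(read_cum >= p & ops_type == "M")[1]
        if (is.na(op)) next
        before <- p - 1L - (if (op > 1L) read_cum[op - 1L] else 0L)
        after <- ops_len[op] - before - (if (edit == "D") 1L else 0L)
        if (edit == "D") {
          bases <- bases[-p]
          ins <- list(len = c(before, 1L, after), type = c("M", "D", "M"))
        } else {
          bases <- append(bases, sample(BASES, 1L), after = p - 1L)
          ins <- list(len = c(before, 1L, after + 1L),
                      type = c("M", "I", "M"))
        }
        ops_len <- append(ops_len[-op], ins$len, after = op - 1L)
        ops_type <- append(ops_type[-op], ins$type, after = op - 1L)
        keep <- ops_len > 0L
        ops_len <- ops_len[keep]; ops_type <- ops_type[keep]
      }
    }
  }
  # merge adjacent ops of the same type
  if (length(ops_len) > 1L) {
    grp <- cumsum(c(TRUE, ops_type[-1] != ops_type[-length(ops_type)]))
    ops_len <- as.integer(tapply(ops_len, grp, sum))
    ops_type <- ops_type[!duplicated(grp)]
  }
  list(bases = bases, ops_len = ops_len, ops_type = ops_type)
}

#' Simulate long cDNA reads with ground-truth alignments
#'
#' Per isoform and replicate, a read count is drawn (negative binomial or
#' fixed). Each read is the transcript sequence truncated by 5'/3'
#' completeness draws, end-jittered, with substitutions/indels injected, and
#' (in FASTQ output) a poly(A) tail appended. The returned truth alignments
#' carry the read's genomic span, strand and intron chain, so downstream
#' stages can run without an external aligner.
#'
#' @param genome Named `DNAStringSet` (or FASTA path).
#' @param transcripts Truth transcript table.
#' @param sim A [sim_config()].
#' @param out_dir If non-NULL, writes `repN.fastq` and `repN.truth.sam`
#'   there.
#' @return list with `reads` (AlignedRead table over all replicates, with
#'   `cigar` and `introns`), `fastq` (list per replicate of id/seq/qual), and
#'   `files` (written paths, when `out_dir` is given).
#' @export
simulate_reads <- function(genome, transcripts, sim = sim_config(),
                           out_dir = NULL) {
  genome <- load_genome(genome)
  chrom_seq <- lapply(as.character(genome), function(s)
    strsplit(s, "", fixed = TRUE)[[1]])
  reps <- sprintf("rep%d", seq_len(sim$n_replicates))
  all_reads <- list(); all_fastq <- list(); files <- list()
  for (r in seq_along(reps)) {
    set.seed(derive_seed(sim$seed, c("reads", reps[r])))
    counts <- draw_read_counts(nrow(transcripts), sim)
    rows <- list(); fq_id <- character(0); fq_seq <- character(0)
    serial <- 0L
    for (i in seq_len(nrow(transcripts))) {
      if (counts[i] == 0L) next
      ex <- transcripts$exons[[i]]
      strand <- transcripts$strand[i]
      chrom <- transcripts$chrom[i]
      L <- sum(ex[, 2] - ex[, 1])
      c5 <- draw_completeness(counts[i], sim$prob_full_5p, sim$beta_5p)
      c3 <- draw_completeness(counts[i], sim$prob_full_3p, sim$beta_3p)
      j5 <- if (sim$end_jitter_sd > 0)
        as.integer(round(stats::rnorm(counts[i], 0, sim$end_jitter_sd)))
        else integer(counts[i])
      j3 <- if (sim$end_jitter_sd > 0)
        as.integer(round(stats::rnorm(counts[i], 0, sim$end_jitter_sd)))
        else integer(counts[i])
      a <- pmin(pmax(as.integer(floor((1 - c5) * L)) + j5, 0L), L - 1L)
      b <- pmax(pmin(L - as.integer(floor((1 - c3) * L)) - j3, L), 1L)
      for (q in seq_len(counts[i])) {
        if (b[q] - a[q] < sim$min_read_len) next
        blocks <- transcript_blocks(ex, strand, a[q], b[q])
        bases <- unlist(lapply(seq_len(nrow(blocks)), function(e)
          chrom_seq[[chrom]][(blocks[e, 1] + 1L):blocks[e, 2]]))
        w <- blocks[, 2] - blocks[, 1]
        gaps <- if (nrow(blocks) > 1L)
          blocks[-1, 1] - blocks[-nrow(blocks), 2] else integer(0)
        ops_len <- c(rbind(w, c(gaps, NA)))
        ops_len <- ops_len[!is.na(ops_len)]
        ops_type <- rep(c("M", "N"), length.out = length(ops_len))
        err <- inject_errors(bases, as.integer(ops_len), ops_type,
                             sim$subst_rate, sim$indel_rate)
        serial <- serial + 1L
        rid <- sprintf("%s_%s_%05d", reps[r], transcripts$tx_id[i], serial)
        cigar <- paste0(err$ops_len, err$ops_type, collapse = "")
        ref_w <- sum(err$ops_len[err$ops_type %in% c("M", "D", "N")])
        introns <- cbind(start = blocks[-nrow(blocks), 2],
                         end = blocks[-1, 1])
        if (nrow(blocks) == 1L)
          introns <- matrix(integer(0), 0, 2,
                            dimnames = list(NULL, c("start", "end")))
        rows[[length(rows) + 1L]] <- list(
          read_id = rid, chrom = chrom, start = blocks[1, 1],
          end = blocks[1, 1] + ref_w, strand = strand, cigar = cigar,
          seq_fwd = paste(err$bases, collapse = ""), introns = introns)
        sense <- if (strand == "+") paste(err$bases, collapse = "")
                 else as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(paste(err$bases, collapse = ""))))
        tail_len <- sample(sim$polya_len[1]:sim$polya_len[2], 1L)
        fq_id <- c(fq_id, rid)
        fq_seq <- c(fq_seq, paste0(sense, strrep("A", tail_len)))
      }
    }
    reads <- data.frame(
      read_id = vapply(rows, `[[`, character(1), "read_id"),
      replicate = reps[r],
      chrom = vapply(rows, `[[`, character(1), "chrom"),
      start = vapply(rows, function(x) as.integer(x$start), integer(1)),
      end = vapply(rows, function(x) as.integer(x$end), integer(1)),
      strand = vapply(rows, `[[`, character(1), "strand"),
      cigar = vapply(rows, `[[`, character(1), "cigar"),
      stringsAsFactors = FALSE)
    reads$introns <- lapply(rows, `[[`, "introns")
    all_reads[[r]] <- reads
    fq <- list(id = fq_id, seq = fq_seq, qual = strrep("5", nchar(fq_seq)))
    all_fastq[[reps[r]]] <- fq
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      fq_path <- file.path(out_dir, paste0(reps[r], ".fastq"))
      write_fastq(fq$id, fq$seq, fq$qual, fq_path)
      sam_path <- file.path(out_dir, paste0(reps[r], ".truth.sam"))
      write_truth_sam(rows, genome, sam_path)
      files[[reps[r]]] <- c(fastq = fq_path, sam = sam_path)
    }
  }
  list(reads = do.call(rbind, all_reads), fastq = all_fastq, files = files)
}

# Write ground-truth alignments as SAM (forward-strand SEQ, flag 16 for
# minus-strand reads).
write_truth_sam <- function(rows, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (cn in names(genome)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", cn, length(genome[[cn]])), con)
  }
  for (x in rows) {
    flag <- if (x$strand == "+") 0L else 16L
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                       x$read_id, flag, x$chrom, x$start + 1L, x$cigar,
                       x$seq_fwd, strrep("5", nchar(x$seq_fwd))), con)
  }
  invisible(path)
}

#' Randomly distort transcript boundaries of an annotation
#'
#' Each transcript is assigned uniformly at random one of seven
#' modifications: 5' end moved `shift` bp downstream or upstream, 3' end
#' moved downstream or upstream, both ends upstream, both ends downstream, or
#' no change. Upstream/downstream are taken in transcription direction
#' (strand-aware). Shifts extend or contract the terminal exon only; a
#' contraction that would cross the first/last splice junction stops 1 bp
#' short of it, and extensions never go below position 0.
#'
#' @param transcripts Transcript table.
#' @param shift Shift size in bp.
#' @param seed RNG seed.
#' @return The distorted transcript table; attribute `cases` records the
#'   modification drawn per transcript (levels `5d`, `5u`, `3d`, `3u`, `bu`,
#'   `bd`, `none`).
#' @export
distort_annotation <- function(transcripts, shift = 100L, seed = 1L) {
  set.seed(derive_seed(seed, "distort"))
  levels <- c("5d", "5u", "3d", "3u", "bu", "bd", "none")
  cases <- sample(levels, nrow(transcripts), replace = TRUE)
  out <- transcripts
  for (i in seq_len(nrow(out))) {
    cs <- cases[i]
    if (cs == "none") next
    ex <- out$exons[[i]]
    k <- nrow(ex)
    plus <- out$strand[i] == "+"
    move5 <- if (cs %in% c("5d", "bd")) shift
             else if (cs %in% c("5u", "bu")) -shift else 0L
    move3 <- if (cs %in% c("3d", "bd")) shift
             else if (cs %in% c("3u", "bu")) -shift else 0L
    if (move5 != 0L) {
      if (plus) {  # 5' end is ex[1, 1]; downstream increases coordinate
        lim <- if (k > 1L) ex[1, 2] - 1L else ex[1, 2] - 1L
        ex[1, 1] <- max(0L, min(ex[1, 1] + move5, lim))
      } else {     # 5' end is ex[k, 2]; downstream decreases coordinate
        lim <- ex[k, 1] + 1L
        ex[k, 2] <- max(ex[k, 2] - move5, lim)
      }
    }
    if (move3 != 0L) {
      if (plus) {  # 3' end is ex[k, 2]; downstream increases coordinate
        lim <- ex[k, 1] + 1L
        ex[k, 2] <- max(ex[k, 2] + move3, lim)
      } else {     # 3' end is ex[1, 1]; downstream decreases coordinate
        lim <- ex[1, 2] - 1L
        ex[1, 1] <- max(0L, min(ex[1, 1] - move3, lim))
      }
    }
    out$exons[[i]] <- ex
    out$start[i] <- ex[1, 1]
    out$end[i] <- ex[k, 2]
  }
  attr(out, "cases") <- factor(cases, levels = levels)
  out
}
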
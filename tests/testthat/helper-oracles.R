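# Independent brute-force oracles and small fixture builders shared by the
# test files. Each oracle is written from the operation's definition, not
# from the package's implementation.

# Build an AlignedRead table from vectors; introns default to empty chains.
make_reads <- function(chrom, start, end, strand, replicate = "rep1",
                       read_id = NULL, introns = NULL) {
  n <- max(length(chrom), length(start), length(end), length(strand),
           length(replicate))
  df <- data.frame(
    read_id = if (is.null(read_id)) sprintf("r%04d", seq_len(n)) else read_id,
    replicate = rep_len(replicate, n), chrom = rep_len(chrom, n),
    start = as.integer(rep_len(start, n)), end = as.integer(rep_len(end, n)),
    strand = rep_len(strand, n), stringsAsFactors = FALSE)
  df$introns <- if (is.null(introns)) {
    replicate(n, matrix(integer(0), 0, 2,
                        dimnames = list(NULL, c("start", "end"))),
              simplify = FALSE)
  } else {
    introns
  }
  df
}

chain_mat <- function(...) {
  v <- c(...)
  m <- matrix(as.integer(v), ncol = 2, byrow = TRUE)
  colnames(m) <- c("start", "end")
  m
}

# Hand CIGAR walker: reference intervals of N operations.
oracle_cigar_introns <- function(cigar, pos) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  cur <- pos
  out <- NULL
  for (i in seq_along(ops)) {
    if (ops[i] == "N") out <- rbind(out, c(cur, cur + lens[i]))
    if (ops[i] %in% c("M", "D", "N", "=", "X")) cur <- cur + lens[i]
  }
  if (is.null(out)) out <- matrix(integer(0), 0, 2)
  colnames(out) <- c("start", "end")
  storage.mode(out) <- "integer"
  out
}

# Reference-consumed length of a CIGAR.
oracle_cigar_ref_width <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  sum(lens[ops %in% c("M", "D", "N", "=", "X")])
}

# Brute-force junction scan: all reference introns on chrom with both
# boundaries within tol.
oracle_junction_scan <- function(jset, chrom, start, end, tol) {
  tab <- jset$introns
  which(tab$chrom == chrom & abs(tab$start - start) <= tol &
        abs(tab$end - end) <= tol)
}

# Brute-force all-pairs cluster merging of candidate positions on one track:
# repeatedly merge any two clusters whose closest candidates have fewer than
# merge_dist intervening positions. Returns a list of position vectors.
oracle_merge_clusters <- function(pos, merge_dist) {
  clusters <- as.list(sort(pos))
  repeat {
    merged <- FALSE
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        gap <- min(abs(outer(clusters[[a]], clusters[[b]], "-"))) - 1L
        if (gap < merge_dist) {
          clusters[[a]] <- sort(c(clusters[[a]], clusters[[b]]))
          clusters <- clusters[-b]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  clusters[order(vapply(clusters, min, double(1)))]
}

# Brute-force transitive closure for gene clustering: adjacency matrix of the
# overlap relation, connected components via repeated boolean multiplication.
oracle_components <- function(chrom, strand, s, e, frac) {
  n <- length(s)
  adj <- diag(n) > 0
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (chrom[a] != chrom[b] || strand[a] != strand[b]) next
      ov <- max(0L, min(e[a], e[b]) - max(s[a], s[b]))
      if (ov >= frac * min(e[a] - s[a], e[b] - s[b])) adj[a, b] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[adj[i, ]] <- cid
    }
  }
  comp
}

# Brute-force poly(A) trimming: try every tail start position, keep
# admissible ones, pick the one maximizing matched A count (ties: fewest
# errors, i.e. latest start).
oracle_trim_polya <- function(s, adapter_len = 100, error_rate = 0.1,
                              min_overlap = 3) {
  L <- nchar(s)
  best <- NULL
  for (i in seq_len(L)) {
    len <- L - i + 1
    if (len < min_overlap || len > adapter_len) next
    suffix <- substring(s, i, L)
    n_a <- sum(strsplit(suffix, "")[[1]] == "A")
    errs <- len - n_a
    if (errs > error_rate * len) next
    if (is.null(best) || n_a > best$n_a ||
        (n_a == best$n_a && errs < best$errs)) {
      best <- list(i = i, n_a = n_a, errs = errs)
    }
  }
  if (is.null(best)) s else substring(s, 1, best$i - 1)
}

# Write a tiny SAM file from a record list; each record is a list with
# qname, flag, rname, pos1 (1-based), cigar, seq.
write_test_sam <- function(records, chroms, path) {
  lines <- c("@HD\tVN:1.6",
             sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), chroms))
  for (r in records) {
    seq <- if (is.null(r$seq)) "*" else r$seq
    qual <- if (seq == "*") "*" else strrep("I", nchar(seq))
    lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                              r$qname, r$flag, r$rname, r$pos1,
                              if (is.null(r$mapq)) 60L else r$mapq,
                              r$cigar, seq, qual))
  }
  writeLines(lines, path)
  path
}

# Random nucleotide string.
random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
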
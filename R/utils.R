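# Internal shared helpers: interval checks, seed derivation, chain encoding.

# Validate a 0-based half-open interval specification; returns invisibly.
check_interval <- function(start, end, what = "interval") {
  bad <- is.na(start) | is.na(end) | start < 0L | start >= end
  if (any(bad)) {
    stop(what, " must satisfy 0 <= start < end (violated at row ",
         which(bad)[1], ")")
  }
  invisible(NULL)
}

check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  invisible(NULL)
}

# Deterministic 32-bit seed derived from a base seed and a string key, so
# per-(replicate, chrom, strand) RNG streams are reproducible and independent
# of processing order.
derive_seed <- function(seed, key) {
  h <- as.double(seed) %% 2147483647
  for (cp in utf8ToInt(paste(key, collapse = "|"))) {
    h <- (h * 31 + cp) %% 2147483647
  }
  as.integer(h)
}

# Encode an intron chain (n x 2 integer matrix, 0-based half-open) as a
# stable string key; empty chains encode as "".
chain_key <- function(introns) {
  if (is.null(introns) || nrow(introns) == 0L) return("")
  paste(paste(introns[, 1], introns[, 2], sep = "-"), collapse = ";")
}

# Inverse of chain_key().
decode_chain <- function(key) {
  if (is.na(key) || !nzchar(key)) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  parts <- strsplit(strsplit(key, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE)
  colnames(m) <- c("start", "end")
  m
}

# Overlap length of [s1,e1) and [s2,e2); vectorized.
overlap_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# Empty AlignedRead table with the canonical columns.
empty_reads <- function() {
  df <- data.frame(read_id = character(0), replicate = character(0),
                   chrom = character(0), start = integer(0), end = integer(0),
                   strand = character(0), stringsAsFactors = FALSE)
  df$introns <- list()
  df
}
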
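#' Read splice-junction files
#'
#' Parses STAR `SJ.out.tab` files (9 columns) or a minimal 4-column TSV
#' (chrom, start, end, strand), distinguished by column count. Both dialects
#' carry 1-based inclusive intronic coordinates, converted here to the
#' internal 0-based half-open convention. STAR strand codes are mapped
#' 0 = undefined, 1 = `+`, 2 = `-`; in the 4-column dialect the strand column
#' may hold `+`/`-`/`.` directly.
#'
#' @param paths Character vector of junction files, one per source sample.
#' @param samples Optional sample labels (default: file basenames, made
#'   unique).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open intron),
#'   `strand` (`+`, `-` or `*` for undefined), `sample`.
#' @export
read_star_junctions <- function(paths, samples = NULL) {
  if (is.null(samples)) samples <- make.unique(basename(paths))
  stopifnot(length(samples) == length(paths))
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    tab <- utils::read.table(paths[i], sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 4) {
      stop("junction file ", paths[i], " has fewer than 4 columns")
    }
    strand_raw <- tab[[4]]
    strand <- if (is.numeric(strand_raw)) {
      c("0" = "*", "1" = "+", "2" = "-")[as.character(strand_raw)]
    } else {
      ifelse(strand_raw %in% c("+", "-"), strand_raw, "*")
    }
    out[[i]] <- data.frame(
      chrom = as.character(tab[[1]]),
      start = as.integer(tab[[2]]) - 1L,  # 1-based first intronic base
      end = as.integer(tab[[3]]),         # 1-based last intronic base
      strand = unname(strand),
      sample = samples[i],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  check_interval(res$start, res$end, "junction")
  rownames(res) <- NULL
  res
}

#' Write a junction table in the 4-column dialect
#'
#' Inverse of the minimal-TSV dialect of [read_star_junctions()]: coordinates
#' are emitted 1-based inclusive.
#'
#' @param junctions data.frame with `chrom`, `start`, `end`, `strand`
#'   (internal 0-based half-open coordinates).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_junctions <- function(junctions, path) {
  tab <- data.frame(junctions$chrom, junctions$start + 1L, junctions$end,
                    junctions$strand)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
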
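# Gene-model readers. Two dialects:
#   * BED   — standard UCSC/GENCODE 0-based half-open, "chr"-prefixed names;
#   * BNBED — the numeric-chromosome dialect used by optical-mapping tools
#             (X/Y as 23/24, 1-based inclusive coordinates).
# Both are unified into a 1-based inclusive gene interval set.

#' Read a gene BED file into a gene interval set
#'
#' @param path Path to the file.
#' @param fmt "BED" (0-based half-open, chromosome names) or "BNBED"
#'   (numeric chromosomes 1-24, 1-based inclusive).
#' @return An object of class \code{gene_interval_set}: a data.frame with
#'   columns chrom (integer 1-24), start, end (1-based inclusive), strand,
#'   symbol. Rows on unsupported contigs are skipped with a warning naming
#'   the count. An attribute \code{n_skipped} records the skip count.
#' @export
read_bed <- function(path, fmt = c("BED", "BNBED")) {
  fmt <- match.arg(fmt)
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          quote = "", comment.char = "#", fill = TRUE)
  if (!nrow(df)) stop("no parseable rows in BED file ", path)
  nms <- c("chrom", "start", "end", "symbol", "score", "strand")
  names(df)[seq_len(min(ncol(df), 6L))] <- nms[seq_len(min(ncol(df), 6L))]
  if (ncol(df) < 4L) stop("BED file ", path, " needs at least 4 columns")
  if (!"strand" %in% names(df)) df$strand <- "+"
  chrom <- rep(NA_integer_, nrow(df))
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    chrom[i] <- tryCatch(normalize_chromosome(df$chrom[i]),
                         ogmsv_unsupported_contig = function(e) NA_integer_)
    if (is.na(chrom[i])) keep[i] <- FALSE
  }
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    warning(n_skipped, " BED row(s) on unsupported contigs skipped")
  }
  df <- df[keep, , drop = FALSE]
  chrom <- chrom[keep]
  if (!nrow(df)) stop("no parseable rows in BED file ", path)
  if (fmt == "BED") {
    start <- as.numeric(df$start) + 1  # 0-based half-open -> 1-based inclusive
    end <- as.numeric(df$end)
  } else {
    start <- as.numeric(df$start)
    end <- as.numeric(df$end)
  }
  strand <- as.character(df$strand)
  strand[!strand %in% c("+", "-")] <- "+"
  genes <- data.frame(chrom = chrom, start = start, end = end,
                      strand = strand, symbol = as.character(df$symbol),
                      stringsAsFactors = FALSE)
  bad <- genes$start >= genes$end
  genes <- genes[!bad, , drop = FALSE]
  structure(genes, class = c("gene_interval_set", "data.frame"),
            n_skipped = n_skipped)
}

#' Convert a standard BED file to the numeric-chromosome (BNBED) dialect
#'
#' Writes a tab-delimited file with chromosomes as integers (X/Y as 23/24)
#' and 1-based inclusive coordinates; reading the result with
#' \code{fmt = "BNBED"} is equivalent to reading the original with
#' \code{fmt = "BED"}.
#'
#' @param path Input BED path.
#' @param out Output BNBED path.
#' @return \code{out}, invisibly.
#' @export
bed_to_bnbed <- function(path, out) {
  genes <- read_bed(path, fmt = "BED")
  utils::write.table(
    data.frame(genes$chrom, genes$start, genes$end, genes$symbol, 0, genes$strand),
    out, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(out)
}
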
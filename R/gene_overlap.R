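# Gene overlap and nearest-gene annotation.
#
# A +/- window around the SV (3 kb for insertions/deletions/duplications,
# 10 kb for inversions/translocations) absorbs the ~3.3 kb breakpoint
# uncertainty of optical mapping when *searching* for genes; the reported
# percent overlap is always computed on the unexpanded SV interval against
# the gene body, as a fraction of gene length.

gene_window <- function(cls, win_indel_gene, win_invtrans_gene) {
  if (cls %in% c("inversion", "translocation")) win_invtrans_gene else win_indel_gene
}

overlap_len <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)

genes_hit <- function(genes, chrom, lo, hi) {
  sub <- genes[genes$chrom == chrom, , drop = FALSE]
  if (!nrow(sub)) return(sub)
  hits <- IRanges::findOverlaps(IRanges::IRanges(lo, hi),
                                IRanges::IRanges(sub$start, sub$end))
  sub[S4Vectors::subjectHits(hits), , drop = FALSE]
}

#' Genes overlapping an SV (within the breakpoint-uncertainty window)
#'
#' Genes intersecting [start - W, end + W] are reported with the percent of
#' the gene's length covered by the unexpanded SV interval, capped at 100
#' (gene fully inside the SV) and floored at a display minimum of 0.01 so a
#' window-only or sub-resolution overlap is never confused with no overlap.
#' For translocations each breakpoint is treated as a point: genes within
#' +/- the inversion/translocation window of either breakpoint are reported
#' with the percent of the gene covered by that window.
#'
#' @param sv One-row data.frame/list with chrom, chrom2, ref_start, ref_end
#'   and sv_class (or sv_type).
#' @param genes A \code{gene_interval_set} from [read_bed()].
#' @param win_indel_gene Search window in bp for insertion/deletion/
#'   duplication (default 3000).
#' @param win_invtrans_gene Window for inversion/translocation
#'   (default 10000).
#' @return data.frame(symbol, strand, percent, start, end), duplicate-free.
#' @export
overlap_genes <- function(sv, genes, win_indel_gene = 3000,
                          win_invtrans_gene = 10000) {
  cls <- if (!is.null(sv$sv_class)) sv$sv_class else sv_class(sv$sv_type)
  W <- gene_window(cls, win_indel_gene, win_invtrans_gene)
  if (cls == "translocation") {
    bps <- list(c(sv$chrom, sv$ref_start),
                c(if (is.null(sv$chrom2)) sv$chrom else sv$chrom2, sv$ref_end))
    out <- do.call(rbind, lapply(bps, function(bp) {
      g <- genes_hit(genes, bp[1], bp[2] - W, bp[2] + W)
      if (!nrow(g)) return(NULL)
      pct <- overlap_len(bp[2] - W, bp[2] + W, g$start, g$end) /
        (g$end - g$start + 1) * 100
      data.frame(symbol = g$symbol, strand = g$strand,
                 percent = pmax(pmin(pct, 100), 0.01),
                 start = g$start, end = g$end, chrom = g$chrom,
                 stringsAsFactors = FALSE)
    }))
  } else {
    g <- genes_hit(genes, sv$chrom, sv$ref_start - W, sv$ref_end + W)
    out <- if (!nrow(g)) NULL else {
      pct <- overlap_len(sv$ref_start, sv$ref_end, g$start, g$end) /
        (g$end - g$start + 1) * 100
      data.frame(symbol = g$symbol, strand = g$strand,
                 percent = pmax(pmin(pct, 100), 0.01),
                 start = g$start, end = g$end, chrom = g$chrom,
                 stringsAsFactors = FALSE)
    }
  }
  if (is.null(out)) {
    out <- data.frame(symbol = character(0), strand = character(0),
                      percent = numeric(0), start = numeric(0),
                      end = numeric(0), chrom = integer(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[!duplicated(out[, c("symbol", "start", "end", "chrom")]), , drop = FALSE]
  out[order(out$start, out$symbol), , drop = FALSE]
}

#' Nearest non-overlapping genes up- and downstream of an SV
#'
#' Upstream genes lie wholly before the SV start (distance in kb =
#' (start - gene end) / 1000); downstream genes wholly after the SV end.
#' Genes already reported as overlapping are excluded. Lists are sorted by
#' ascending distance (ties broken by start coordinate, then symbol) and
#' truncated to \code{k} entries. For translocations the two breakpoints
#' anchor the up- and downstream searches on their respective chromosomes.
#'
#' @param sv One-row data.frame/list describing the SV.
#' @param genes A \code{gene_interval_set}.
#' @param k Number of genes reported per side (default 3).
#' @param overlaps Optional result of [overlap_genes()] for exclusion; when
#'   NULL it is computed.
#' @param ... Passed to [overlap_genes()].
#' @return List with data.frames \code{upstream} and \code{downstream}
#'   (symbol, strand, dist_kb).
#' @export
nearest_genes <- function(sv, genes, k = 3, overlaps = NULL, ...) {
  if (is.null(overlaps)) overlaps <- overlap_genes(sv, genes, ...)
  cls <- if (!is.null(sv$sv_class)) sv$sv_class else sv_class(sv$sv_type)
  up_chrom <- sv$chrom
  dn_chrom <- if (cls == "translocation" && !is.null(sv$chrom2)) sv$chrom2 else sv$chrom
  ex_key <- paste(overlaps$chrom, overlaps$symbol, overlaps$start, overlaps$end)
  side <- function(chrom, upstream) {
    sub <- genes[genes$chrom == chrom, , drop = FALSE]
    sub <- sub[!paste(sub$chrom, sub$symbol, sub$start, sub$end) %in% ex_key, ,
               drop = FALSE]
    if (upstream) {
      sub <- sub[sub$end < sv$ref_start, , drop = FALSE]
      d <- (sv$ref_start - sub$end) / 1000
    } else {
      sub <- sub[sub$start > sv$ref_end, , drop = FALSE]
      d <- (sub$start - sv$ref_end) / 1000
    }
    o <- order(d, sub$start, sub$symbol)
    sub <- sub[o, , drop = FALSE]; d <- d[o]
    n <- min(k, nrow(sub))
    data.frame(symbol = sub$symbol[seq_len(n)], strand = sub$strand[seq_len(n)],
               dist_kb = d[seq_len(n)], stringsAsFactors = FALSE)
  }
  list(upstream = side(up_chrom, TRUE), downstream = side(dn_chrom, FALSE))
}

fmt_num <- function(x) {
  # up to 2 decimals, trailing zeros trimmed
  s <- formatC(x, format = "f", digits = 2)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

join_cell <- function(parts) if (length(parts)) paste(parts, collapse = ";") else "-"

#' Append gene-annotation columns to an SV call set
#'
#' Adds the three list columns \code{OverlapGenes_strand_perc},
#' \code{Upstream_nonOverlapGenes_dist_kb} and
#' \code{Downstream_nonOverlapGenes_dist_kb}, with entries formatted
#' \code{SYMBOL(strand:value)} joined by ";" (value = percent overlap, or
#' distance in kb to 2 decimals). The raw per-row annotation tables are kept
#' in the \code{gene_annotation} element for downstream expression and
#' gene-list integration.
#'
#' @param callset An \code{sv_call_set}.
#' @param genes A \code{gene_interval_set}.
#' @param k Nearest genes per side (default 3).
#' @param win_indel_gene,win_invtrans_gene Search windows in bp.
#' @return The call set with annotation columns and \code{gene_annotation}.
#' @export
annotate_genes <- function(callset, genes, k = 3, win_indel_gene = 3000,
                           win_invtrans_gene = 10000) {
  calls <- callset$calls
  ann <- vector("list", nrow(calls))
  ov_col <- up_col <- dn_col <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    sv <- calls[i, , drop = FALSE]
    ov <- overlap_genes(sv, genes, win_indel_gene, win_invtrans_gene)
    nr <- nearest_genes(sv, genes, k = k, overlaps = ov)
    ann[[i]] <- list(overlaps = ov, upstream = nr$upstream,
                     downstream = nr$downstream)
    ov_col[i] <- join_cell(sprintf("%s(%s:%s)", ov$symbol, ov$strand,
                                   fmt_num(ov$percent)))
    up_col[i] <- join_cell(sprintf("%s(%s:%s)", nr$upstream$symbol,
                                   nr$upstream$strand,
                                   formatC(nr$upstream$dist_kb, format = "f", digits = 2)))
    dn_col[i] <- join_cell(sprintf("%s(%s:%s)", nr$downstream$symbol,
                                   nr$downstream$strand,
                                   formatC(nr$downstream$dist_kb, format = "f", digits = 2)))
  }
  calls$OverlapGenes_strand_perc <- ov_col
  calls$Upstream_nonOverlapGenes_dist_kb <- up_col
  calls$Downstream_nonOverlapGenes_dist_kb <- dn_col
  callset$calls <- calls
  callset$gene_annotation <- ann
  callset
}
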
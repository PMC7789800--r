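# Phenotype-driven primary gene list.
#
# Phenotype terms are matched (case-insensitive substring) against local
# snapshot tables of the condition-to-gene associations of four sources:
# NCBI Gene, OMIM, GTR and ClinVar. The union of matched genes forms the
# primary gene list; genes with Pathogenic / Likely pathogenic ClinVar
# records for a matched condition are flagged as clinically significant.
# Snapshot files keep runs reproducible; live-query adapters are out of the
# tested core because remote results drift between database releases.

genelist_sources <- c("Gene", "OMIM", "GTR", "ClinVar")

read_snapshot <- function(x) {
  if (is.data.frame(x)) return(x)
  sep <- if (grepl("\\.csv$", x, ignore.case = TRUE)) "," else "\t"
  utils::read.table(x, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    quote = "\"")
}

#' Build a primary gene list from phenotype terms and snapshot tables
#'
#' @param terms A single term, a character vector of terms, or a path to a
#'   text file with one term per line.
#' @param snapshots Named list with any of "Gene", "OMIM", "GTR", "ClinVar";
#'   each either a data.frame or a file path. All tables need columns
#'   \code{gene} and \code{condition}; the ClinVar table additionally
#'   \code{clinical_significance}.
#' @return A \code{primary_gene_list}: data.frame with columns
#'   \code{Genes}, \code{Terms} (entries \code{SYMBOL(term,Source)} joined
#'   by ";") and \code{ClinicalSignificance} ("Pathogenic/Likely Pathogenic"
#'   or ""). Symbols are unique.
#' @export
build_gene_list <- function(terms, snapshots) {
  if (length(terms) == 1L && file.exists(terms)) {
    terms <- readLines(terms)
  }
  terms <- trimws(terms[nzchar(trimws(terms))])
  if (!length(terms)) stop("no phenotype terms given")
  stopifnot(is.list(snapshots), all(names(snapshots) %in% genelist_sources))

  hits <- list()
  for (src in names(snapshots)) {
    tab <- read_snapshot(snapshots[[src]])
    stopifnot(all(c("gene", "condition") %in% names(tab)))
    cond <- tolower(tab$condition)
    for (term in terms) {
      i <- grepl(tolower(term), cond, fixed = TRUE)
      if (!any(i)) next
      h <- data.frame(gene = tab$gene[i], term = term, source = src,
                      stringsAsFactors = FALSE)
      if (src == "ClinVar") {
        h$clinsig <- tab$clinical_significance[i]
      } else h$clinsig <- NA_character_
      hits[[length(hits) + 1L]] <- h
    }
  }
  if (!length(hits)) {
    return(structure(data.frame(Genes = character(0), Terms = character(0),
                                ClinicalSignificance = character(0),
                                stringsAsFactors = FALSE),
                     class = c("primary_gene_list", "data.frame")))
  }
  all_hits <- do.call(rbind, hits)
  genes <- sort(unique(all_hits$gene))
  terms_col <- vapply(genes, function(g) {
    h <- all_hits[all_hits$gene == g, , drop = FALSE]
    h <- h[!duplicated(h[, c("term", "source")]), , drop = FALSE]
    paste(sprintf("%s(%s,%s)", g, h$term, h$source), collapse = ";")
  }, "")
  path_flag <- vapply(genes, function(g) {
    sig <- tolower(all_hits$clinsig[all_hits$gene == g & all_hits$source == "ClinVar"])
    any(sig %in% c("pathogenic", "likely pathogenic",
                   "pathogenic/likely pathogenic"), na.rm = TRUE)
  }, logical(1))
  structure(
    data.frame(Genes = genes, Terms = unname(terms_col),
               ClinicalSignificance = ifelse(path_flag,
                                             "Pathogenic/Likely Pathogenic", ""),
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("primary_gene_list", "data.frame"))
}

#' Read / write a primary gene list CSV
#'
#' A user-supplied CSV with columns Genes, Terms, ClinicalSignificance can
#' stand in for [build_gene_list()] output.
#'
#' @param path CSV path.
#' @param pg A \code{primary_gene_list} (write).
#' @export
read_gene_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot("Genes" %in% names(df))
  if (!"Terms" %in% names(df)) df$Terms <- ""
  if (!"ClinicalSignificance" %in% names(df)) df$ClinicalSignificance <- ""
  structure(df[, c("Genes", "Terms", "ClinicalSignificance")],
            class = c("primary_gene_list", "data.frame"))
}

#' @rdname read_gene_list
#' @export
write_gene_list <- function(pg, path) {
  utils::write.csv(as.data.frame(pg), path, row.names = FALSE)
  invisible(path)
}

#' Intersect each SV's annotated genes with the primary gene list
#'
#' Appends six columns: \code{Overlap_PG} / \code{Overlap_PG_Terms} for
#' overlapping genes present in the list, and the corresponding
#' \code{Non_Overlap_UP_PG} / \code{_Terms} and \code{Non_Overlap_DN_PG} /
#' \code{_Terms} pairs for the nearest up-/downstream genes. Cells with no
#' intersection contain "-".
#'
#' @param callset An \code{sv_call_set} after [annotate_genes()].
#' @param pg A \code{primary_gene_list}.
#' @return The call set with the six PG columns appended.
#' @export
intersect_primary_genes <- function(callset, pg) {
  if (is.null(callset$gene_annotation)) {
    stop("call set has no gene annotation; run annotate_genes() first")
  }
  terms_of <- stats::setNames(pg$Terms, pg$Genes)
  one <- function(symbols) {
    hit <- unique(symbols[symbols %in% pg$Genes])
    if (!length(hit)) return(c("-", "-"))
    c(paste(hit, collapse = ";"), paste(terms_of[hit], collapse = ";"))
  }
  ann <- callset$gene_annotation
  ov <- vapply(ann, function(a) one(a$overlaps$symbol), character(2))
  up <- vapply(ann, function(a) one(a$upstream$symbol), character(2))
  dn <- vapply(ann, function(a) one(a$downstream$symbol), character(2))
  callset$calls$Overlap_PG <- ov[1, ]
  callset$calls$Overlap_PG_Terms <- ov[2, ]
  callset$calls$Non_Overlap_UP_PG <- up[1, ]
  callset$calls$Non_Overlap_UP_Terms <- up[2, ]
  callset$calls$Non_Overlap_DN_PG <- dn[1, ]
  callset$calls$Non_Overlap_DN_Terms <- dn[2, ]
  callset
}
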
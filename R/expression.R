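# Gene-expression integration: merge per-sample quantification tables
# (gene symbol + TPM) into one matrix and append per-role expression strings
# for the genes that overlap or flank each SV.

expr_role_codes <- c(P = "proband", UM = "mother", AM = "mother",
                     UF = "father", AF = "father")

parse_expr_role <- function(filename) {
  toks <- regmatches(basename(filename),
                     gregexpr("_(P|UM|AM|UF|AF)(?=_)", basename(filename),
                              perl = TRUE))[[1]]
  codes <- unique(gsub("_", "", toks))
  if (length(codes) != 1L) {
    stop("cannot determine sample role from file name '", basename(filename),
         "': expected exactly one _P_/_UM_/_AM_/_UF_/_AF_ token, found ",
         length(codes))
  }
  unname(expr_role_codes[codes])
}

#' Merge per-sample expression tables into a gene-by-sample matrix
#'
#' Each input is a two-column table (gene symbol, TPM). The sample's role is
#' parsed from a filename token: \code{_P_} proband, \code{_UM_}/\code{_AM_}
#' unaffected/affected mother, \code{_UF_}/\code{_AF_} father. Gene sets are
#' outer-joined; a gene absent from a sample is NA (absent, not zero).
#' Duplicate symbols within one file are aggregated by summing TPM.
#'
#' @param files Character vector of file paths.
#' @return An \code{expression_matrix}: data.frame with column \code{gene}
#'   then one numeric column per sample (named by file stem), plus a
#'   \code{roles} attribute mapping column name to role.
#' @export
combine_expression <- function(files) {
  stopifnot(length(files) >= 1)
  tabs <- list(); roles <- character(0)
  for (f in files) {
    role <- parse_expr_role(f)
    df <- utils::read.table(f, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, quote = "")
    if (ncol(df) < 2) stop("expression file ", f, " needs two columns")
    val <- suppressWarnings(as.numeric(df[[2]]))
    n_bad <- sum(is.na(val) & !is.na(df[[2]]) & nzchar(df[[2]]))
    if (n_bad) stop(n_bad, " non-numeric expression value(s) in ", f)
    agg <- stats::aggregate(val, list(gene = as.character(df[[1]])), sum)
    nm <- sub("\\.[^.]*$", "", basename(f))
    names(agg) <- c("gene", nm)
    tabs[[nm]] <- agg
    roles[nm] <- role
  }
  if (anyDuplicated(roles[roles == "proband"]) ||
      sum(roles == "proband") > 1 || sum(roles == "mother") > 1 ||
      sum(roles == "father") > 1) {
    stop("more than one expression file maps to the same family role")
  }
  mat <- Reduce(function(a, b) merge(a, b, by = "gene", all = TRUE), tabs)
  mat <- mat[order(mat$gene), , drop = FALSE]
  rownames(mat) <- NULL
  structure(mat, class = c("expression_matrix", "data.frame"), roles = roles)
}

expr_lookup <- function(mat, role) {
  roles <- attr(mat, "roles")
  col <- names(roles)[roles == role]
  if (!length(col)) return(NULL)
  stats::setNames(mat[[col[1]]], mat$gene)
}

render_expr <- function(symbols, values) {
  if (!length(symbols)) return("-")
  v <- ifelse(is.na(values), "-", vapply(values, fmt_num, ""))
  paste(sprintf("%s(%s)", symbols, v), collapse = ";")
}

#' Append per-role expression columns for SV-associated genes
#'
#' For each SV row, the overlap / upstream / downstream gene symbols (from
#' [annotate_genes()]) are rendered as \code{SYMBOL(value)} with the role's
#' expression value, \code{SYMBOL(-)} when the gene is absent from the
#' matrix, and "-" for an empty list. Column sets by design:
#' solo 3 (proband), duo 6 (proband + one parent), trio 9.
#'
#' @param callset An \code{sv_call_set} already passed through
#'   [annotate_genes()].
#' @param matrix An \code{expression_matrix}.
#' @param design "solo", "duo" or "trio".
#' @return The call set with expression columns appended.
#' @export
attach_expression <- function(callset, matrix, design = c("solo", "duo", "trio")) {
  design <- match.arg(design)
  if (is.null(callset$gene_annotation)) {
    stop("call set has no gene annotation; run annotate_genes() first")
  }
  roles <- switch(design,
    solo = "proband",
    duo = c("proband", intersect(c("mother", "father"), attr(matrix, "roles"))),
    trio = c("proband", "mother", "father"))
  col_tag <- c(proband = "Proband", mother = "Mother", father = "Father")
  sub_tag <- c(proband = "proband", mother = "mother", father = "father")
  ann <- callset$gene_annotation
  for (role in roles) {
    lut <- expr_lookup(matrix, role)
    if (is.null(lut)) lut <- stats::setNames(numeric(0), character(0))
    ov <- vapply(ann, function(a) render_expr(a$overlaps$symbol,
                                              lut[a$overlaps$symbol]), "")
    up <- vapply(ann, function(a) render_expr(a$upstream$symbol,
                                              lut[a$upstream$symbol]), "")
    dn <- vapply(ann, function(a) render_expr(a$downstream$symbol,
                                              lut[a$downstream$symbol]), "")
    callset$calls[[paste0("Overlap", col_tag[role], "EXP")]] <- ov
    callset$calls[[paste0("NonOverlapUP", sub_tag[role], "EXP")]] <- up
    callset$calls[[paste0("NonOverlapDN", sub_tag[role], "EXP")]] <- dn
  }
  callset
}
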
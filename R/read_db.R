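# Readers for external SV frequency databases: DGV, DECIPHER and the
# optical-mapping control database (BNDB, split into per-type files).
# Column mapping is configuration-driven because the public download schemas
# drift across releases; defaults target the standard layouts.

db_sources <- c("DGV", "DECIPHER", "BNDB", "INTERNAL")

# source vocabulary -> the five coarse classes used for matching
dgv_type_map <- c(
  "loss" = "deletion", "deletion" = "deletion",
  "gain" = "duplication", "duplication" = "duplication",
  "tandem duplication" = "duplication",
  "insertion" = "insertion", "mobile element insertion" = "insertion",
  "novel sequence insertion" = "insertion",
  "inversion" = "inversion", "translocation" = "translocation"
)

default_db_map <- function(source) {
  switch(source,
    DGV = list(chrom = "chr", start = "start", end = "end",
               type = "variantsubtype", sample = "samples",
               size = NULL, zygosity = NULL, confidence = NULL,
               n_samples = "samplesize", multi_sample = TRUE),
    DECIPHER = list(chrom = "chr", start = "start", end = "end",
                    type = "type", sample = "sample_id",
                    size = NULL, zygosity = NULL, confidence = NULL,
                    n_samples = NULL, multi_sample = FALSE),
    BNDB = list(chrom = "RefcontigID1", start = "RefStartPos", end = "RefEndPos",
                type = "Type", sample = "Sample", size = "Size",
                zygosity = "Zygosity", confidence = "Confidence",
                n_samples = NULL, multi_sample = FALSE)
  )
}

new_db_variant_set <- function(source, records, n_samples) {
  stopifnot(source %in% db_sources)
  needed <- c("sample_label", "chrom", "chrom2", "ref_start", "ref_end",
              "sv_class", "size_bp", "zygosity", "confidence")
  for (nm in setdiff(needed, names(records))) {
    records[[nm]] <- switch(nm,
      chrom2 = records$chrom, zygosity = "unknown",
      size_bp = NA_real_, confidence = NA_real_, NA)
  }
  if (n_samples <= 0) stop("database n_samples must be positive")
  structure(list(source = source, n_samples = n_samples,
                 records = records[, union(needed, names(records)), drop = FALSE],
                 index_env = new.env(parent = emptyenv())),
            class = "db_variant_set")
}

#' @export
print.db_variant_set <- function(x, ...) {
  cat(sprintf("<db_variant_set> source=%s records=%d n_samples=%d\n",
              x$source, nrow(x$records), x$n_samples))
  invisible(x)
}

#' Read an external SV database table (DGV or DECIPHER)
#'
#' Maps the source's variant-class vocabulary onto the five coarse classes
#' (e.g. DGV "loss" to deletion, "gain" to duplication); rows of unmappable
#' class are skipped with a warning giving the count.
#'
#' @param source "DGV" or "DECIPHER".
#' @param path Tab-delimited table in the source's download schema.
#' @param column_map Named list locating the chrom/start/end/type/sample
#'   (and optionally size/zygosity/confidence/n_samples) columns; defaults
#'   per source. DGV's \code{samples} field may hold comma-separated sample
#'   lists (\code{multi_sample = TRUE}).
#' @param n_samples_override Cohort size to use in the frequency denominator
#'   instead of the count of distinct sample identifiers in the file.
#' @return A \code{db_variant_set}.
#' @export
read_external_db <- function(source = c("DGV", "DECIPHER"), path,
                             column_map = NULL, n_samples_override = NULL) {
  source <- match.arg(source)
  if (is.null(column_map)) column_map <- default_db_map(source)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE)
  names(df) <- sub("^#", "", names(df))
  for (f in c("chrom", "start", "end", "type")) {
    if (!column_map[[f]] %in% names(df)) {
      stop(source, " table ", path, " lacks column '", column_map[[f]], "'")
    }
  }
  type_raw <- tolower(trimws(df[[column_map$type]]))
  cls <- ifelse(type_raw %in% names(dgv_type_map), dgv_type_map[type_raw],
                ifelse(type_raw %in% c("insertion", "deletion", "duplication",
                                       "inversion", "translocation"),
                       type_raw, NA))
  n_bad <- sum(is.na(cls))
  if (n_bad) warning(n_bad, " ", source, " row(s) of unmappable variant class skipped")
  keep <- !is.na(cls)
  if (!any(keep)) stop("no rows with a mappable variant class in ", path)
  df <- df[keep, , drop = FALSE]
  cls <- cls[keep]

  chrom <- vapply(df[[column_map$chrom]], function(x) {
    tryCatch(normalize_chromosome(x), ogmsv_unsupported_contig = function(e) NA_integer_)
  }, integer(1), USE.NAMES = FALSE)
  keep2 <- !is.na(chrom)
  if (sum(!keep2)) warning(sum(!keep2), " ", source, " row(s) on unsupported contigs skipped")
  df <- df[keep2, , drop = FALSE]; cls <- cls[keep2]; chrom <- chrom[keep2]

  samp_col <- column_map$sample
  sample_label <- if (!is.null(samp_col) && samp_col %in% names(df)) {
    as.character(df[[samp_col]])
  } else sprintf("%s_rec%d", source, seq_len(nrow(df)))

  rec <- data.frame(
    sample_label = sample_label, chrom = chrom, chrom2 = chrom,
    ref_start = as.numeric(df[[column_map$start]]),
    ref_end = as.numeric(df[[column_map$end]]),
    sv_class = unname(cls), stringsAsFactors = FALSE
  )
  if (!is.null(column_map$size) && column_map$size %in% names(df)) {
    rec$size_bp <- as.numeric(df[[column_map$size]])
  }
  if (isTRUE(column_map$multi_sample)) {
    # expand comma-separated sample lists so unique-sample counting works
    parts <- strsplit(rec$sample_label, ",")
    rec <- rec[rep(seq_len(nrow(rec)), lengths(parts)), , drop = FALSE]
    rec$sample_label <- trimws(unlist(parts))
    rec$db_entry <- rep(seq_along(parts), lengths(parts))
  } else {
    rec$db_entry <- seq_len(nrow(rec))
  }

  n_samples <- n_samples_override
  if (is.null(n_samples) && !is.null(column_map$n_samples) &&
      column_map$n_samples %in% names(df)) {
    n_samples <- suppressWarnings(max(as.numeric(df[[column_map$n_samples]]), na.rm = TRUE))
    if (!is.finite(n_samples)) n_samples <- NULL
  }
  if (is.null(n_samples)) n_samples <- length(unique(rec$sample_label))
  new_db_variant_set(source, rec, as.integer(n_samples))
}

#' Aggregate the per-type control-database files into one variant set
#'
#' The optical-mapping control database ships as per-SV-type files (indels,
#' duplications, inversions, translocations) per reference build; files are
#' selected by a filename pattern and merged.
#'
#' @param dir Directory holding the per-type files.
#' @param reference_pattern Filename substring selecting the build, e.g.
#'   "hg19" or "hg38".
#' @param n_samples Number of diploid control samples represented
#'   (default 234).
#' @param column_map Column mapping, defaulting to the SMAP-style layout.
#' @return A \code{db_variant_set} with source "BNDB".
#' @export
aggregate_bndb <- function(dir, reference_pattern = "hg19", n_samples = 234,
                           column_map = default_db_map("BNDB")) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[grepl(reference_pattern, basename(files), fixed = TRUE)]
  if (!length(files)) {
    stop("no control-database files matching '", reference_pattern, "' in ", dir)
  }
  type_tokens <- c("indel", "dup", "inversion", "translocation")
  found <- vapply(type_tokens, function(t) any(grepl(t, tolower(basename(files)))), logical(1))
  if (!all(found)) {
    warning("control-database type file(s) missing: ",
            paste(type_tokens[!found], collapse = ", "))
  }
  recs <- lapply(files, function(f) {
    df <- utils::read.table(f, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                            quote = "", comment.char = "#", check.names = FALSE)
    data.frame(
      sample_label = as.character(df[[column_map$sample]]),
      chrom = normalize_chromosome(df[[column_map$chrom]]),
      chrom2 = if ("RefcontigID2" %in% names(df))
        normalize_chromosome(df[["RefcontigID2"]])
      else normalize_chromosome(df[[column_map$chrom]]),
      ref_start = as.numeric(df[[column_map$start]]),
      ref_end = as.numeric(df[[column_map$end]]),
      sv_class = sv_class(df[[column_map$type]]),
      size_bp = if (!is.null(column_map$size) && column_map$size %in% names(df)) {
        v <- as.numeric(df[[column_map$size]]); v[!is.na(v) & v < 0] <- NA; v
      } else NA_real_,
      zygosity = if (!is.null(column_map$zygosity) && column_map$zygosity %in% names(df))
        normalize_zygosity(df[[column_map$zygosity]]) else "unknown",
      confidence = if (!is.null(column_map$confidence) && column_map$confidence %in% names(df)) {
        v <- as.numeric(df[[column_map$confidence]]); v[!is.na(v) & v < 0] <- NA; v
      } else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  rec <- do.call(rbind, recs)
  rec$db_entry <- seq_len(nrow(rec))
  new_db_variant_set("BNDB", rec, as.integer(n_samples))
}
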
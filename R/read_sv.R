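# Readers for optical-mapping SV call files.
#
# Two on-disk dialects exist:
#   * single_enzyme — an unmodified SMAP from the SV caller (one labelling
#     enzyme, e.g. DLE1), with unsuffixed quality columns such as
#     Found_in_self_molecules / Fail_assembly_chimeric_score.
#   * svmerge — the merged two-enzyme TXT, where every quality column comes
#     in a BSPQI- and a BSSSI-suffixed pair; the pairs are harmonized
#     disjunctively (self-molecule support or chimeric pass from either
#     enzyme counts).
#
# Comment lines start with "#"; the column declaration line starts with "#h".
# Files without a "#h" line use their first non-comment line as the header.

# Default mapping from canonical field -> candidate source column names, in
# priority order. Mappings are config-driven because column names drift
# across caller releases.
smap_default_map <- function() {
  list(
    call_id    = c("SmapEntryID", "SVIndex", "SVId"),
    chrom      = c("RefcontigID1", "RefContigID1", "Chromosome"),
    chrom2     = c("RefcontigID2", "RefContigID2"),
    ref_start  = c("RefStartPos", "RefStart"),
    ref_end    = c("RefEndPos", "RefEnd"),
    size_bp    = c("Size", "SVsize"),
    sv_type    = c("Type", "SVType"),
    confidence = c("Confidence", "Conf"),
    zygosity   = c("Zygosity",  "SVzygosity"),
    sample     = c("Sample", "SampleID")
  )
}

sv_pick <- function(cols, candidates) {
  hit <- candidates[candidates %in% cols]
  if (length(hit)) hit[1] else NA_character_
}

# yes/no style harmonization across a set of columns; disjunctive on `hit`.
harmonize_flag <- function(df, cols, hit, miss, default) {
  cols <- cols[cols %in% names(df)]
  if (!length(cols)) return(rep(default, nrow(df)))
  vals <- lapply(cols, function(cl) tolower(trimws(as.character(df[[cl]]))))
  any_hit <- Reduce(`|`, lapply(vals, function(v) v %in% hit))
  all_na <- Reduce(`&`, lapply(vals, function(v) !nzchar(v) | is.na(v)))
  out <- rep(miss, nrow(df))
  out[any_hit] <- hit[1]
  out[all_na] <- default
  out
}

#' Read an SV call file (SMAP or SVmerge TXT)
#'
#' Parses one sample's SV calls, normalizes coordinates/type/zygosity, and
#' harmonizes the molecule-support, chimeric-score, parental-support and
#' control-support quality flags across the two dialects. All source columns
#' not consumed by the canonical fields are carried through verbatim
#' ("extras") and re-emitted in reports.
#'
#' @param path Path to the SMAP or TXT file.
#' @param dialect "auto" (default) sniffs for enzyme-suffixed (BSPQI/BSSSI)
#'   quality columns, otherwise "single_enzyme" or "svmerge".
#' @param sample Optional sample label overriding any in-file label.
#' @param column_map Named list mapping canonical fields to candidate source
#'   column names; defaults cover standard caller output.
#' @return An object of class \code{sv_call_set}: a list with \code{calls}
#'   (data.frame of canonical + extra columns), \code{dialect},
#'   \code{design} ("solo"/"duo"/"trio", inferred from which support columns
#'   are present), \code{sample} and \code{source_header}.
#' @export
read_sv_file <- function(path, dialect = c("auto", "single_enzyme", "svmerge"),
                         sample = NULL, column_map = smap_default_map()) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  header_lines <- lines[startsWith(lines, "#")]
  h_line <- header_lines[startsWith(header_lines, "#h")]
  body <- lines[!startsWith(lines, "#")]
  if (length(h_line)) {
    cols <- strsplit(sub("^#h[ \t]*", "", h_line[1]), "\t")[[1]]
  } else {
    if (!length(body)) stop("no header found in ", path)
    cols <- strsplit(body[1], "\t")[[1]]
    body <- body[-1]
  }
  cols <- trimws(cols)
  body <- body[nzchar(trimws(body))]
  if (length(body)) {
    df <- utils::read.table(text = body, sep = "\t", col.names = cols,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            colClasses = "character", quote = "",
                            comment.char = "")
  } else {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                        check.names = FALSE)
  }

  is_svmerge <- any(grepl("BSPQI|BSSSI", cols))
  if (dialect == "auto") dialect <- if (is_svmerge) "svmerge" else "single_enzyme"

  used <- character(0)
  get_col <- function(field) {
    nm <- sv_pick(cols, column_map[[field]])
    if (!is.na(nm)) used <<- c(used, nm)
    if (is.na(nm)) NULL else df[[nm]]
  }

  ref_start <- get_col("ref_start"); ref_end <- get_col("ref_end")
  sv_type <- get_col("sv_type")
  missing_mand <- c("RefStartPos", "RefEndPos", "Type")[c(is.null(ref_start), is.null(ref_end), is.null(sv_type))]
  if (length(missing_mand)) {
    stop("SV file ", path, " is missing mandatory columns: ",
         paste(missing_mand, collapse = ", "))
  }

  chrom_raw <- get_col("chrom")
  chrom2_raw <- get_col("chrom2")
  calls <- data.frame(
    call_id = {
      v <- get_col("call_id")
      if (is.null(v)) as.character(seq_len(nrow(df))) else as.character(v)
    },
    chrom = normalize_chromosome(if (is.null(chrom_raw)) rep("1", nrow(df)) else chrom_raw),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  calls$chrom2 <- if (is.null(chrom2_raw)) calls$chrom else normalize_chromosome(chrom2_raw)
  calls$ref_start <- as.numeric(ref_start)
  calls$ref_end <- as.numeric(ref_end)
  calls$sv_type <- as.character(sv_type)
  calls$sv_class <- sv_class(calls$sv_type)
  calls$is_nbase <- is_nbase_type(calls$sv_type)
  sz <- get_col("size_bp")
  sz <- if (is.null(sz)) rep(NA_real_, nrow(df)) else as.numeric(sz)
  sz[!is.na(sz) & sz < 0] <- NA_real_  # -1 sentinel: size not reported
  calls$size_bp <- sz
  conf <- get_col("confidence")
  conf <- if (is.null(conf)) rep(NA_real_, nrow(df)) else as.numeric(conf)
  conf[!is.na(conf) & conf < 0] <- NA_real_  # -1 sentinel: no score for this type
  calls$confidence <- conf
  zyg <- get_col("zygosity")
  calls$zygosity <- if (is.null(zyg)) rep("unknown", nrow(df)) else normalize_zygosity(zyg)

  # Quality flags, harmonized disjunctively across enzymes for SVmerge.
  self_cols <- c("Found_in_self_molecules",
                 "Found_in_self_BSPQI_molecules", "Found_in_self_BSSSI_molecule",
                 "Found_in_self_BSSSI_molecules")
  chim_cols <- c("Fail_assembly_chimeric_score",
                 "Fail_BSPQI_assembly_chimeric_score", "Fail_BSSSI_assembly_chimeric_score")
  par_cols <- c("Found_in_parents_molecules",
                "Found_in_parents_BSPQI_molecules", "Found_in_parents_BSSSI_molecules")
  ctrl_cols <- c("Found_in_control_molecules",
                 "Found_in_control_BSPQI_molecules", "Found_in_control_BSSSI_molecules")
  used <- c(used, self_cols, chim_cols, par_cols, ctrl_cols)

  calls$found_in_self <- harmonize_flag(df, self_cols, hit = "yes", miss = "no",
                                        default = "unknown")
  calls$chimeric_pass <- harmonize_flag(df, chim_cols, hit = "pass", miss = "fail",
                                        default = "unknown")
  calls$parental_support <- harmonize_parental(df, par_cols)
  calls$control_support <- {
    cl <- ctrl_cols[ctrl_cols %in% names(df)]
    if (!length(cl)) rep("not_applicable", nrow(df))
    else harmonize_flag(df, ctrl_cols, hit = "yes", miss = "no", default = "no")
  }

  design <- if (any(par_cols %in% cols)) "trio"
            else if (any(ctrl_cols %in% cols)) "duo" else "solo"

  samp <- sample
  if (is.null(samp)) {
    v <- get_col("sample")
    samp <- if (!is.null(v) && length(v) && nzchar(v[1])) v[1]
            else sub("\\.(smap|txt)$", "", basename(path), ignore.case = TRUE)
  }

  extras <- setdiff(cols, unique(used))
  for (e in extras) calls[[e]] <- df[[e]]

  bad <- calls$sv_class != "translocation" & !is.na(calls$ref_start) &
    !is.na(calls$ref_end) & calls$ref_start > calls$ref_end
  if (any(bad)) {
    stop("ref_start > ref_end for non-translocation rows: ",
         paste(utils::head(calls$call_id[bad], 5), collapse = ", "))
  }

  structure(
    list(sample = samp, dialect = dialect, design = design, calls = calls,
         source_header = header_lines, extra_cols = extras),
    class = "sv_call_set"
  )
}

harmonize_parental <- function(df, par_cols) {
  cl <- par_cols[par_cols %in% names(df)]
  if (!length(cl)) return(rep("not_applicable", nrow(df)))
  vals <- lapply(cl, function(x) tolower(trimws(as.character(df[[x]]))))
  out <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    v <- vapply(vals, `[`, "", i)
    v[v == "-"] <- "none"                  # SVmerge prints "-" for no support
    v <- v[nzchar(v)]
    has_m <- any(v %in% c("mother", "both"))
    has_f <- any(v %in% c("father", "both"))
    out[i] <- if (has_m && has_f) "both" else if (has_m) "mother"
              else if (has_f) "father" else "none"
  }
  out
}

#' @export
print.sv_call_set <- function(x, ...) {
  cat(sprintf("<sv_call_set> sample=%s dialect=%s design=%s calls=%d\n",
              x$sample, x$dialect, x$design, nrow(x$calls)))
  invisible(x)
}

#' Write an SV call set back to a tab-delimited SMAP-style file
#'
#' Canonical fields are re-emitted under standard column names together with
#' every pass-through extra column, so reading then writing loses no data.
#'
#' @param callset An \code{sv_call_set}.
#' @param path Output path.
#' @export
write_sv_file <- function(callset, path) {
  calls <- callset$calls
  out <- data.frame(
    SmapEntryID = calls$call_id,
    RefcontigID1 = calls$chrom, RefcontigID2 = calls$chrom2,
    RefStartPos = calls$ref_start, RefEndPos = calls$ref_end,
    Type = calls$sv_type, Size = calls$size_bp,
    Confidence = ifelse(is.na(calls$confidence), -1, calls$confidence),
    Zygosity = calls$zygosity,
    Found_in_self_molecules = calls$found_in_self,
    Fail_assembly_chimeric_score = calls$chimeric_pass,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  if (!all(calls$parental_support == "not_applicable")) {
    out$Found_in_parents_molecules <- calls$parental_support
  }
  if (!all(calls$control_support == "not_applicable")) {
    out$Found_in_control_molecules <- calls$control_support
  }
  for (e in callset$extra_cols) out[[e]] <- calls[[e]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# SMAP-style SV call table",
               paste0("#h ", paste(names(out), collapse = "\t"))), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = "")
  invisible(path)
}
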
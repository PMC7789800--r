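# Quality filtration, inheritance/type categorization into the sheet
# taxonomy, and end-to-end orchestration of the annotation pipeline.
#
# Sheet taxonomy (fixed order; "all" is always the last sheet):
#   solo : indel_dup | inv | trans | [Mismatch] | all_PG_OV | all
#   duo  : indel_dup_notShared | indel_dup_Shared | inv | trans |
#          [Mismatch] | all_PG_OV | all
#   trio : indel_dup_denovo | indel_dup_both | indel_dup_mother |
#          indel_dup_father | indel_dup_cmpdHET | inv | trans |
#          [Mismatch] | all_PG_OV | all
# "Mismatch" exists only for the dual-enzyme (svmerge) dialect, giving
# 5/6, 6/7 and 9/10 sheets for solo/duo/trio.

#' Sheet plan for a design and dialect
#'
#' @param design "solo", "duo" or "trio".
#' @param dialect "single_enzyme" or "svmerge".
#' @return Character vector of sheet names in their fixed workbook order.
#' @export
sheet_plan <- function(design = c("solo", "duo", "trio"),
                       dialect = c("single_enzyme", "svmerge")) {
  design <- match.arg(design); dialect <- match.arg(dialect)
  core <- switch(design,
    solo = "indel_dup",
    duo = c("indel_dup_notShared", "indel_dup_Shared"),
    trio = c("indel_dup_denovo", "indel_dup_both", "indel_dup_mother",
             "indel_dup_father", "indel_dup_cmpdHET"))
  c(core, "inv", "trans",
    if (dialect == "svmerge") "Mismatch",
    "all_PG_OV", "all")
}

#' Default quality filtration
#'
#' Keeps a call iff it is supported by self molecules, and — for
#' duplications, inversions and translocations — additionally passes the
#' chimeric-score check. This is the gate applied to every sheet except
#' "all", "all_PG_OV" and "Mismatch".
#'
#' @param callset An \code{sv_call_set}.
#' @return Logical vector over the rows of \code{callset$calls}.
#' @export
default_filter <- function(callset) {
  calls <- callset$calls
  calls$found_in_self == "yes" &
    (!calls$sv_class %in% c("duplication", "inversion", "translocation") |
       calls$chimeric_pass == "pass")
}

#' Assign filtered calls to report sheets
#'
#' Insertion/deletion/duplication calls are routed by parental support
#' (trio: none = de novo, both, mother, father; the compound-heterozygous
#' candidate sheet is the union of the mother-only and father-only sheets)
#' or control support (duo: notShared / Shared). The inversion sheet takes
#' all inversion subtypes; the translocation sheet takes only
#' translocation_intrachr/interchr (the "*_common" translocation types are
#' flagged likely-false upstream and excluded); "Mismatch" takes MisMatch
#' rows; "_nbase"-suffixed calls appear only in "all".
#'
#' @param callset An \code{sv_call_set} (already carrying quality flags).
#' @param design "solo", "duo" or "trio".
#' @return Named list of integer row-index vectors, one per non-"all" sheet.
#' @export
categorize <- function(callset, design = c("solo", "duo", "trio")) {
  design <- match.arg(design)
  calls <- callset$calls
  if (design == "trio" && all(calls$parental_support == "not_applicable") &&
      nrow(calls) > 0) {
    stop("trio design but input has no parental-support columns")
  }
  if (design == "duo" && all(calls$control_support == "not_applicable") &&
      nrow(calls) > 0) {
    stop("duo design but input has no control-support columns")
  }
  keep <- default_filter(callset) & !calls$is_nbase
  idx <- seq_len(nrow(calls))
  indel <- keep & calls$sv_class %in% indel_classes
  out <- list()
  if (design == "solo") {
    out$indel_dup <- idx[indel]
  } else if (design == "duo") {
    out$indel_dup_notShared <- idx[indel & calls$control_support == "no"]
    out$indel_dup_Shared <- idx[indel & calls$control_support == "yes"]
  } else {
    ps <- calls$parental_support
    out$indel_dup_denovo <- idx[indel & ps == "none"]
    out$indel_dup_both <- idx[indel & ps == "both"]
    out$indel_dup_mother <- idx[indel & ps == "mother"]
    out$indel_dup_father <- idx[indel & ps == "father"]
    out$indel_dup_cmpdHET <- sort(c(out$indel_dup_mother, out$indel_dup_father))
  }
  out$inv <- idx[keep & calls$sv_class == "inversion"]
  out$trans <- idx[keep & tolower(calls$sv_type) %in%
                     c("translocation_intrachr", "translocation_interchr")]
  out$Mismatch <- idx[calls$sv_class == "mismatch"]
  out
}

pg_hit_rows <- function(calls) {
  has <- function(col) if (col %in% names(calls)) calls[[col]] != "-" else
    rep(FALSE, nrow(calls))
  which(has("Overlap_PG") | has("Non_Overlap_UP_PG") | has("Non_Overlap_DN_PG"))
}

#' Assemble an annotated report
#'
#' Builds the sheet-partitioned view of a fully annotated call set.
#' "all" holds every input row; "all_PG_OV" the rows whose genes intersect
#' the primary gene list (no quality gate); the remaining sheets follow
#' [categorize()] after [default_filter()].
#'
#' @param callset Annotated \code{sv_call_set}.
#' @param design,dialect Report mode.
#' @return An \code{annotated_report}: list with \code{sample},
#'   \code{design}, \code{dialect}, \code{sheet_names} and \code{sheets}
#'   (named list of data.frames).
#' @export
build_report <- function(callset, design = callset$design,
                         dialect = callset$dialect) {
  plan <- sheet_plan(design, dialect)
  cat_idx <- categorize(callset, design)
  calls <- callset$calls
  sheets <- list()
  for (sh in plan) {
    rows <- switch(sh,
      all = seq_len(nrow(calls)),
      all_PG_OV = pg_hit_rows(calls),
      Mismatch = cat_idx$Mismatch,
      cat_idx[[sh]])
    sheets[[sh]] <- calls[rows, , drop = FALSE]
  }
  structure(list(sample = callset$sample, design = design, dialect = dialect,
                 sheet_names = plan, sheets = sheets),
            class = "annotated_report")
}

#' @export
print.annotated_report <- function(x, ...) {
  cat(sprintf("<annotated_report> sample=%s design=%s dialect=%s\n",
              x$sample, x$design, x$dialect))
  for (sh in x$sheet_names) {
    cat(sprintf("  %-22s %d rows\n", sh, nrow(x$sheets[[sh]])))
  }
  invisible(x)
}

#' Write / read a sheet-partitioned report
#'
#' The report is written as a workbook directory: one TSV per sheet plus a
#' \code{sheets.tsv} index fixing the sheet order — a plain-text container
#' that diffs cleanly and feeds pipelines directly. The default directory
#' name is \code{<sample>_<design>}.
#'
#' @param report An \code{annotated_report}.
#' @param path Output directory; created if needed. Defaults to
#'   \code{<sample>_<design>} under the working directory.
#' @return The directory path, invisibly (write); an
#'   \code{annotated_report} (read).
#' @export
write_report <- function(report, path = NULL) {
  if (is.null(path)) path <- paste0(report$sample, "_", report$design)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create report directory ", path)
  idx <- data.frame(order = seq_along(report$sheet_names),
                    sheet = report$sheet_names,
                    file = paste0(sprintf("%02d_", seq_along(report$sheet_names)),
                                  report$sheet_names, ".tsv"))
  utils::write.table(idx, file.path(path, "sheets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (i in seq_len(nrow(idx))) {
    utils::write.table(report$sheets[[idx$sheet[i]]],
                       file.path(path, idx$file[i]), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  idx <- utils::read.table(file.path(path, "sheets.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  idx <- idx[order(idx$order), , drop = FALSE]
  sheets <- lapply(seq_len(nrow(idx)), function(i) {
    utils::read.table(file.path(path, idx$file[i]), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, quote = "", check.names = FALSE,
                      colClasses = "character", comment.char = "")
  })
  names(sheets) <- idx$sheet
  structure(list(sample = basename(path), design = NA, dialect = NA,
                 sheet_names = idx$sheet, sheets = sheets),
            class = "annotated_report")
}

#' Append all frequency and zygosity columns to a call set
#'
#' Runs every configured database against every call and appends, per row:
#' DGV_Count, DGV_Freq_Perc, DECIPHER_Freq_Perc, BNG_Freq_Perc_Filtered,
#' BNG_Freq_Perc_UnFiltered, BNG_Homozygotes, MotherZygosity,
#' FatherZygosity, Internal_Freq_Perc_Filtered,
#' Internal_Freq_Perc_Unfiltered and Internal_Homozygotes. Percentages are
#' displayed truncated to two decimals (full precision drives any numeric
#' filtering); non-applicable fields contain dashes.
#'
#' @param callset An \code{sv_call_set}.
#' @param dgv,decipher,bndb,internal \code{db_variant_set}s (any may be
#'   NULL to skip its columns).
#' @param family Query sample's family id (needed for internal frequency
#'   and parental zygosity).
#' @param criteria A [match_criteria()].
#' @param project Optional project identifier for the query sample.
#' @return The call set with frequency columns appended.
#' @export
annotate_frequencies <- function(callset, dgv = NULL, decipher = NULL,
                                 bndb = NULL, internal = NULL, family = NULL,
                                 criteria = match_criteria(), project = NULL) {
  calls <- callset$calls
  n <- nrow(calls)
  fmt_pct <- function(x) ifelse(is.na(x), "-",
                                formatC(trunc_pct(x), format = "f", digits = 2))
  if (!is.null(dgv)) {
    r <- lapply(seq_len(n), function(i)
      public_db_frequency(calls[i, , drop = FALSE], dgv, criteria))
    calls$DGV_Count <- vapply(r, `[[`, 0, "n_unique_samples")
    calls$DGV_Freq_Perc <- fmt_pct(vapply(r, `[[`, 0, "freq_perc"))
  }
  if (!is.null(decipher)) {
    r <- lapply(seq_len(n), function(i)
      public_db_frequency(calls[i, , drop = FALSE], decipher, criteria))
    calls$DECIPHER_Freq_Perc <- fmt_pct(vapply(r, `[[`, 0, "freq_perc"))
  }
  if (!is.null(bndb)) {
    r <- lapply(seq_len(n), function(i)
      bndb_frequency(calls[i, , drop = FALSE], bndb, criteria))
    calls$BNG_Freq_Perc_Filtered <- fmt_pct(vapply(r, `[[`, 0, "freq_perc_filtered"))
    calls$BNG_Freq_Perc_UnFiltered <- fmt_pct(vapply(r, `[[`, 0, "freq_perc_unfiltered"))
    calls$BNG_Homozygotes <- vapply(r, `[[`, 0, "n_homozygotes")
  }
  if (!is.null(internal)) {
    if (is.null(family)) {
      calls$MotherZygosity <- "-"
      calls$FatherZygosity <- "-"
      # family id -1 matches no cohort nanoID: plain cohort-wide frequency
      r <- lapply(seq_len(n), function(i)
        internal_frequency(calls[i, , drop = FALSE], internal,
                           query_family = -1, criteria = criteria,
                           project = project))
    } else {
      z <- lapply(seq_len(n), function(i)
        parental_zygosity(calls[i, , drop = FALSE], internal, family,
                          criteria = criteria, project = project))
      calls$MotherZygosity <- vapply(z, `[[`, "", "mother_zygosity")
      calls$FatherZygosity <- vapply(z, `[[`, "", "father_zygosity")
      r <- lapply(seq_len(n), function(i)
        internal_frequency(calls[i, , drop = FALSE], internal, family,
                           criteria = criteria, project = project))
    }
    calls$Internal_Freq_Perc_Filtered <- fmt_pct(vapply(r, `[[`, 0, "freq_perc_filtered"))
    calls$Internal_Freq_Perc_Unfiltered <- fmt_pct(vapply(r, `[[`, 0, "freq_perc_unfiltered"))
    calls$Internal_Homozygotes <- vapply(r, `[[`, 0, "n_homozygotes")
  }
  callset$calls <- calls
  callset
}

#' Run the full annotation pipeline
#'
#' Orchestrates read, external/internal frequency, gene overlap, expression,
#' gene-list intersection, filtration/categorization and report writing for
#' one of the six design-by-dialect entry modes. Missing optional inputs
#' (expression, gene list) skip their columns with a logged notice; any
#' stage failure aborts with a stage-named error.
#'
#' @param config Named list with elements: \code{sv_file} (path),
#'   \code{dialect} ("auto"/"single_enzyme"/"svmerge"), \code{design}
#'   ("solo"/"duo"/"trio"), \code{bed} + \code{bed_fmt}, \code{dgv},
#'   \code{decipher} (paths), \code{bndb_dir} + \code{bndb_reference} +
#'   \code{bndb_n_samples}, \code{internal_db} (path to a persisted internal
#'   database), \code{family_id}, \code{project}, \code{expression_files},
#'   \code{genelist} (CSV path) or \code{terms} + \code{snapshots},
#'   \code{criteria} ([match_criteria()]), \code{k_nearest}, \code{out}
#'   (report directory). Only \code{sv_file} and \code{design} are
#'   mandatory.
#' @param quiet Suppress per-stage log messages.
#' @return The \code{annotated_report}, invisibly; the report is written to
#'   \code{config$out} (or the default directory name) unless
#'   \code{config$out} is \code{NA}.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  log <- function(...) if (!quiet) message("[ogmsv] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  criteria <- config$criteria %||% match_criteria()
  design <- match.arg(config$design, c("solo", "duo", "trio"))

  callset <- stage("read_sv", read_sv_file(config$sv_file,
                                           dialect = config$dialect %||% "auto",
                                           sample = config$sample))
  log("read %d calls (%s, %s) from %s", nrow(callset$calls), callset$dialect,
      design, config$sv_file)

  dgv <- if (!is.null(config$dgv))
    stage("dgv", read_external_db("DGV", config$dgv,
                                  n_samples_override = config$dgv_n_samples))
  decipher <- if (!is.null(config$decipher))
    stage("decipher", read_external_db("DECIPHER", config$decipher,
                                       n_samples_override = config$decipher_n_samples))
  bndb <- if (!is.null(config$bndb_dir))
    stage("bndb", aggregate_bndb(config$bndb_dir,
                                 reference_pattern = config$bndb_reference %||% "hg19",
                                 n_samples = config$bndb_n_samples %||% 234))
  internal <- if (!is.null(config$internal_db)) {
    stage("internal_db",
          if (inherits(config$internal_db, "db_variant_set")) config$internal_db
          else read_internal_db(config$internal_db))
  }
  callset <- stage("frequencies",
                   annotate_frequencies(callset, dgv = dgv, decipher = decipher,
                                        bndb = bndb, internal = internal,
                                        family = config$family_id,
                                        criteria = criteria,
                                        project = config$project))
  log("frequency columns appended")

  if (!is.null(config$bed)) {
    genes <- stage("bed", read_bed(config$bed, fmt = config$bed_fmt %||% "BED"))
    callset <- stage("gene_overlap",
                     annotate_genes(callset, genes, k = config$k_nearest %||% 3))
    log("gene overlap/nearest annotation appended (%d genes)", nrow(genes))
  }

  if (!is.null(config$expression_files)) {
    mat <- stage("expression", combine_expression(config$expression_files))
    callset <- stage("expression", attach_expression(callset, mat, design))
    log("expression columns appended")
  } else log("no expression input; expression columns skipped")

  pg <- NULL
  if (!is.null(config$genelist)) {
    pg <- stage("genelist", read_gene_list(config$genelist))
  } else if (!is.null(config$terms) && !is.null(config$snapshots)) {
    pg <- stage("genelist", build_gene_list(config$terms, config$snapshots))
  }
  if (!is.null(pg) && !is.null(callset$gene_annotation)) {
    callset <- stage("genelist", intersect_primary_genes(callset, pg))
    log("primary-gene-list columns appended (%d genes in list)", nrow(pg))
  } else log("no gene list; PG columns skipped")

  report <- stage("report", build_report(callset, design,
                                         dialect = callset$dialect))
  for (sh in report$sheet_names) {
    log("sheet %-22s %d rows", sh, nrow(report$sheets[[sh]]))
  }
  if (!isTRUE(is.na(config$out))) {
    path <- stage("write", write_report(report, config$out))
    log("report written to %s", path)
  }
  invisible(report)
}
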
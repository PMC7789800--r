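# Internal cohort database: per-sample SV files concatenated under nanoID
# labels, used for (i) family-excluded internal frequency and (ii) parental
# zygosity extraction in duo/trio analyses.

#' Build the internal cohort database from per-sample SV files
#'
#' Each file is read with [read_sv_file()] and its calls are tagged with the
#' serialized nanoID derived from the key (family id + relation per raw
#' sample label). The result can be persisted with
#' [write_internal_db()] and reloaded without the key.
#'
#' @param files Character vector of SMAP/TXT paths, or a list of
#'   \code{sv_call_set} objects.
#' @param key data.frame with columns \code{sample} (raw label matching the
#'   file's sample), \code{family_id}, \code{relation} (1 proband, 2 mother,
#'   3 father).
#' @param project Optional project identifier prefixed to every nanoID.
#' @return A \code{db_variant_set} with source "INTERNAL" whose
#'   \code{sample_label}s are nanoIDs and whose records retain quality flags.
#' @export
build_internal_db <- function(files, key, project = NULL) {
  if (!length(files)) stop("no input files given for internal database")
  stopifnot(all(c("sample", "family_id", "relation") %in% names(key)))
  if (anyDuplicated(key[, c("family_id", "relation")])) {
    stop("duplicate (family_id, relation) pair in key")
  }
  sets <- lapply(files, function(f) {
    if (inherits(f, "sv_call_set")) f else read_sv_file(f)
  })
  recs <- lapply(sets, function(s) {
    i <- match(s$sample, key$sample)
    if (is.na(i)) stop("sample '", s$sample, "' has no row in the key")
    if (!key$relation[i] %in% 1:3) {
      stop("relation code ", key$relation[i], " for sample '", s$sample,
           "' is not supported (trio codes 1-3 only)")
    }
    nid <- format_nanoid(list(project = project, family_id = key$family_id[i],
                              relation = key$relation[i]))
    cc <- s$calls
    data.frame(sample_label = rep(nid, nrow(cc)),
               chrom = cc$chrom, chrom2 = cc$chrom2,
               ref_start = cc$ref_start, ref_end = cc$ref_end,
               sv_class = cc$sv_class, sv_type = cc$sv_type,
               size_bp = cc$size_bp, zygosity = cc$zygosity,
               confidence = cc$confidence,
               found_in_self = cc$found_in_self,
               chimeric_pass = cc$chimeric_pass,
               is_nbase = cc$is_nbase,
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, recs)
  rec$db_entry <- seq_len(nrow(rec))
  # the cohort roster includes samples whose files carry no calls
  roster <- unique(vapply(sets, function(s) {
    j <- match(s$sample, key$sample)
    format_nanoid(list(project = project, family_id = key$family_id[j],
                       relation = key$relation[j]))
  }, ""))
  db <- new_db_variant_set("INTERNAL", rec, length(roster))
  db$samples <- roster
  db
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Persist / reload the internal cohort database as a tab-delimited table
#'
#' @param db A \code{db_variant_set} with source "INTERNAL".
#' @param path File path.
#' @return \code{path} (write) or the reloaded \code{db_variant_set} (read).
#' @export
write_internal_db <- function(db, path) {
  stopifnot(db$source == "INTERNAL")
  con <- file(path, "w")
  on.exit(close(con))
  roster <- db$samples %||% unique(db$records$sample_label)
  writeLines(paste0("#samples\t", paste(roster, collapse = ",")), con)
  utils::write.table(db$records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_internal_db
#' @export
read_internal_db <- function(path) {
  first <- readLines(path, n = 1)
  roster <- NULL
  if (startsWith(first, "#samples")) {
    roster <- strsplit(sub("^#samples\t", "", first), ",")[[1]]
  }
  rec <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  rec$is_nbase <- as.logical(rec$is_nbase)
  roster <- roster %||% unique(rec$sample_label)
  db <- new_db_variant_set("INTERNAL", rec, length(roster))
  db$samples <- roster
  db
}

family_key <- function(project, family_id) {
  p <- if (is.null(project) || is.na(project)) "" else project
  paste(p, family_id)
}

internal_family_of <- function(label) {
  id <- parse_nanoid(label)
  family_key(id$project, id$family_id)
}

#' Internal-cohort frequency of a query SV, excluding the query's family
#'
#' Matching records from samples sharing the query's family identifier are
#' removed from the numerator, and all family members are removed from the
#' denominator: alleles / (2 * (n cohort samples - n family members)) * 100.
#' Within-sample exact duplicate records (same chromosome, breakpoints,
#' type, size and zygosity — the caller occasionally emits these under two
#' call ids) are counted once. The filtered figure additionally requires
#' candidates to be non-"nbase" (not overlapping an assembly gap), supported
#' by self molecules, and, for duplications/inversions/translocations, to
#' pass the chimeric-score check.
#'
#' @param query One-row data.frame/list describing the query SV.
#' @param db Internal \code{db_variant_set} from [build_internal_db()].
#' @param query_family Family id (integer) of the query sample; with
#'   \code{project}, identifies the records to exclude.
#' @param criteria A [match_criteria()].
#' @param project Optional project identifier of the query sample.
#' @return List with \code{freq_perc_filtered}, \code{freq_perc_unfiltered},
#'   \code{n_homozygotes}, allele counts and the denominator used. When the
#'   whole cohort belongs to the family the frequencies are \code{NA} (not
#'   computable), not an error.
#' @export
internal_frequency <- function(query, db, query_family,
                               criteria = match_criteria(), project = NULL) {
  stopifnot(db$source == "INTERNAL")
  fam_key <- family_key(project, query_family)
  roster <- db$samples %||% unique(db$records$sample_label)
  n_family <- sum(vapply(roster, internal_family_of, "") == fam_key)
  denom <- 2 * (db$n_samples - n_family)

  m <- find_matches(query, db, criteria, size_absent_ok = TRUE)$matches
  m <- m[vapply(m$sample_label, internal_family_of, "") != fam_key, , drop = FALSE]
  # collapse duplicate caller records within a sample
  dkey <- paste(m$sample_label, m$chrom, m$ref_start, m$ref_end, m$sv_type,
                m$size_bp, m$zygosity)
  m <- m[!duplicated(dkey), , drop = FALSE]

  gate <- !m$is_nbase & m$found_in_self == "yes" &
    (!m$sv_class %in% c("duplication", "inversion", "translocation") |
       m$chimeric_pass == "pass")
  filt <- m[gate, , drop = FALSE]

  a_un <- count_alleles(m$sample_label, m$zygosity)
  a_fi <- count_alleles(filt$sample_label, filt$zygosity)
  if (denom <= 0) {
    return(list(freq_perc_filtered = NA_real_, freq_perc_unfiltered = NA_real_,
                n_homozygotes = sum(normalize_zygosity(filt$zygosity) == "homozygous"),
                alleles_filtered = a_fi, alleles_unfiltered = a_un,
                denominator = denom))
  }
  list(freq_perc_filtered = a_fi / denom * 100,
       freq_perc_unfiltered = a_un / denom * 100,
       n_homozygotes = sum(normalize_zygosity(filt$zygosity) == "homozygous"),
       alleles_filtered = a_fi, alleles_unfiltered = a_un,
       denominator = denom)
}

#' Parental zygosity of a query SV
#'
#' The query is matched against the mother's (relation 2) and father's
#' (relation 3) records of its family at a tightened size-similarity
#' threshold (default 0.90 — inherited variants are expected to be virtually
#' identical) and standard breakpoint windows. The matched records'
#' zygosities are reported per parent; "-" when no record matches; multiple
#' discordant matches are joined as unique values in the fixed order
#' homozygous < heterozygous < unknown.
#'
#' @param query One-row data.frame/list describing the query SV.
#' @param db Internal \code{db_variant_set}.
#' @param family Family id of the query sample.
#' @param criteria Base [match_criteria()]; its \code{perc_similarity} is
#'   overridden by \code{perc_similarity_parent}.
#' @param perc_similarity_parent Size-similarity for inherited-variant
#'   matching (default 0.9).
#' @param project Optional project identifier.
#' @return List with \code{mother_zygosity} and \code{father_zygosity}.
#' @export
parental_zygosity <- function(query, db, family, criteria = match_criteria(),
                              perc_similarity_parent = 0.9, project = NULL) {
  stopifnot(db$source == "INTERNAL")
  crit <- criteria
  crit$perc_similarity <- perc_similarity_parent
  one <- function(relation) {
    lab <- format_nanoid(list(project = project, family_id = family,
                              relation = relation))
    sub <- db$records[db$records$sample_label == lab, , drop = FALSE]
    if (!nrow(sub)) return("-")
    subdb <- new_db_variant_set("INTERNAL", sub, 1L)
    m <- find_matches(query, subdb, crit, size_absent_ok = TRUE)$matches
    if (!nrow(m)) return("-")
    z <- unique(normalize_zygosity(m$zygosity))
    z <- z[order(match(z, c("homozygous", "heterozygous", "unknown")))]
    paste(z, collapse = ",")
  }
  list(mother_zygosity = one(2L), father_zygosity = one(3L))
}
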
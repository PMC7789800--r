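# Population-frequency estimation.
#
# Public databases (DGV, DECIPHER) report no zygosity, so their frequency is
#   n matching variants / (2 * n samples) * 100.
# The optical-mapping control database (BNDB) and the internal cohort report
# zygosity, so matches are collapsed per carrier sample and counted as
# alleles: 2 for a homozygous (or unknown — a deliberate overestimate) match,
# 1 for a heterozygous one.

#' Zygosity-aware allele count over matched database records
#'
#' Matches are grouped by carrier sample; each distinct sample contributes
#' 2 alleles if any of its matches is homozygous or of unknown zygosity, and
#' 1 allele otherwise (multiple matches in one sample count as a single
#' variant/sample).
#'
#' @param sample_label Character vector of carrier sample labels, one per
#'   matched record.
#' @param zygosity Matching vector over \{homozygous, heterozygous, unknown\}.
#' @return Integer total allele count.
#' @examples
#' count_alleles(c("S1", "S2", "S3"), c("homozygous", "unknown", "heterozygous"))  # 5
#' @export
count_alleles <- function(sample_label, zygosity) {
  if (!length(sample_label)) return(0L)
  stopifnot(length(sample_label) == length(zygosity))
  z <- normalize_zygosity(zygosity)
  per <- tapply(z %in% c("homozygous", "unknown"), sample_label, any)
  sum(ifelse(per, 2L, 1L))
}

#' Frequency of a query SV in a public database (DGV / DECIPHER)
#'
#' Percent frequency is the number of matching database variants divided by
#' twice the number of samples (the allele count of a diploid cohort), times
#' 100. For DGV the count of unique matched samples is also reported (these
#' databases carry no zygosity, so no allele-level refinement applies).
#'
#' @param query One-row data.frame/list describing the query SV.
#' @param db A \code{db_variant_set} with source DGV or DECIPHER.
#' @param criteria A [match_criteria()].
#' @return List with \code{n_matches} (matched database entries),
#'   \code{n_unique_samples} and \code{freq_perc}.
#' @export
public_db_frequency <- function(query, db, criteria = match_criteria()) {
  if (is.null(db$n_samples) || db$n_samples <= 0) {
    stop("database has no positive sample count configured")
  }
  m <- find_matches(query, db, criteria, size_absent_ok = TRUE)$matches
  n <- if ("db_entry" %in% names(m)) length(unique(m$db_entry)) else nrow(m)
  list(n_matches = n,
       n_unique_samples = length(unique(m$sample_label)),
       freq_perc = n / (2 * db$n_samples) * 100)
}

# confidence gate by class; duplications carry no score and are exempt, and
# an absent score (the caller's -1 sentinel) is likewise exempt
confidence_pass <- function(cls, confidence, criteria) {
  thr <- rep(NA_real_, length(cls))
  thr[cls %in% c("insertion", "deletion")] <- criteria$conf_indel
  thr[cls == "inversion"] <- criteria$conf_inv
  thr[cls == "translocation"] <- criteria$conf_trans
  is.na(thr) | is.na(confidence) | confidence >= thr
}

#' Filtered and unfiltered control-database (BNDB) frequency
#'
#' Unfiltered: all records matching the breakpoint/size-similarity criteria,
#' allele-counted per carrier sample. Filtered: additionally each candidate
#' must carry a confidence score at or above its class threshold (indels
#' 0.5, inversions 0.01, translocations 0.1; duplications exempt) and a size
#' of at least \code{min_db_size_bp} (default 1 kb). Both are divided by
#' twice the number of database samples.
#'
#' @param query One-row data.frame/list describing the query SV.
#' @param db A \code{db_variant_set} (source BNDB).
#' @param criteria A [match_criteria()].
#' @return List with \code{freq_perc_filtered}, \code{freq_perc_unfiltered},
#'   \code{n_homozygotes} (homozygous candidates among filtered matches) and
#'   the allele counts \code{alleles_filtered}, \code{alleles_unfiltered}.
#' @export
bndb_frequency <- function(query, db, criteria = match_criteria()) {
  if (is.null(db$n_samples) || db$n_samples <= 0) {
    stop("database has no positive sample count configured")
  }
  m <- find_matches(query, db, criteria, size_absent_ok = TRUE)$matches
  denom <- 2 * db$n_samples
  # indel-class candidates need a usable size to enter the filtered set;
  # inversions/translocations often lack one and are size-gated only when a
  # size is present
  size_gate <- ifelse(m$sv_class %in% indel_classes,
                      !is.na(m$size_bp) & m$size_bp >= criteria$min_db_size_bp,
                      is.na(m$size_bp) | m$size_bp >= criteria$min_db_size_bp)
  filt <- m[confidence_pass(m$sv_class, m$confidence, criteria) & size_gate, ,
            drop = FALSE]
  a_un <- count_alleles(m$sample_label, m$zygosity)
  a_fi <- count_alleles(filt$sample_label, filt$zygosity)
  list(freq_perc_filtered = a_fi / denom * 100,
       freq_perc_unfiltered = a_un / denom * 100,
       n_homozygotes = sum(normalize_zygosity(filt$zygosity) == "homozygous"),
       alleles_filtered = a_fi, alleles_unfiltered = a_un)
}
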
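#' Normalize a chromosome label to its integer code
#'
#' Optical-mapping SV callers and the numeric-chromosome BED dialect encode
#' the human X and Y chromosomes as 23 and 24. This helper maps any common
#' chromosome token ("chr1", "1", "X", "chrY", "23") onto the 1-24 integer
#' code space used throughout the package.
#'
#' @param label Character vector of chromosome tokens. Case-insensitive; a
#'   leading "chr" prefix is stripped.
#' @return Integer vector: 1-22 for autosomes, 23 for X, 24 for Y.
#'   Unsupported contigs (mitochondrial, alt scaffolds, ...) raise an error
#'   of class \code{ogmsv_unsupported_contig} so that callers may catch it
#'   and skip the offending row with a warning.
#' @examples
#' normalize_chromosome(c("chrX", "1", "chr22", "y"))
#' @export
normalize_chromosome <- function(label) {
  lab <- sub("^chr", "", tolower(as.character(label)))
  code <- suppressWarnings(as.integer(lab))
  code[lab == "x"] <- 23L
  code[lab == "y"] <- 24L
  bad <- is.na(code) | code < 1L | code > 24L
  if (any(bad)) {
    stop(errorCondition(
      sprintf("unsupported contig: %s", paste(unique(label[bad]), collapse = ", ")),
      class = "ogmsv_unsupported_contig"
    ))
  }
  code
}

#' Parse a cohort sample identifier (nanoID)
#'
#' Internal-cohort samples are labelled \code{NR<family>.<relation>} with
#' relation 1 = proband, 2 = mother, 3 = father, optionally prefixed by an
#' underscore-delimited project identifier (e.g. \code{Project1_NR23.1}).
#' Only trio relation codes are accepted.
#'
#' @param text A single nanoID string.
#' @return A list of class \code{nano_id} with elements \code{project}
#'   (character or NA), \code{family_id} (integer), \code{relation}
#'   (integer 1-3) and \code{raw_label}.
#' @seealso [format_nanoid()]
#' @examples
#' parse_nanoid("NR23.2")
#' parse_nanoid("Project1_NR23.1")
#' @export
parse_nanoid <- function(text) {
  stopifnot(length(text) == 1L, is.character(text))
  m <- regmatches(text, regexec("^(?:(.+)_)?NR([0-9]+)\\.([0-9]+)$", text))[[1]]
  if (length(m) == 0L) {
    stop("malformed nanoID: '", text, "' (expected [project_]NR<family>.<relation>)")
  }
  relation <- as.integer(m[4])
  if (!relation %in% 1:3) {
    stop("nanoID relation code ", relation, " in '", text,
         "' is not supported: only trio codes 1 (proband), 2 (mother), 3 (father)")
  }
  family <- as.integer(m[3])
  if (is.na(family) || family < 1L) stop("malformed nanoID family in '", text, "'")
  structure(
    list(project = if (nzchar(m[2])) m[2] else NA_character_,
         family_id = family, relation = relation, raw_label = text),
    class = "nano_id"
  )
}

#' Serialize a sample identity back to its nanoID string
#'
#' @param id A \code{nano_id} as returned by [parse_nanoid()], or a list with
#'   \code{project}, \code{family_id}, \code{relation}.
#' @return The canonical string form \code{[project_]NR<family>.<relation>}.
#' @export
format_nanoid <- function(id) {
  base <- sprintf("NR%d.%d", as.integer(id$family_id), as.integer(id$relation))
  if (!is.null(id$project) && !is.na(id$project) && nzchar(id$project)) {
    base <- paste0(id$project, "_", base)
  }
  base
}

#' @export
print.nano_id <- function(x, ...) {
  rel <- c("proband", "mother", "father")[x$relation]
  cat(sprintf("<nano_id> %s (family %d, %s)\n", format_nanoid(x), x$family_id, rel))
  invisible(x)
}

#' Variant-matching criteria
#'
#' Bundles every threshold governing whether two SVs are considered the same
#' event: breakpoint windows, size-similarity fraction, the confidence
#' thresholds used for filtered database frequency, and the minimum database
#' variant size.
#'
#' @param win_indel Breakpoint window in bp for insertions, deletions and
#'   duplications (default 10000).
#' @param win_inv_trans Breakpoint window in bp for inversions and
#'   translocations (default 50000).
#' @param perc_similarity Minimum size-similarity fraction for indel-class
#'   matches (default 0.5; 0.9 is used for inherited-variant matching).
#' @param apply_size_to_inv_trans Apply the size-similarity rule to
#'   inversions/translocations too (default FALSE; caller sizes for these
#'   classes are often absent).
#' @param min_db_size_bp Minimum database-variant size in bp for the filtered
#'   frequency figure (default 1000).
#' @param conf_indel,conf_inv,conf_trans Confidence-score thresholds applied
#'   to database candidates in filtered frequency (defaults 0.5, 0.01, 0.1;
#'   duplications carry no confidence score and are exempt).
#' @return A list of class \code{match_criteria}.
#' @export
match_criteria <- function(win_indel = 10000, win_inv_trans = 50000,
                           perc_similarity = 0.5,
                           apply_size_to_inv_trans = FALSE,
                           min_db_size_bp = 1000,
                           conf_indel = 0.5, conf_inv = 0.01, conf_trans = 0.1) {
  stopifnot(win_indel >= 0, win_inv_trans >= 0,
            perc_similarity >= 0, perc_similarity <= 1,
            conf_indel >= 0, conf_indel <= 1,
            conf_inv >= 0, conf_inv <= 1,
            conf_trans >= 0, conf_trans <= 1)
  structure(
    list(win_indel = win_indel, win_inv_trans = win_inv_trans,
         perc_similarity = perc_similarity,
         apply_size_to_inv_trans = isTRUE(apply_size_to_inv_trans),
         min_db_size_bp = min_db_size_bp,
         conf_indel = conf_indel, conf_inv = conf_inv, conf_trans = conf_trans),
    class = "match_criteria"
  )
}

# Type vocabulary ------------------------------------------------------------

indel_classes <- c("insertion", "deletion", "duplication")

#' Collapse a source SV type string onto its coarse class
#'
#' Source dialects carry many subtype strings (duplication_split,
#' inversion_paired, translocation_interchr, "_nbase"-suffixed variants of
#' all of them, "trans_*_common" flags, "MisMatch"). External databases only
#' distinguish five classes, so matching operates on the collapsed class.
#'
#' @param sv_type Character vector of source type strings.
#' @return Character vector over \{insertion, deletion, duplication,
#'   inversion, translocation, mismatch, other\}.
#' @export
sv_class <- function(sv_type) {
  t <- tolower(sub("_nbase$", "", as.character(sv_type)))
  out <- rep("other", length(t))
  out[t == "insertion"] <- "insertion"
  out[t == "deletion"] <- "deletion"
  out[t %in% c("duplication", "duplication_split", "duplication_inverted")] <- "duplication"
  out[t %in% c("inversion", "inversion_paired", "inversion_partial", "inversion_repeat")] <- "inversion"
  out[grepl("^(translocation|trans)", t)] <- "translocation"
  out[t == "mismatch"] <- "mismatch"
  out
}

is_nbase_type <- function(sv_type) grepl("_nbase$", tolower(as.character(sv_type)))

normalize_zygosity <- function(z) {
  z <- tolower(trimws(as.character(z)))
  out <- rep("unknown", length(z))
  out[z %in% c("homozygous", "hom")] <- "homozygous"
  out[z %in% c("heterozygous", "het")] <- "heterozygous"
  out
}

# Truncate (not round) a percentage for display, matching the convention of
# printing 43/468*100 = 9.188... as 9.18.
trunc_pct <- function(x, digits = 2) {
  ifelse(is.na(x), NA_real_, floor(x * 10^digits + 1e-9) / 10^digits)
}
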
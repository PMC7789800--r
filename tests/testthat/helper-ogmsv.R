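# Shared helpers: in-code database construction, an independent brute-force
# matching oracle, and small random record generators.

make_db <- function(records, source = "BNDB", n_samples = 100L) {
  defaults <- list(sample_label = "S", chrom = 1L, chrom2 = NA, ref_start = 0,
                   ref_end = 0, sv_class = "deletion", size_bp = NA_real_,
                   zygosity = "unknown", confidence = NA_real_)
  for (nm in names(defaults)) {
    if (!nm %in% names(records)) records[[nm]] <- defaults[[nm]]
  }
  records$chrom2 <- ifelse(is.na(records$chrom2), records$chrom, records$chrom2)
  records$db_entry <- seq_len(nrow(records))
  ogmsv:::new_db_variant_set(source, records, as.integer(n_samples))
}

make_query <- function(chrom = 1L, start, end, class = "deletion",
                       size = end - start, chrom2 = chrom, id = "q1") {
  data.frame(call_id = id, chrom = chrom, chrom2 = chrom2, ref_start = start,
             ref_end = end, sv_class = class, size_bp = size,
             stringsAsFactors = FALSE)
}

# Independent O(n) oracle for the matching rule, written directly from its
# definition (same class; same chromosome(s); per-breakpoint windows; size
# similarity for indel classes).
brute_force_match_ids <- function(query, db, criteria,
                                  size_absent_ok = TRUE) {
  rec <- db$records
  hits <- integer(0)
  W <- if (query$sv_class %in% c("inversion", "translocation")) {
    criteria$win_inv_trans
  } else criteria$win_indel
  for (i in seq_len(nrow(rec))) {
    r <- rec[i, ]
    if (r$sv_class != query$sv_class) next
    if (r$chrom != query$chrom) next
    if (query$sv_class == "translocation" && r$chrom2 != query$chrom2) next
    if (abs(r$ref_start - query$ref_start) > W) next
    if (abs(r$ref_end - query$ref_end) > W) next
    need_size <- query$sv_class %in% c("insertion", "deletion", "duplication") ||
      (criteria$apply_size_to_inv_trans &&
         query$sv_class %in% c("inversion", "translocation"))
    if (need_size) {
      ok_sizes <- !is.na(r$size_bp) && r$size_bp > 0 &&
        !is.na(query$size_bp) && query$size_bp > 0
      if (ok_sizes) {
        if (min(r$size_bp, query$size_bp) / max(r$size_bp, query$size_bp) <
            criteria$perc_similarity) next
      } else if (!size_absent_ok) next
    }
    hits <- c(hits, r$db_entry)
  }
  sort(hits)
}

random_db_records <- function(n, n_chrom = 4, span = 2e6) {
  data.frame(
    sample_label = sprintf("S%d", sample.int(20, n, replace = TRUE)),
    chrom = sample.int(n_chrom, n, replace = TRUE),
    start_tmp = round(runif(n, 1e5, span)),
    stringsAsFactors = FALSE
  ) -> d
  size <- round(runif(n, 500, 3e5))
  d$ref_start <- d$start_tmp
  d$ref_end <- d$start_tmp + size
  d$start_tmp <- NULL
  d$sv_class <- sample(c("deletion", "insertion", "duplication", "inversion"),
                       n, replace = TRUE)
  d$size_bp <- ifelse(runif(n) < 0.1, NA, size)
  d$zygosity <- sample(c("homozygous", "heterozygous", "unknown"), n, TRUE)
  d$confidence <- round(runif(n), 2)
  d
}

write_lines_smap <- function(path, cols, rows) {
  writeLines(c("# test file", paste0("#h ", paste(cols, collapse = "\t")),
               vapply(rows, function(r) paste(r, collapse = "\t"), "")),
             path)
  path
}

# minimal single-enzyme SMAP content used across io tests
basic_smap_cols <- c("SmapEntryID", "RefcontigID1", "RefcontigID2",
                     "RefStartPos", "RefEndPos", "Type", "Size", "Confidence",
                     "Zygosity", "Found_in_self_molecules",
                     "Fail_assembly_chimeric_score", "OrigRow")
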
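# Variant-to-variant identity kernel.
#
# Two SVs are "the same" when they are of the same coarse class, on the same
# chromosome (both breakpoint chromosomes for translocations), their start
# and end breakpoints each fall within a class-specific window (10 kb for
# insertions/deletions/duplications, 50 kb for inversions/translocations by
# default — optical-mapping breakpoints carry ~3.3 kb uncertainty), and, for
# the indel classes, their sizes agree to at least the size-similarity
# fraction (default 50%).

#' Size similarity of two SVs
#'
#' The ratio of the smaller to the larger size: symmetric and bounded in
#' (0, 1], equal to 1 for identical sizes.
#'
#' @param size_a,size_b Sizes in bp; both must be positive.
#' @return Numeric fraction in (0, 1].
#' @examples
#' size_similarity(500, 1000)  # 0.5
#' @export
size_similarity <- function(size_a, size_b) {
  if (any(is.na(size_a)) || any(is.na(size_b)) ||
      any(size_a <= 0) || any(size_b <= 0)) {
    stop(errorCondition("size unavailable (absent or non-positive)",
                        class = "ogmsv_size_unavailable"))
  }
  pmin(size_a, size_b) / pmax(size_a, size_b)
}

match_window <- function(cls, criteria) {
  ifelse(cls %in% c("inversion", "translocation"),
         criteria$win_inv_trans, criteria$win_indel)
}

# Vectorized core: query (scalars) against candidate vectors. Returns a
# logical vector; size_absent_ok governs indel-class candidates with an
# unusable size (kept for unfiltered matching, dropped otherwise).
match_mask <- function(q_class, q_chrom, q_chrom2, q_start, q_end, q_size,
                       chrom, chrom2, start, end, size, cls, criteria,
                       size_absent_ok = TRUE) {
  ok <- cls == q_class & chrom == q_chrom
  if (q_class == "translocation") ok <- ok & chrom2 == q_chrom2
  W <- match_window(q_class, criteria)
  ok <- ok & abs(start - q_start) <= W & abs(end - q_end) <= W
  need_size <- q_class %in% indel_classes ||
    (criteria$apply_size_to_inv_trans && q_class %in% c("inversion", "translocation"))
  if (need_size) {
    usable <- !is.na(size) & size > 0 & rep(!is.na(q_size) && q_size > 0, length(size))
    sim <- rep(NA_real_, length(size))
    sim[usable] <- pmin(size[usable], q_size) / pmax(size[usable], q_size)
    pass_size <- ifelse(usable, sim >= criteria$perc_similarity, size_absent_ok)
    ok <- ok & pass_size
  }
  ok & !is.na(ok)
}

#' Does a database candidate match a query SV?
#'
#' @param query A one-row data.frame (or list) with \code{sv_class} (or
#'   \code{sv_type}), \code{chrom}, \code{chrom2}, \code{ref_start},
#'   \code{ref_end}, \code{size_bp}.
#' @param candidate Same fields for the database record.
#' @param criteria A [match_criteria()] object.
#' @param size_absent_ok Treat an unusable candidate/query size as passing
#'   the size rule (used for unfiltered matching; default TRUE).
#' @return Logical scalar.
#' @export
is_match <- function(query, candidate, criteria = match_criteria(),
                     size_absent_ok = TRUE) {
  qc <- if (!is.null(query$sv_class)) query$sv_class else sv_class(query$sv_type)
  cc <- if (!is.null(candidate$sv_class)) candidate$sv_class else sv_class(candidate$sv_type)
  q_chrom2 <- if (!is.null(query$chrom2)) query$chrom2 else query$chrom
  c_chrom2 <- if (!is.null(candidate$chrom2)) candidate$chrom2 else candidate$chrom
  match_mask(qc, query$chrom, q_chrom2, query$ref_start, query$ref_end,
             if (is.null(query$size_bp)) NA_real_ else query$size_bp,
             candidate$chrom, c_chrom2, candidate$ref_start, candidate$ref_end,
             if (is.null(candidate$size_bp)) NA_real_ else candidate$size_bp,
             cc, criteria, size_absent_ok = size_absent_ok)
}

db_index <- function(db) {
  # lazy (chrom, class) index, cached by reference; results are identical to
  # a full linear scan (tested against one)
  env <- db$index_env
  build <- function() split(seq_len(nrow(db$records)),
                            paste(db$records$chrom, db$records$sv_class))
  if (is.null(env)) return(build())
  if (is.null(env$idx)) env$idx <- build()
  env$idx
}

#' Retrieve all database records matching a query SV
#'
#' Candidate lookup is restricted to the query's (chromosome, class) stratum
#' of the database; the result is identical to applying [is_match()] in a
#' full linear scan.
#'
#' @param query One-row data.frame/list describing the query SV.
#' @param db A \code{db_variant_set}.
#' @param criteria A [match_criteria()].
#' @param size_absent_ok Passed to the size rule (see [is_match()]).
#' @return A \code{match_result}: list with \code{query_id} and
#'   \code{matches}, a data.frame of the matched records with appended
#'   \code{size_similarity}, \code{start_delta} and \code{end_delta}.
#' @export
find_matches <- function(query, db, criteria = match_criteria(),
                         size_absent_ok = TRUE) {
  rec <- db$records
  qc <- if (!is.null(query$sv_class)) query$sv_class else sv_class(query$sv_type)
  cand_i <- db_index(db)[[paste(query$chrom, qc)]]
  if (is.null(cand_i)) cand_i <- integer(0)
  cand <- rec[cand_i, , drop = FALSE]
  q_size <- if (is.null(query$size_bp)) NA_real_ else query$size_bp
  q_chrom2 <- if (!is.null(query$chrom2)) query$chrom2 else query$chrom
  ok <- match_mask(qc, query$chrom, q_chrom2, query$ref_start, query$ref_end,
                   q_size, cand$chrom, cand$chrom2, cand$ref_start,
                   cand$ref_end, cand$size_bp, cand$sv_class, criteria,
                   size_absent_ok = size_absent_ok)
  m <- cand[ok, , drop = FALSE]
  m <- m[!duplicated(m), , drop = FALSE]
  sim <- rep(NA_real_, nrow(m))
  if (nrow(m)) {
    usable <- !is.na(m$size_bp) & m$size_bp > 0 & rep(!is.na(q_size) && q_size > 0, nrow(m))
    sim[usable] <- pmin(m$size_bp[usable], q_size) / pmax(m$size_bp[usable], q_size)
  }
  m$size_similarity <- sim
  m$start_delta <- m$ref_start - query$ref_start
  m$end_delta <- m$ref_end - query$ref_end
  structure(list(query_id = if (!is.null(query$call_id)) query$call_id else NA,
                 matches = m),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> query=%s matches=%d\n",
              as.character(x$query_id), nrow(x$matches)))
  invisible(x)
}
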
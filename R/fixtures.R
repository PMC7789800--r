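# Deterministic synthetic-data generator.
#
# Emits a complete, self-consistent input bundle — per-sample SV files with
# a family key, a gene BED, DGV/DECIPHER tables, a per-type control-database
# directory, expression tables and a gene-list snapshot — together with a
# manifest of analytically derived expected annotations (frequencies,
# overlap percentages, nearest-gene distances, sheet assignments), so that
# every pipeline stage can be exercised without any external download.
# One seeded random stream drives all stochastic choices; equal seeds give
# byte-identical bundles.

#' Specification for a synthetic input bundle
#'
#' Defaults emulate the study conditions of a single-enzyme trio analysed
#' against an 8-sample internal cohort (3 of them the query family), a
#' 234-sample control database, and small DGV/DECIPHER tables. The default
#' planted-variant set covers every sheet of the report taxonomy, the
#' worked internal-frequency scenario (one heterozygous and one homozygous
#' non-family carrier, plus a duplicated caller record), a parentally
#' shifted but >90%-size-similar maternal record, and the quality-gate edge
#' cases (nbase, self-molecule failure, chimeric failure, likely-false
#' "common" translocation).
#'
#' @param seed Integer seed for the bundle's random stream.
#' @param n_cohort_samples Internal cohort size (default 8).
#' @param family_design "solo", "duo" or "trio" (default "trio").
#' @param dialect "single_enzyme" or "svmerge".
#' @param planted_variants data.frame; NULL for the default set (see
#'   \code{ogmsv:::default_planted}).
#' @param gene_layout data.frame(symbol, chrom, start, end, strand); NULL
#'   for the default layout.
#' @param n_background Random background variants per sample (default 5).
#' @param bndb_n_samples Control-database cohort size (default 234).
#' @param chrom_lengths Named numeric vector of toy chromosome lengths.
#' @return A \code{fixture_spec} list.
#' @export
fixture_spec <- function(seed = 1L, n_cohort_samples = 8L,
                         family_design = c("trio", "solo", "duo"),
                         dialect = c("single_enzyme", "svmerge"),
                         planted_variants = NULL, gene_layout = NULL,
                         n_background = 5L, bndb_n_samples = 234L,
                         chrom_lengths = stats::setNames(rep(5e6, 24), 1:24)) {
  family_design <- match.arg(family_design)
  dialect <- match.arg(dialect)
  n_family <- switch(family_design, solo = 1L, duo = 2L, trio = 3L)
  if (n_cohort_samples < n_family) {
    stop("cohort must contain at least the ", n_family, " family member(s)")
  }
  pv <- planted_variants %||% default_planted(family_design, dialect)
  gl <- gene_layout %||% default_gene_layout()
  # validate before anything is written
  for (i in seq_len(nrow(pv))) {
    v <- pv[i, ]
    if (!v$chrom %in% as.integer(names(chrom_lengths)) ||
        v$ref_end > chrom_lengths[[as.character(v$chrom)]]) {
      stop("planted variant '", v$name, "' exceeds the declared genome")
    }
    for (cz in parse_carriers(v$carriers)) {
      if (cz$idx <= n_family || cz$idx > n_cohort_samples) {
        stop("carrier index ", cz$idx, " of '", v$name,
             "' is not a non-family cohort sample")
      }
    }
  }
  structure(list(seed = as.integer(seed), n_cohort_samples = n_cohort_samples,
                 family_design = family_design, dialect = dialect,
                 n_family = n_family, planted_variants = pv, gene_layout = gl,
                 n_background = as.integer(n_background),
                 bndb_n_samples = as.integer(bndb_n_samples),
                 chrom_lengths = chrom_lengths),
            class = "fixture_spec")
}

parse_carriers <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list())
  lapply(strsplit(s, "|", fixed = TRUE)[[1]], function(p) {
    kv <- strsplit(p, ":", fixed = TRUE)[[1]]
    list(idx = as.integer(kv[1]), zygosity = kv[2])
  })
}

default_planted <- function(family_design, dialect) {
  pv <- data.frame(
    name = c("del_main", "del_denovo", "ins_both", "ins_father", "inv_inherited",
             "trans_common", "trans_real", "del_nbase", "del_noself",
             "dup_chimfail"),
    sv_type = c("deletion", "deletion", "insertion", "insertion", "inversion",
                "trans_interchr_common", "translocation_interchr",
                "deletion_nbase", "deletion", "duplication"),
    chrom = c(4L, 2L, 3L, 5L, 6L, 7L, 7L, 9L, 11L, 12L),
    chrom2 = c(4L, 2L, 3L, 5L, 6L, 8L, 8L, 9L, 11L, 12L),
    ref_start = c(500000, 1000000, 2000000, 1500000, 800000, 1000000,
                  1500000, 3000000, 1000000, 2000000),
    ref_end = c(650000, 1080000, 2000500, 1500400, 1200000, 2000000,
                2500000, 3050000, 1040000, 2200000),
    size_bp = c(150000, 80000, 1500, 1500, NA, NA, NA, 50000, 40000, 200000),
    zygosity = c("heterozygous", "heterozygous", "heterozygous", "heterozygous",
                 "heterozygous", "unknown", "unknown", "heterozygous",
                 "heterozygous", "heterozygous"),
    confidence = c(0.9, 0.8, 0.7, 0.7, 0.05, 0.2, 0.2, 0.9, 0.9, NA),
    found_in_self = c("yes", "yes", "yes", "yes", "yes", "yes", "yes", "yes",
                      "no", "yes"),
    chimeric_pass = c("pass", "pass", "pass", "pass", "pass", "pass", "pass",
                      "pass", "pass", "fail"),
    parental_support = c("mother", "none", "both", "father", "both", "none",
                         "none", "both", "both", "both"),
    carriers = c("4:heterozygous|5:homozygous", "", "", "", "", "", "", "",
                 "", ""),
    duplicate_carrier = c(4L, NA, NA, NA, NA, NA, NA, NA, NA, NA),
    extra_maternal_shifted = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                               FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  pv$expected_sheet <- planted_expected_sheet(pv, family_design)
  if (dialect == "svmerge") {
    pv <- rbind(pv, within(pv[1, ], {
      name <- "mismatch_1"; sv_type <- "MisMatch"; chrom <- 10L; chrom2 <- 10L
      ref_start <- 100000; ref_end <- 150000; size_bp <- 50000
      carriers <- ""; duplicate_carrier <- NA; extra_maternal_shifted <- FALSE
      parental_support <- "none"; expected_sheet <- "Mismatch"
    }))
  }
  pv
}

planted_expected_sheet <- function(pv, family_design) {
  cls <- sv_class(pv$sv_type)
  keep <- pv$found_in_self == "yes" &
    (!cls %in% c("duplication", "inversion", "translocation") |
       pv$chimeric_pass == "pass") & !is_nbase_type(pv$sv_type)
  sheet <- rep("all", nrow(pv))
  indel <- keep & cls %in% indel_classes
  if (family_design == "trio") {
    sheet[indel] <- paste0("indel_dup_",
                           c(none = "denovo", both = "both", mother = "mother",
                             father = "father")[pv$parental_support[indel]])
  } else if (family_design == "duo") {
    # generate_fixture derives control support: absent for "none"/"father"
    sheet[indel] <- ifelse(pv$parental_support[indel] %in% c("none", "father"),
                           "indel_dup_notShared", "indel_dup_Shared")
  } else sheet[indel] <- "indel_dup"
  sheet[keep & cls == "inversion"] <- "inv"
  sheet[keep & tolower(pv$sv_type) %in%
          c("translocation_intrachr", "translocation_interchr")] <- "trans"
  sheet
}

default_gene_layout <- function() {
  data.frame(
    symbol = c("GENEA", "GENEB", "UPG1", "UPG2", "UPG3", "UPG4",
               "DNG1", "DNG2", "DNG3", "GENEC"),
    chrom = c(4L, 4L, 4L, 4L, 4L, 4L, 4L, 4L, 4L, 2L),
    start = c(520000, 643701, 460000, 430000, 400000, 300000,
              660000, 670000, 700000, 1020000),
    end = c(550000, 653700, 490000, 480000, 470000, 450000,
            700000, 720000, 750000, 1050000),
    strand = c("+", "-", "+", "-", "+", "+", "+", "-", "+", "+"),
    stringsAsFactors = FALSE
  )
}

write_fixture_sv <- function(df, path, dialect, design) {
  out <- data.frame(SmapEntryID = df$call_id,
                    RefcontigID1 = df$chrom, RefcontigID2 = df$chrom2,
                    RefStartPos = format(df$ref_start, scientific = FALSE, trim = TRUE),
                    RefEndPos = format(df$ref_end, scientific = FALSE, trim = TRUE),
                    Type = df$sv_type,
                    Size = ifelse(is.na(df$size_bp), -1,
                                  format(df$size_bp, scientific = FALSE, trim = TRUE)),
                    Confidence = ifelse(is.na(df$confidence), -1, df$confidence),
                    Zygosity = df$zygosity, stringsAsFactors = FALSE)
  if (dialect == "svmerge") {
    # split self-molecule support across the enzymes to exercise the
    # disjunctive harmonization
    alt <- seq_len(nrow(df)) %% 2 == 0
    out$Found_in_self_BSPQI_molecules <- ifelse(df$found_in_self == "yes",
                                                ifelse(alt, "no", "yes"), "no")
    out$Found_in_self_BSSSI_molecule <- ifelse(df$found_in_self == "yes",
                                               ifelse(alt, "yes", "no"), "no")
    out$Fail_BSPQI_assembly_chimeric_score <- df$chimeric_pass
    out$Fail_BSSSI_assembly_chimeric_score <- df$chimeric_pass
    if (design == "trio") {
      ps <- ifelse(df$parental_support == "none", "-", df$parental_support)
      out$Found_in_parents_BSPQI_molecules <- ps
      out$Found_in_parents_BSSSI_molecules <- ps
    }
    if (design == "duo") {
      out$Found_in_control_BSPQI_molecules <- df$control_support
      out$Found_in_control_BSSSI_molecules <- df$control_support
    }
  } else {
    out$Found_in_self_molecules <- df$found_in_self
    out$Fail_assembly_chimeric_score <- df$chimeric_pass
    if (design == "trio") out$Found_in_parents_molecules <- df$parental_support
    if (design == "duo") out$Found_in_control_molecules <- df$control_support
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# synthetic optical-mapping SV calls",
               paste0("#h ", paste(names(out), collapse = "\t"))), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

background_calls <- function(spec, sample_idx) {
  n <- spec$n_background
  if (n == 0) return(NULL)
  types <- sample(c("insertion", "deletion"), n, replace = TRUE)
  chrom <- 13L + (seq_len(n) - 1L) %% 4L
  start <- 1e5 + (sample_idx - 1) * 2e5 + (seq_len(n) - 1) * 3e4 +
    round(stats::runif(n, 0, 5000))
  size <- round(stats::runif(n, 5000, 20000))
  data.frame(call_id = sprintf("bg%d_%d", sample_idx, seq_len(n)),
             chrom = chrom, chrom2 = chrom,
             ref_start = start, ref_end = start + size, size_bp = size,
             sv_type = types,
             zygosity = sample(c("heterozygous", "homozygous"), n, replace = TRUE),
             confidence = round(stats::runif(n, 0.6, 1), 2),
             found_in_self = "yes", chimeric_pass = "pass",
             parental_support = "both", control_support = "yes",
             stringsAsFactors = FALSE)
}

#' Generate a synthetic input bundle with known ground truth
#'
#' Writes every file the pipeline consumes and a manifest of expected
#' annotations. See [fixture_spec()] for what the bundle emulates.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory (created).
#' @return List with the generated \code{paths} (named), the
#'   \code{manifest} data.frame (also written as \code{manifest.tsv}), and
#'   \code{expected} scalars (sheet count, total call count, primary-gene
#'   rows).
#' @export
generate_fixture <- function(spec, outdir) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "cohort"), showWarnings = FALSE)
  dir.create(file.path(outdir, "bndb"), showWarnings = FALSE)
  pv <- spec$planted_variants
  design <- spec$family_design
  n_fam <- spec$n_family
  N <- spec$n_cohort_samples

  pv$control_support <- ifelse(pv$parental_support %in% c("none", "father"),
                               "no", "yes")

  planted_rows <- data.frame(call_id = sprintf("pv_%s", pv$name), chrom = pv$chrom,
                             chrom2 = pv$chrom2, ref_start = pv$ref_start,
                             ref_end = pv$ref_end, size_bp = pv$size_bp,
                             sv_type = pv$sv_type, zygosity = pv$zygosity,
                             confidence = pv$confidence,
                             found_in_self = pv$found_in_self,
                             chimeric_pass = pv$chimeric_pass,
                             parental_support = pv$parental_support,
                             control_support = pv$control_support,
                             stringsAsFactors = FALSE)

  # --- cohort files -----------------------------------------------------
  key <- data.frame(sample = sprintf("S%02d", seq_len(N)),
                    family_id = ifelse(seq_len(N) <= n_fam, 1L,
                                       seq_len(N) - n_fam + 1L),
                    relation = ifelse(seq_len(N) <= n_fam, seq_len(N), 1L),
                    stringsAsFactors = FALSE)
  cohort_paths <- character(N)
  sample1_rows <- NULL
  col_order <- names(planted_rows)
  bind2 <- function(a, b) {
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    rbind(a[, col_order, drop = FALSE], b[, col_order, drop = FALSE])
  }
  for (i in seq_len(N)) {
    rows <- background_calls(spec, i)
    if (i == 1L) rows <- bind2(planted_rows, rows)
    if (i == 2L && design %in% c("duo", "trio")) {
      # parent/control records: identical breakpoints, heterozygous
      mi <- pv$parental_support %in% c("mother", "both") |
        (design == "duo" & pv$control_support == "yes")
      if (any(mi)) {
        mrow <- planted_rows[mi, , drop = FALSE]
        mrow$zygosity <- "heterozygous"
        mrow$call_id <- paste0("m_", mrow$call_id)
        sh <- pv$extra_maternal_shifted
        if (any(sh & mi)) {
          ex <- planted_rows[sh & mi, , drop = FALSE]
          ex$ref_start <- ex$ref_start + 5000
          ex$size_bp <- ex$size_bp - 5000
          ex$zygosity <- "heterozygous"
          ex$call_id <- paste0("mshift_", ex$call_id)
          mrow <- rbind(mrow, ex)
        }
        rows <- bind2(mrow, rows)
      }
    }
    if (i == 3L && design == "trio") {
      fi <- pv$parental_support %in% c("father", "both")
      if (any(fi)) {
        frow <- planted_rows[fi, , drop = FALSE]
        frow$zygosity <- "heterozygous"
        frow$call_id <- paste0("f_", frow$call_id)
        rows <- bind2(frow, rows)
      }
    }
    if (i > n_fam) {
      for (k in seq_len(nrow(pv))) {
        for (cz in parse_carriers(pv$carriers[k])) {
          if (cz$idx != i) next
          crow <- planted_rows[k, , drop = FALSE]
          crow$zygosity <- cz$zygosity
          crow$call_id <- paste0("c", i, "_", crow$call_id)
          rows <- bind2(rows, crow)
          if (!is.na(pv$duplicate_carrier[k]) && pv$duplicate_carrier[k] == i) {
            dup <- crow
            dup$call_id <- paste0(crow$call_id, "_dup")  # caller double call
            rows <- bind2(rows, dup)
          }
        }
      }
    }
    p <- file.path(outdir, "cohort", sprintf("S%02d.smap", i))
    write_fixture_sv(rows, p, "single_enzyme", "solo")
    cohort_paths[i] <- p
    if (i == 1L) sample1_rows <- rows
  }

  # --- query (proband) file with design-specific support columns --------
  query_path <- file.path(outdir, sprintf("proband_%s.%s", design,
                                          if (spec$dialect == "svmerge") "txt" else "smap"))
  write_fixture_sv(sample1_rows, query_path, spec$dialect, design)

  # --- gene BED (standard 0-based) --------------------------------------
  gl <- spec$gene_layout
  bed_path <- file.path(outdir, "genes.bed")
  utils::write.table(
    data.frame(paste0("chr", ifelse(gl$chrom == 23, "X",
                                    ifelse(gl$chrom == 24, "Y", gl$chrom))),
               format(gl$start - 1, scientific = FALSE, trim = TRUE),
               format(gl$end, scientific = FALSE, trim = TRUE),
               gl$symbol, 0, gl$strand),
    bed_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  # --- external databases ----------------------------------------------
  main <- pv[pv$name == "del_main", ]
  has_main <- nrow(main) == 1L
  dgv_path <- file.path(outdir, "dgv.txt")
  dgv <- data.frame(
    chr = c(if (has_main) rep(main$chrom, 3), 1, 1),
    start = c(if (has_main) main$ref_start + c(500, -1000, -2000), 100000, 300000),
    end = c(if (has_main) main$ref_end + c(-500, 1000, -2000), 150000, 350000),
    variantsubtype = c(if (has_main) rep("loss", 3), "gain", "inversion"),
    samples = c(if (has_main) c("DGVS1", "DGVS1", "DGVS2"), "DGVS3", "DGVS4"),
    samplesize = 100, stringsAsFactors = FALSE)
  utils::write.table(dgv, dgv_path, sep = "\t", quote = FALSE, row.names = FALSE)

  decipher_path <- file.path(outdir, "decipher.txt")
  dec <- data.frame(
    chr = c(if (has_main) main$chrom, rep(1, 9)),
    start = c(if (has_main) main$ref_start + 1000, 100000 + (1:9) * 50000),
    end = c(if (has_main) main$ref_end - 1000, 130000 + (1:9) * 50000),
    type = c(if (has_main) "deletion", rep(c("duplication", "deletion"), length.out = 9)),
    sample_id = paste0("DEC_S", seq_len(9 + has_main)),
    stringsAsFactors = FALSE)
  utils::write.table(dec, decipher_path, sep = "\t", quote = FALSE, row.names = FALSE)

  # BNDB: matches for del_main (2 hom + 2 het + 1 unknown + 1 low-confidence
  # het), an 800 bp candidate matching ins_both (similarity passes, 1 kb size
  # gate fails), and an inversion candidate matching inv_inherited
  bndb_dir <- file.path(outdir, "bndb")
  ins <- pv[pv$name == "ins_both", ]
  indel_tab <- data.frame(
    Sample = paste0("BN_S", 1:7),
    RefcontigID1 = c(rep(if (has_main) main$chrom else 1L, 6),
                     if (nrow(ins)) ins$chrom else 1L),
    RefStartPos = c(if (has_main) main$ref_start + c(0, 200, -300, 400, 500, 100)
                    else 1:6 * 1000,
                    if (nrow(ins)) ins$ref_start + 50 else 99000),
    RefEndPos = c(if (has_main) main$ref_end + c(0, -200, 300, -400, 500, -100)
                  else 1:6 * 1000 + 500,
                  if (nrow(ins)) ins$ref_start + 850 else 99500),
    Type = c(rep("deletion", 6), "insertion"),
    Size = c(rep(if (has_main) main$size_bp else 1500, 6), 800),
    Confidence = c(0.9, 0.8, 0.95, 0.7, 0.9, 0.4, 0.9),
    Zygosity = c("homozygous", "homozygous", "heterozygous", "heterozygous",
                 "unknown", "heterozygous", "heterozygous"),
    stringsAsFactors = FALSE)
  utils::write.table(indel_tab, file.path(bndb_dir, "bndb_hg19_indel.txt"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  inv <- pv[pv$name == "inv_inherited", ]
  inv_tab <- data.frame(
    Sample = "BN_S8",
    RefcontigID1 = if (nrow(inv)) inv$chrom else 6L,
    RefStartPos = if (nrow(inv)) inv$ref_start + 5000 else 800000,
    RefEndPos = if (nrow(inv)) inv$ref_end - 5000 else 1200000,
    Type = "inversion", Size = -1, Confidence = 0.02,
    Zygosity = "heterozygous", stringsAsFactors = FALSE)
  utils::write.table(inv_tab, file.path(bndb_dir, "bndb_hg19_inversion.txt"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(Sample = "BN_S9", RefcontigID1 = 20L, RefStartPos = 100000,
               RefEndPos = 300000, Type = "duplication", Size = 200000,
               Confidence = -1, Zygosity = "heterozygous"),
    file.path(bndb_dir, "bndb_hg19_dup.txt"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(Sample = "BN_S10", RefcontigID1 = 21L, RefcontigID2 = 22L,
               RefStartPos = 100000, RefEndPos = 300000,
               Type = "translocation_interchr", Size = -1, Confidence = 0.3,
               Zygosity = "unknown"),
    file.path(bndb_dir, "bndb_hg19_translocation.txt"), sep = "\t",
    quote = FALSE, row.names = FALSE)

  # --- expression + gene list ------------------------------------------
  expr_genes <- c("GENEA", "GENEB", "GENEC", "UPG1", "DNG1")
  expr_paths <- character(0)
  roles <- switch(design, solo = c(P = "proband"),
                  duo = c(P = "proband", AM = "mother"),
                  trio = c(P = "proband", AM = "mother", UF = "father"))
  for (code in names(roles)) {
    p <- file.path(outdir, sprintf("Sample1_%s_expression.txt", code))
    g <- expr_genes
    val <- switch(code, P = c(10, 3.5, 0.2, 7, 1.25),
                  AM = c(12.5, 2, 0.1, 6, 2), UF = c(NA, 4, 0.3, 5, 1))
    keep <- !is.na(val)
    utils::write.table(data.frame(gene = g[keep], TPM = val[keep]), p,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    expr_paths <- c(expr_paths, p)
  }
  snap_dir <- file.path(outdir, "snapshots")
  dir.create(snap_dir, showWarnings = FALSE)
  utils::write.table(
    data.frame(gene = c("GENEA", "OTHER1"), condition = c("Osteoporosis", "deafness")),
    file.path(snap_dir, "omim.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = c("GENEC", "OTHER2", "GENEC"),
               condition = c("osteoporosis, adult", "cardiomyopathy", "osteoporosis"),
               clinical_significance = c("Pathogenic", "Benign", "Likely pathogenic")),
    file.path(snap_dir, "clinvar.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = "UPG1", condition = "Osteoporosis panel"),
    file.path(snap_dir, "gene.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  # --- internal database (persisted form) ------------------------------
  db <- build_internal_db(cohort_paths, key)
  internal_path <- file.path(outdir, "internal_db.tsv")
  write_internal_db(db, internal_path)
  utils::write.csv(key, file.path(outdir, "key.csv"), row.names = FALSE)

  manifest <- fixture_manifest(spec, pv)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  list(
    dir = outdir,
    paths = list(query = query_path, cohort = cohort_paths, key = file.path(outdir, "key.csv"),
                 internal_db = internal_path, bed = bed_path, dgv = dgv_path,
                 decipher = decipher_path, bndb_dir = bndb_dir,
                 expression = expr_paths,
                 snapshots = list(OMIM = file.path(snap_dir, "omim.tsv"),
                                  ClinVar = file.path(snap_dir, "clinvar.tsv"),
                                  Gene = file.path(snap_dir, "gene.tsv"))),
    manifest = manifest,
    expected = list(
      n_sheets = length(sheet_plan(design, spec$dialect)),
      n_calls = nrow(pv) + spec$n_background,
      internal_denominator = 2 * (N - n_fam))
  )
}

# Analytic expectations per planted variant, straight from the frequency
# formulas and the gene geometry; no pipeline code paths are exercised here
# beyond trivial arithmetic.
fixture_manifest <- function(spec, pv) {
  N <- spec$n_cohort_samples; n_fam <- spec$n_family
  denom_int <- 2 * (N - n_fam)
  gl <- spec$gene_layout
  man <- data.frame(name = pv$name, expected_sheet = pv$expected_sheet,
                    stringsAsFactors = FALSE)
  man$internal_alleles <- vapply(pv$carriers, function(s) {
    cz <- parse_carriers(s)
    if (!length(cz)) return(0)
    sum(vapply(cz, function(x)
      if (x$zygosity %in% c("homozygous", "unknown")) 2 else 1, 0))
  }, 0, USE.NAMES = FALSE)
  man$internal_freq_perc <- man$internal_alleles / denom_int * 100
  main_i <- pv$name == "del_main"
  ins_i <- pv$name == "ins_both"
  inv_i <- pv$name == "inv_inherited"
  denom_bn <- 2 * spec$bndb_n_samples
  man$bndb_alleles_filtered <- rep(0, nrow(man))
  man$bndb_alleles_unfiltered <- rep(0, nrow(man))
  man$bndb_homozygotes <- rep(0, nrow(man))
  # del_main: 2 hom + 2 het + 1 unknown pass filters; low-confidence het only
  # unfiltered
  man$bndb_alleles_filtered[main_i] <- 2 * 2 + 2 * 1 + 2
  man$bndb_alleles_unfiltered[main_i] <- man$bndb_alleles_filtered[main_i] + 1
  man$bndb_homozygotes[main_i] <- 2
  man$bndb_alleles_unfiltered[ins_i] <- 1   # 800 bp candidate fails size gate
  man$bndb_alleles_filtered[inv_i] <- 1     # sizeless inversion, conf 0.02
  man$bndb_alleles_unfiltered[inv_i] <- 1
  man$bndb_freq_perc_filtered <- man$bndb_alleles_filtered / denom_bn * 100
  man$bndb_freq_perc_unfiltered <- man$bndb_alleles_unfiltered / denom_bn * 100
  man$dgv_count <- ifelse(main_i, 2, 0)
  man$dgv_freq_perc <- ifelse(main_i, 3 / (2 * 100) * 100, 0)
  man$decipher_freq_perc <- ifelse(main_i, 1 / (2 * 10) * 100, 0)
  man$mother_zygosity <- ifelse(pv$parental_support %in% c("mother", "both") &
                                  spec$family_design == "trio",
                                "heterozygous", "-")
  man$father_zygosity <- ifelse(pv$parental_support %in% c("father", "both") &
                                  spec$family_design == "trio",
                                "heterozygous", "-")
  ov_expect <- function(i) {
    v <- pv[i, ]
    cls <- sv_class(v$sv_type)
    if (cls == "translocation") return("")
    W <- if (cls == "inversion") 10000 else 3000
    g <- gl[gl$chrom == v$chrom & gl$start <= v$ref_end + W &
              gl$end >= v$ref_start - W, , drop = FALSE]
    if (!nrow(g)) return("")
    pct <- pmax(pmin(overlap_len(v$ref_start, v$ref_end, g$start, g$end) /
                       (g$end - g$start + 1) * 100, 100), 0.01)
    paste(sprintf("%s:%g", g$symbol, round(pct, 2)), collapse = ";")
  }
  man$overlap_genes <- vapply(seq_len(nrow(pv)), ov_expect, "")
  up_dn <- function(i, upstream) {
    v <- pv[i, ]
    if (sv_class(v$sv_type) == "translocation") return("")
    ex <- strsplit(man$overlap_genes[i], ";")[[1]]
    ex <- sub(":.*", "", ex)
    g <- gl[gl$chrom == v$chrom & !gl$symbol %in% ex, , drop = FALSE]
    if (upstream) {
      g <- g[g$end < v$ref_start, , drop = FALSE]
      d <- (v$ref_start - g$end) / 1000
    } else {
      g <- g[g$start > v$ref_end, , drop = FALSE]
      d <- (g$start - v$ref_end) / 1000
    }
    o <- order(d, g$start, g$symbol)
    g <- g[o, , drop = FALSE]; d <- d[o]
    n <- min(3, nrow(g))
    if (!n) return("")
    paste(sprintf("%s:%g", g$symbol[seq_len(n)], d[seq_len(n)]), collapse = ";")
  }
  man$upstream_genes <- vapply(seq_len(nrow(pv)), up_dn, "", upstream = TRUE)
  man$downstream_genes <- vapply(seq_len(nrow(pv)), up_dn, "", upstream = FALSE)
  man
}
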
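test_that("equal seeds produce byte-identical bundles", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_fixture(fixture_spec(seed = 4), d1)
  generate_fixture(fixture_spec(seed = 4), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  d3 <- withr::local_tempdir()
  generate_fixture(fixture_spec(seed = 5), d3)
  smap1 <- readLines(file.path(d1, "cohort", "S04.smap"))
  smap3 <- readLines(file.path(d3, "cohort", "S04.smap"))
  expect_false(identical(smap1, smap3))
})

test_that("inconsistent specs fail before any file is written", {
  pv <- ogmsv:::default_planted("trio", "single_enzyme")
  pv$ref_end[1] <- 9e9
  expect_error(fixture_spec(planted_variants = pv), "exceeds the declared genome")
  pv2 <- ogmsv:::default_planted("trio", "single_enzyme")
  pv2$carriers[1] <- "2:heterozygous"  # sample 2 is the mother, not cohort
  expect_error(fixture_spec(planted_variants = pv2), "non-family")
})

test_that("an empty planted set still yields a valid bundle", {
  pv <- ogmsv:::default_planted("trio", "single_enzyme")[0, ]
  fx <- generate_fixture(fixture_spec(planted_variants = pv, n_background = 2),
                         withr::local_tempdir())
  expect_equal(nrow(fx$manifest), 0)
  cs <- read_sv_file(fx$paths$query)
  expect_equal(nrow(cs$calls), 2)
})

test_that("the manifest's worked internal-frequency scenario is encoded", {
  fx <- generate_fixture(fixture_spec(seed = 2), withr::local_tempdir())
  m <- fx$manifest
  expect_equal(fx$expected$internal_denominator, 10)  # 2 x (8 - 3)
  expect_equal(m$internal_alleles[m$name == "del_main"], 3)  # het + hom
  expect_equal(m$internal_freq_perc[m$name == "del_main"], 30)
})

test_that("the pipeline reproduces every manifest expectation end to end", {
  fx <- generate_fixture(fixture_spec(seed = 6), withr::local_tempdir())
  rep <- run_pipeline(list(
    sv_file = fx$paths$query, design = "trio", family_id = 1,
    bed = fx$paths$bed, dgv = fx$paths$dgv, decipher = fx$paths$decipher,
    bndb_dir = fx$paths$bndb_dir, internal_db = fx$paths$internal_db,
    expression_files = fx$paths$expression,
    terms = "osteoporosis", snapshots = fx$paths$snapshots,
    out = NA), quiet = TRUE)
  a <- rep$sheets$all
  denom_int <- fx$expected$internal_denominator
  denom_bn <- 2 * 234
  for (i in seq_len(nrow(fx$manifest))) {
    m <- fx$manifest[i, ]
    row <- a[a$call_id == paste0("pv_", m$name), ]
    expect_equal(nrow(row), 1, info = m$name)
    # sheet assignment
    in_sheet <- vapply(rep$sheet_names, function(sh)
      row$call_id %in% rep$sheets[[sh]]$call_id, TRUE)
    expect_true(in_sheet[[m$expected_sheet]], info = m$name)
    cat_sheets <- setdiff(rep$sheet_names,
                          c("all", "all_PG_OV", "indel_dup_cmpdHET",
                            m$expected_sheet))
    expect_false(any(in_sheet[cat_sheets]), info = m$name)
    # frequencies as displayed (truncated to 2 decimals)
    tr <- function(x) formatC(floor(x * 100 + 1e-9) / 100, format = "f",
                              digits = 2)
    expect_equal(row$Internal_Freq_Perc_Unfiltered,
                 tr(m$internal_freq_perc), info = m$name)
    expect_equal(row$BNG_Freq_Perc_Filtered,
                 tr(m$bndb_alleles_filtered / denom_bn * 100), info = m$name)
    expect_equal(row$BNG_Freq_Perc_UnFiltered,
                 tr(m$bndb_alleles_unfiltered / denom_bn * 100), info = m$name)
    expect_equal(row$BNG_Homozygotes, m$bndb_homozygotes, info = m$name)
    expect_equal(row$DGV_Count, m$dgv_count, info = m$name)
    expect_equal(row$DGV_Freq_Perc, tr(m$dgv_freq_perc), info = m$name)
    expect_equal(row$DECIPHER_Freq_Perc, tr(m$decipher_freq_perc),
                 info = m$name)
    expect_equal(row$MotherZygosity, m$mother_zygosity, info = m$name)
    expect_equal(row$FatherZygosity, m$father_zygosity, info = m$name)
    # gene annotation: symbols, overlap percentages (2 decimals) and
    # nearest distances from the manifest's analytic geometry
    if (nzchar(m$overlap_genes)) {
      exp_pairs <- strsplit(strsplit(m$overlap_genes, ";")[[1]], ":")
      got <- row$OverlapGenes_strand_perc
      for (pair in exp_pairs) {
        expect_match(got, pair[1], fixed = TRUE)
        got_pct <- as.numeric(sub(".*:", "", sub("\\)", "",
          regmatches(got, regexpr(paste0(pair[1], "\\([+-]:[0-9.]+\\)"),
                                  got)))))
        expect_equal(got_pct, as.numeric(pair[2]), tolerance = 0.011,
                     info = paste(m$name, pair[1]))
      }
    }
    if (nzchar(m$upstream_genes)) {
      exp_pairs <- strsplit(strsplit(m$upstream_genes, ";")[[1]], ":")
      expect_equal(sub("\\(.*", "",
                       strsplit(row$Upstream_nonOverlapGenes_dist_kb, ";")[[1]]),
                   vapply(exp_pairs, `[`, "", 1), info = m$name)
      got_d <- as.numeric(sub(".*:", "", sub("\\)", "",
        strsplit(row$Upstream_nonOverlapGenes_dist_kb, ";")[[1]])))
      expect_equal(got_d, as.numeric(vapply(exp_pairs, `[`, "", 2)),
                   info = m$name)
    }
  }
})

test_that("solo and svmerge bundles run through their pipeline modes", {
  fx <- generate_fixture(fixture_spec(seed = 8, family_design = "solo",
                                      n_background = 2),
                         withr::local_tempdir())
  rep <- run_pipeline(list(sv_file = fx$paths$query, design = "solo",
                           internal_db = fx$paths$internal_db, out = NA),
                      quiet = TRUE)
  expect_equal(rep$sheet_names, sheet_plan("solo", "single_enzyme"))
  expect_true("pv_del_main" %in% rep$sheets$indel_dup$call_id)

  fx2 <- generate_fixture(fixture_spec(seed = 9, dialect = "svmerge",
                                       n_background = 2),
                          withr::local_tempdir())
  rep2 <- run_pipeline(list(sv_file = fx2$paths$query, design = "trio",
                            family_id = 1, out = NA), quiet = TRUE)
  expect_equal(rep2$sheet_names, sheet_plan("trio", "svmerge"))
  expect_true("pv_mismatch_1" %in% rep2$sheets$Mismatch$call_id)
  expect_false("pv_mismatch_1" %in% rep2$sheets$indel_dup_both$call_id)
})
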
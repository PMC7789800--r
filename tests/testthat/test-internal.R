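# Builds a small cohort database entirely in code via build_internal_db on
# temporary SMAP files.

cohort_smap <- function(dir, name, rows) {
  cols <- basic_smap_cols[1:11]  # no extras
  p <- file.path(dir, paste0(name, ".smap"))
  write_lines_smap(p, cols, rows)
  p
}

del_row <- function(id, start = 500000, end = 650000, zyg = "heterozygous",
                    type = "deletion", self = "yes", chim = "pass",
                    size = end - start, conf = "0.9") {
  c(id, "4", "4", format(start, scientific = FALSE),
    format(end, scientific = FALSE), type,
    format(size, scientific = FALSE), conf, zyg, self, chim)
}

# Cohort of 8: samples 1-3 one family (proband/mother/father), 5 singletons.
# The family's deletion also sits in two unrelated samples (one het, one hom),
# one of them with a duplicated caller record.
worked_cohort <- function(dir) {
  files <- c(
    cohort_smap(dir, "S1", list(del_row("p1"))),
    cohort_smap(dir, "S2", list(del_row("m1"),
                                del_row("m2", start = 505000, size = 145000))),
    cohort_smap(dir, "S3", list()),
    cohort_smap(dir, "S4", list(del_row("c1"), del_row("c1dup"))),
    cohort_smap(dir, "S5", list(del_row("c2", zyg = "homozygous"))),
    cohort_smap(dir, "S6", list()),
    cohort_smap(dir, "S7", list()),
    cohort_smap(dir, "S8", list()))
  key <- data.frame(sample = paste0("S", 1:8),
                    family_id = c(1, 1, 1, 2:6),
                    relation = c(1, 2, 3, rep(1, 5)))
  build_internal_db(files, key)
}

test_that("the internal database tags records with nanoIDs", {
  db <- worked_cohort(withr::local_tempdir())
  expect_equal(db$source, "INTERNAL")
  expect_equal(db$n_samples, 8)
  expect_setequal(unique(db$records$sample_label),
                  c("NR1.1", "NR1.2", "NR2.1", "NR3.1"))
  dir2 <- withr::local_tempdir()
  p <- file.path(dir2, "db.tsv")
  write_internal_db(db, p)
  db2 <- read_internal_db(p)
  expect_equal(db2$records$sample_label, db$records$sample_label)
  expect_equal(db2$records$ref_start, db$records$ref_start)
  expect_equal(db2$n_samples, 8)
})

test_that("key and relation errors are caught when building the cohort", {
  dir <- withr::local_tempdir()
  f <- cohort_smap(dir, "S1", list(del_row("a")))
  expect_error(build_internal_db(list(), data.frame()), "no input files")
  expect_error(
    build_internal_db(f, data.frame(sample = "OTHER", family_id = 1, relation = 1)),
    "no row in the key")
  expect_error(
    build_internal_db(f, data.frame(sample = "S1", family_id = 1, relation = 4)),
    "not supported")
  f2 <- cohort_smap(dir, "S2", list(del_row("b")))
  expect_error(
    build_internal_db(c(f, f2),
                      data.frame(sample = c("S1", "S2"), family_id = 1,
                                 relation = 1)),
    "duplicate")
})

test_that("family-excluded internal frequency reproduces the worked 30%", {
  db <- worked_cohort(withr::local_tempdir())
  q <- make_query(4L, 500000, 650000, "deletion", size = 150000)
  r <- internal_frequency(q, db, query_family = 1)
  # 8-sample cohort minus 3 family members -> denominator 10; non-family
  # carriers one het (duplicate record collapsed) + one hom -> 3 alleles
  expect_equal(r$denominator, 10)
  expect_equal(r$alleles_unfiltered, 3)
  expect_equal(r$freq_perc_unfiltered, 30)
  expect_equal(r$freq_perc_filtered, 30)  # all records pass the quality gates
  expect_equal(r$n_homozygotes, 1)
})

test_that("adding more records for the query family never changes frequency", {
  dir <- withr::local_tempdir()
  db <- worked_cohort(dir)
  q <- make_query(4L, 500000, 650000, "deletion", size = 150000)
  base <- internal_frequency(q, db, query_family = 1)
  extra <- db$records[db$records$sample_label == "NR1.1", , drop = FALSE][
    rep(1, 5), , drop = FALSE]
  extra$db_entry <- max(db$records$db_entry) + 1:5
  db2 <- ogmsv:::new_db_variant_set("INTERNAL", rbind(db$records, extra),
                                    db$n_samples)
  db2$samples <- db$samples
  r2 <- internal_frequency(q, db2, query_family = 1)
  expect_equal(r2$freq_perc_unfiltered, base$freq_perc_unfiltered)
  expect_equal(r2$freq_perc_filtered, base$freq_perc_filtered)
})

test_that("quality gates remove nbase, self-failing and chimeric-failing records", {
  dir <- withr::local_tempdir()
  files <- c(
    cohort_smap(dir, "S1", list()),
    cohort_smap(dir, "S2", list(del_row("a", type = "deletion_nbase"))),
    cohort_smap(dir, "S3", list(del_row("b", self = "no"))),
    cohort_smap(dir, "S4", list(del_row("c", type = "duplication", chim = "fail"))),
    cohort_smap(dir, "S5", list(del_row("d"))))
  key <- data.frame(sample = paste0("S", 1:5), family_id = 1:5, relation = 1)
  db <- build_internal_db(files, key)
  q <- make_query(4L, 500000, 650000, "deletion", size = 150000)
  r <- internal_frequency(q, db, query_family = 1)
  # nbase and self="no" records match but are gated out of the filtered figure
  expect_equal(r$alleles_unfiltered, 3)
  expect_equal(r$alleles_filtered, 1)
  qd <- make_query(4L, 500000, 650000, "duplication", size = 150000)
  rd <- internal_frequency(qd, db, query_family = 1)
  expect_equal(rd$alleles_unfiltered, 1)  # the chimeric-fail duplication
  expect_equal(rd$alleles_filtered, 0)
})

test_that("planting a homozygous variant in k of N samples gives 2k/2N", {
  dir <- withr::local_tempdir()
  N <- 6; k <- 2
  files <- lapply(1:N, function(i) {
    rows <- if (i <= k) list(del_row(paste0("v", i), zyg = "homozygous")) else list()
    cohort_smap(dir, paste0("S", i), rows)
  })
  key <- data.frame(sample = paste0("S", 1:N), family_id = 100 + 1:N, relation = 1)
  db <- build_internal_db(files, key)
  q <- make_query(4L, 500000, 650000, "deletion", size = 150000)
  r <- internal_frequency(q, db, query_family = 999)
  expect_equal(r$freq_perc_unfiltered, 2 * k / (2 * N) * 100)
})

test_that("a cohort consisting only of the family is not computable", {
  dir <- withr::local_tempdir()
  files <- c(cohort_smap(dir, "S1", list(del_row("a"))),
             cohort_smap(dir, "S2", list(del_row("b"))))
  key <- data.frame(sample = c("S1", "S2"), family_id = 1, relation = 1:2)
  db <- build_internal_db(files, key)
  q <- make_query(4L, 500000, 650000, "deletion", size = 150000)
  r <- internal_frequency(q, db, query_family = 1)
  expect_true(is.na(r$freq_perc_unfiltered))
  expect_true(is.na(r$freq_perc_filtered))
})

test_that("parental zygosity uses tight similarity and reports per parent", {
  db <- worked_cohort(withr::local_tempdir())
  q <- make_query(4L, 500000, 650000, "deletion", size = 150000)
  z <- parental_zygosity(q, db, family = 1)
  # both maternal records (identical + shifted with 96.7% size similarity)
  # are heterozygous; no paternal record exists
  expect_equal(z$mother_zygosity, "heterozygous")
  expect_equal(z$father_zygosity, "-")
})

test_that("discordant parental matches join in homozygous-first order", {
  dir <- withr::local_tempdir()
  files <- c(cohort_smap(dir, "S1", list()),
             cohort_smap(dir, "S2", list(del_row("m1", zyg = "heterozygous"),
                                         del_row("m2", zyg = "homozygous"))),
             cohort_smap(dir, "S3", list(del_row("f1", zyg = "unknown"))))
  key <- data.frame(sample = c("S1", "S2", "S3"), family_id = 1, relation = 1:3)
  db <- build_internal_db(files, key)
  q <- make_query(4L, 500000, 650000, "deletion", size = 150000)
  z <- parental_zygosity(q, db, family = 1)
  expect_equal(z$mother_zygosity, "homozygous,heterozygous")
  expect_equal(z$father_zygosity, "unknown")
})

test_that("a shifted parental record below 90% similarity is rejected", {
  dir <- withr::local_tempdir()
  files <- c(cohort_smap(dir, "S1", list()),
             cohort_smap(dir, "S2", list(
               del_row("m1", start = 508000, size = 100000))))
  key <- data.frame(sample = c("S1", "S2"), family_id = 1, relation = 1:2)
  db <- build_internal_db(files, key)
  q <- make_query(4L, 500000, 650000, "deletion", size = 150000)
  # windows pass (8 kb) but 100/150 = 0.67 < 0.9
  expect_equal(parental_zygosity(q, db, family = 1)$mother_zygosity, "-")
  # the default matching criteria would have accepted it
  expect_equal(parental_zygosity(q, db, family = 1,
                                 perc_similarity_parent = 0.5)$mother_zygosity,
               "heterozygous")
})
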
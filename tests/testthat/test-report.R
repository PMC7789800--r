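test_that("sheet plans carry the fixed names and counts per mode", {
  expect_equal(sheet_plan("solo", "single_enzyme"),
               c("indel_dup", "inv", "trans", "all_PG_OV", "all"))
  expect_length(sheet_plan("solo", "svmerge"), 6)
  expect_length(sheet_plan("duo", "single_enzyme"), 6)
  expect_length(sheet_plan("duo", "svmerge"), 7)
  expect_equal(sheet_plan("trio", "single_enzyme"),
               c("indel_dup_denovo", "indel_dup_both", "indel_dup_mother",
                 "indel_dup_father", "indel_dup_cmpdHET", "inv", "trans",
                 "all_PG_OV", "all"))
  expect_length(sheet_plan("trio", "svmerge"), 10)
  expect_true(all(vapply(list(sheet_plan("trio", "svmerge")),
                         function(p) "Mismatch" %in% p, TRUE)))
  expect_false("Mismatch" %in% sheet_plan("trio", "single_enzyme"))
})

filter_callset <- function(rows) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  p <- file.path(dir, "f.smap")
  cols <- c(basic_smap_cols[1:11], "Found_in_parents_molecules")
  write_lines_smap(p, cols, rows)
  read_sv_file(p)
}

test_that("default filtration gates on self molecules and chimeric score", {
  cs <- filter_callset(list(
    c("1", "1", "1", "1000", "60000", "deletion", "59000", "0.9",
      "heterozygous", "no", "pass", "none"),
    c("2", "1", "1", "1000", "60000", "duplication", "59000", "-1",
      "heterozygous", "yes", "fail", "none"),
    c("3", "1", "1", "1000", "60000", "insertion", "59000", "0.9",
      "heterozygous", "yes", "fail", "none"),
    c("4", "1", "1", "1000", "60000", "deletion", "59000", "0.9",
      "heterozygous", "yes", "pass", "none")))
  # self=no always drops; chimeric fail drops duplications but not indels
  expect_equal(default_filter(cs), c(FALSE, FALSE, TRUE, TRUE))
})

test_that("trio categorization routes indels by parental support", {
  cs <- filter_callset(list(
    c("1", "1", "1", "1000", "60000", "deletion", "59000", "0.9",
      "heterozygous", "yes", "pass", "none"),
    c("2", "1", "1", "100000", "160000", "insertion", "59000", "0.9",
      "heterozygous", "yes", "pass", "both"),
    c("3", "1", "1", "200000", "260000", "duplication_split", "59000", "-1",
      "heterozygous", "yes", "pass", "mother"),
    c("4", "1", "1", "300000", "360000", "deletion", "59000", "0.9",
      "heterozygous", "yes", "pass", "father"),
    c("5", "2", "2", "1000", "400000", "inversion_paired", "-1", "0.02",
      "unknown", "yes", "pass", "both"),
    c("6", "2", "3", "1000", "400000", "trans_interchr_common", "-1", "0.2",
      "unknown", "yes", "pass", "none"),
    c("7", "2", "3", "1000", "400000", "translocation_interchr", "-1", "0.2",
      "unknown", "yes", "pass", "none"),
    c("8", "3", "3", "1000", "60000", "deletion_nbase", "59000", "0.9",
      "heterozygous", "yes", "pass", "none")))
  cat <- categorize(cs, "trio")
  expect_equal(cat$indel_dup_denovo, 1L)
  expect_equal(cat$indel_dup_both, 2L)
  expect_equal(cat$indel_dup_mother, 3L)
  expect_equal(cat$indel_dup_father, 4L)
  expect_equal(cat$indel_dup_cmpdHET, c(3L, 4L))
  expect_equal(cat$inv, 5L)
  # likely-false "common" translocation types stay out of the trans sheet
  expect_equal(cat$trans, 7L)
  # nbase rows appear in no category sheet (only "all")
  expect_false(8L %in% unlist(cat))
})

test_that("inheritance sheets partition the filtered indel set", {
  set.seed(31)
  rows <- lapply(1:60, function(i) {
    type <- sample(c("deletion", "insertion", "duplication"), 1)
    par <- sample(c("none", "both", "mother", "father"), 1)
    self <- sample(c("yes", "no"), 1, prob = c(0.8, 0.2))
    start <- i * 1e5
    c(as.character(i), "1", "1", format(start, scientific = FALSE),
      format(start + 50000, scientific = FALSE), type, "50000", "0.9",
      "heterozygous", self, "pass", par)
  })
  cs <- filter_callset(rows)
  cat <- categorize(cs, "trio")
  filtered_indel <- which(default_filter(cs) &
                            cs$calls$sv_class %in%
                              c("insertion", "deletion", "duplication"))
  parts <- cat[c("indel_dup_denovo", "indel_dup_both", "indel_dup_mother",
                 "indel_dup_father")]
  expect_setequal(unlist(parts), filtered_indel)
  expect_equal(sum(lengths(parts)), length(filtered_indel))  # disjoint
  expect_setequal(cat$indel_dup_cmpdHET,
                  c(cat$indel_dup_mother, cat$indel_dup_father))
  expect_equal(length(cat$indel_dup_cmpdHET),
               length(cat$indel_dup_mother) + length(cat$indel_dup_father))
})

test_that("duo categorization splits by control-sample sharing", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "duo.smap")
  cols <- c(basic_smap_cols[1:11], "Found_in_control_molecules")
  write_lines_smap(p, cols, list(
    c("1", "1", "1", "1000", "60000", "deletion", "59000", "0.9",
      "heterozygous", "yes", "pass", "no"),
    c("2", "1", "1", "100000", "160000", "deletion", "59000", "0.9",
      "heterozygous", "yes", "pass", "yes")))
  cs <- read_sv_file(p)
  expect_equal(cs$design, "duo")
  cat <- categorize(cs, "duo")
  expect_equal(cat$indel_dup_notShared, 1L)
  expect_equal(cat$indel_dup_Shared, 2L)
})

test_that("a trio design without parental columns is a configuration error", {
  cs <- filter_callset(list(
    c("1", "1", "1", "1000", "60000", "deletion", "59000", "0.9",
      "heterozygous", "yes", "pass", "none")))
  cs$calls$parental_support <- "not_applicable"
  expect_error(categorize(cs, "trio"), "parental")
})

test_that("the all sheet preserves every input row and reruns are identical", {
  fx <- generate_fixture(fixture_spec(seed = 3, n_background = 3),
                         withr::local_tempdir())
  cfg <- list(sv_file = fx$paths$query, design = "trio", family_id = 1,
              internal_db = fx$paths$internal_db, bed = fx$paths$bed,
              out = NA)
  rep1 <- run_pipeline(cfg, quiet = TRUE)
  expect_equal(nrow(rep1$sheets$all), fx$expected$n_calls)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(run_pipeline(modifyList(cfg, list(out = NA)), quiet = TRUE), d1)
  write_report(rep1, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
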
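genes_df <- function(...) {
  g <- data.frame(..., stringsAsFactors = FALSE)
  structure(g, class = c("gene_interval_set", "data.frame"))
}

layout1 <- genes_df(
  chrom = c(4L, 4L, 4L, 4L, 4L, 4L, 4L),
  start = c(520000, 643701, 460000, 430000, 400000, 660000, 670000),
  end = c(550000, 653700, 490000, 480000, 470000, 700000, 720000),
  strand = c("+", "-", "+", "-", "+", "+", "-"),
  symbol = c("GENEA", "GENEB", "UPG1", "UPG2", "UPG3", "DNG1", "DNG2"))

test_that("a deletion spanning a whole gene reports 100% of the gene", {
  sv <- make_query(4L, 500000, 650000, "deletion")
  ov <- overlap_genes(sv, layout1)
  expect_setequal(ov$symbol, c("GENEA", "GENEB"))
  expect_equal(ov$percent[ov$symbol == "GENEA"], 100)
})

test_that("partial overlap is the covered fraction of the gene length", {
  sv <- make_query(4L, 500000, 650000, "deletion")
  ov <- overlap_genes(sv, layout1)
  # 6300 bp of the 10000 bp gene fall inside the SV
  expect_equal(ov$percent[ov$symbol == "GENEB"], 63, tolerance = 1e-9)
})

test_that("an SV inside a gene reports its own span over the gene length", {
  sv <- make_query(4L, 530000, 532999, "insertion")
  ov <- overlap_genes(sv, layout1)
  expect_equal(ov$percent[ov$symbol == "GENEA"],
               3000 / 30001 * 100, tolerance = 1e-9)
})

test_that("window-only neighbours are reported at the display floor", {
  # gene ends 2 kb before the SV: inside the 3 kb search window, zero true
  # overlap, floored at 0.01 so it is distinguishable from no overlap
  g <- genes_df(chrom = 1L, start = 10000, end = 20000, strand = "+",
                symbol = "NEAR")
  sv <- make_query(1L, 22000, 30000, "deletion")
  ov <- overlap_genes(sv, g)
  expect_equal(ov$percent, 0.01)
  # and outside the window nothing is reported
  sv2 <- make_query(1L, 24000, 30000, "deletion")
  expect_equal(nrow(overlap_genes(sv2, g)), 0)
})

test_that("overlap percent is always in (0, 100]", {
  set.seed(13)
  g <- genes_df(chrom = 1L, start = cumsum(sample.int(5e4, 30)) + 1,
                end = cumsum(sample.int(5e4, 30)) + sample.int(3e4, 30) + 10,
                strand = "+", symbol = sprintf("G%02d", 1:30))
  g <- g[g$start < g$end, , drop = FALSE]
  for (i in 1:30) {
    s <- sample.int(8e5, 1)
    sv <- make_query(1L, s, s + sample.int(2e5, 1), "deletion")
    pct <- overlap_genes(sv, g)$percent
    expect_true(all(pct > 0 & pct <= 100))
  }
})

test_that("nearest genes sort by distance and exclude overlaps", {
  sv <- make_query(4L, 500000, 650000, "deletion")
  nr <- nearest_genes(sv, layout1, k = 3)
  expect_equal(nr$upstream$symbol, c("UPG1", "UPG2", "UPG3"))
  expect_equal(nr$upstream$dist_kb, c(10, 20, 30))
  expect_equal(nr$downstream$symbol, c("DNG1", "DNG2"))
  expect_equal(nr$downstream$dist_kb, c(10, 20))
  # overlap and nearest sets are disjoint
  ov <- overlap_genes(sv, layout1)
  expect_length(intersect(ov$symbol,
                          c(nr$upstream$symbol, nr$downstream$symbol)), 0)
  expect_equal(nrow(nearest_genes(sv, layout1, k = 0)$upstream), 0)
})

test_that("nearest-gene selection agrees with a linear scan on random layouts", {
  set.seed(19)
  for (rep in 1:20) {
    n <- 40
    start <- sample.int(2e6, n)
    g <- genes_df(chrom = 1L, start = start, end = start + sample.int(2e4, n),
                  strand = "+", symbol = sprintf("G%02d", 1:n))
    s <- sample.int(2e6, 1)
    sv <- make_query(1L, s, s + 5e4, "deletion")
    ov <- overlap_genes(sv, g)
    nr <- nearest_genes(sv, g, k = 3, overlaps = ov)
    # oracle: order every wholly-upstream gene by distance
    up <- g[g$end < sv$ref_start & !g$symbol %in% ov$symbol, ]
    up <- up[order(sv$ref_start - up$end, up$start, up$symbol), ]
    expect_equal(nr$upstream$symbol, head(up$symbol, 3))
    dn <- g[g$start > sv$ref_end & !g$symbol %in% ov$symbol, ]
    dn <- dn[order(dn$start - sv$ref_end, dn$start, dn$symbol), ]
    expect_equal(nr$downstream$symbol, head(dn$symbol, 3))
  }
})

test_that("enlarging the search window never shrinks the overlap list", {
  sv <- make_query(4L, 500000, 650000, "deletion")
  small <- overlap_genes(sv, layout1, win_indel_gene = 0)
  big <- overlap_genes(sv, layout1, win_indel_gene = 20000)
  expect_true(all(small$symbol %in% big$symbol))
  expect_true(nrow(big) >= nrow(small))
})

test_that("translocations annotate genes around both breakpoints", {
  g <- genes_df(chrom = c(7L, 8L), start = c(1495000, 2505000),
                end = c(1505000, 2515000), strand = c("+", "-"),
                symbol = c("BPG1", "BPG2"))
  sv <- make_query(7L, 1500000, 2510000, "translocation", size = NA,
                   chrom2 = 8L)
  ov <- overlap_genes(sv, g)
  expect_setequal(ov$symbol, c("BPG1", "BPG2"))
  expect_true(all(ov$percent > 0 & ov$percent <= 100))
})

test_that("formatted annotation columns join entries with semicolons", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "one.smap")
  write_lines_smap(p, basic_smap_cols, list(
    c("1", "4", "4", "500000", "650000", "deletion", "150000", "0.9",
      "heterozygous", "yes", "pass", "x")))
  cs <- annotate_genes(read_sv_file(p), layout1)
  expect_equal(cs$calls$OverlapGenes_strand_perc, "GENEA(+:100);GENEB(-:63)")
  expect_equal(cs$calls$Upstream_nonOverlapGenes_dist_kb,
               "UPG1(+:10.00);UPG2(-:20.00);UPG3(+:30.00)")
  expect_equal(cs$calls$Downstream_nonOverlapGenes_dist_kb,
               "DNG1(+:10.00);DNG2(-:20.00)")
})
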
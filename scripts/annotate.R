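#!/usr/bin/env Rscript
# Thin command-line wrapper over ogmsv::run_pipeline() for the six
# design-by-dialect entry modes.
#
#   Rscript scripts/annotate.R --mode trio-se --smap proband.smap \
#     --bed genes.bed --dgv dgv.txt --decipher decipher.txt \
#     --bndb-dir bndb/ --internal-db internal_db.tsv --family-id 23 \
#     --terms osteoporosis --out report_dir
#
# Modes: solo-se, solo-svmerge, duo-se, duo-svmerge, trio-se, trio-svmerge.

suppressMessages({
  library(ogmsv)
  library(optparse)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--mode", type = "character",
              help = "one of solo-se, solo-svmerge, duo-se, duo-svmerge, trio-se, trio-svmerge"),
  make_option("--smap", type = "character", help = "SV call file (SMAP or SVmerge TXT)"),
  make_option("--bed", type = "character", default = NULL, help = "gene BED file"),
  make_option("--bed-fmt", type = "character", default = "BED",
              help = "BED or BNBED [default %default]"),
  make_option("--dgv", type = "character", default = NULL),
  make_option("--decipher", type = "character", default = NULL),
  make_option("--bndb-dir", type = "character", default = NULL),
  make_option("--bndb-reference", type = "character", default = "hg19"),
  make_option("--bndb-n-samples", type = "integer", default = 234),
  make_option("--internal-db", type = "character", default = NULL),
  make_option("--family-id", type = "integer", default = NULL),
  make_option("--expression", type = "character", default = NULL,
              help = "comma-separated per-sample expression tables"),
  make_option("--genelist", type = "character", default = NULL,
              help = "primary gene list CSV (bypasses term search)"),
  make_option("--terms", type = "character", default = NULL,
              help = "comma-separated phenotype terms"),
  make_option("--snapshot-dir", type = "character", default = NULL,
              help = "directory with omim.tsv/clinvar.tsv/gtr.tsv/gene.tsv"),
  make_option("--win-indel", type = "double", default = 10000),
  make_option("--win-inv-trans", type = "double", default = 50000),
  make_option("--perc-similarity", type = "double", default = 0.5),
  make_option("--k-nearest", type = "integer", default = 3),
  make_option("--out", type = "character", default = NULL,
              help = "report output directory")
)))

if (is.null(opts$mode) || is.null(opts$smap)) {
  stop("--mode and --smap are required; see the header of this script")
}
parts <- strsplit(opts$mode, "-")[[1]]
design <- parts[1]
dialect <- if (identical(parts[2], "se")) "single_enzyme" else "svmerge"

snapshots <- NULL
if (!is.null(opts$`snapshot-dir`)) {
  cand <- c(OMIM = "omim.tsv", ClinVar = "clinvar.tsv", GTR = "gtr.tsv",
            Gene = "gene.tsv")
  found <- file.path(opts$`snapshot-dir`, cand)
  snapshots <- as.list(found[file.exists(found)])
  names(snapshots) <- names(cand)[file.exists(found)]
}

run_pipeline(list(
  sv_file = opts$smap, dialect = dialect, design = design,
  bed = opts$bed, bed_fmt = opts$`bed-fmt`,
  dgv = opts$dgv, decipher = opts$decipher,
  bndb_dir = opts$`bndb-dir`, bndb_reference = opts$`bndb-reference`,
  bndb_n_samples = opts$`bndb-n-samples`,
  internal_db = opts$`internal-db`, family_id = opts$`family-id`,
  expression_files = if (!is.null(opts$expression))
    strsplit(opts$expression, ",")[[1]],
  genelist = opts$genelist,
  terms = if (!is.null(opts$terms)) strsplit(opts$terms, ",")[[1]],
  snapshots = snapshots,
  criteria = match_criteria(win_indel = opts$`win-indel`,
                            win_inv_trans = opts$`win-inv-trans`,
                            perc_similarity = opts$`perc-similarity`),
  k_nearest = opts$`k-nearest`,
  out = opts$out
))
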
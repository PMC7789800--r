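# ogmsv — structural-variant annotation for optical genome mapping

Optical genome mapping (OGM) calls large structural variants (SVs) from
long, fluorescently labelled DNA molecules. Because the technology is not
sequence-based, breakpoints carry a few kilobases of uncertainty, so the
"same" variant rarely has identical coordinates in two call sets — which
makes the two questions an analyst asks first ("how common is this
variant?" and "which genes does it touch?") harder than for small variants.
`ogmsv` answers both for Bionano-style SMAP and dual-enzyme SVmerge call
sets: it estimates population frequency against external databases (DGV,
DECIPHER and a control-sample database) and against a user-built internal
cohort, annotates overlapping and nearest genes, folds in expression values
and a phenotype-driven gene list, applies molecule-support quality
filtration, classifies inheritance, and writes a sheet-partitioned report.
It is aimed at rare-disease and clinical-research groups analysing
singleton, duo (proband vs. control) or trio (proband/mother/father) OGM
studies.

## The method

**Variant identity.** Two SVs of the same class (insertion, deletion,
duplication, inversion, translocation) on the same chromosome(s) are the
same event when each breakpoint lies within a window *W* of its
counterpart — |Δstart| ≤ W and |Δend| ≤ W, with W = 10 kb for
insertions/deletions/duplications and 50 kb for inversions/translocations —
and, for the indel classes, their sizes agree to at least 50 %:

    size similarity = min(s₁, s₂) / max(s₁, s₂) ≥ 0.5

(inversion/translocation sizes are often absent from caller output, so the
size rule is optional for them).

**External frequency.** For databases without zygosity (DGV, DECIPHER):

    freq % = n matching variants / (2 × n samples) × 100

For the zygosity-aware control database, matches are collapsed per carrier
sample and counted as alleles — 2 for homozygous or unknown zygosity, 1 for
heterozygous — and reported twice: *unfiltered* (all matches) and
*filtered* (candidates additionally need a confidence score above the class
threshold — 0.5 indels, 0.01 inversions, 0.1 translocations — and a size of
at least 1 kb).

**Internal cohort.** Per-sample call sets are concatenated under nanoID
labels (`NR<family>.<relation>`, relation 1/2/3 = proband/mother/father).
For a query from family *f*, matching records from family *f* are excluded
and the denominator is 2 × (cohort size − family members). Matching against
a parent uses a tightened 90 % size-similarity threshold (inherited
variants should be near-identical) and reports the parental zygosity.

**Genes.** Overlapping genes are searched within a ±3 kb (indel) or ±10 kb
(inversion/translocation) window around the SV and reported with the
percent of the gene's length covered by the unexpanded SV interval; the 3
nearest non-overlapping genes up- and downstream are reported with
distances in kb.

**Report.** Every call lands in the `all` sheet; quality filtration (self-
molecule support, plus a chimeric-score pass for duplications/inversions/
translocations) gates the type/inheritance sheets: `indel_dup_*` routed by
parental or control support (trio: de novo / both / mother / father, plus a
compound-heterozygous candidate sheet = mother-only ∪ father-only), `inv`,
`trans` (likely-false "common" translocation types excluded), `Mismatch`
(SVmerge only) and `all_PG_OV` (rows whose genes intersect the primary gene
list). That gives 5/6, 6/7 and 9/10 sheets for solo/duo/trio ×
single-enzyme/SVmerge. Reports are written as a workbook directory: one TSV
per sheet plus a `sheets.tsv` order index.

## Worked example

The synthetic-data generator builds a complete trio bundle with known
ground truth (no downloads needed):

```r
library(ogmsv)
fx <- generate_fixture(fixture_spec(seed = 7), "demo_bundle")
rep <- run_pipeline(list(
  sv_file     = fx$paths$query,       design   = "trio", family_id = 1,
  bed         = fx$paths$bed,         dgv      = fx$paths$dgv,
  decipher    = fx$paths$decipher,    bndb_dir = fx$paths$bndb_dir,
  internal_db = fx$paths$internal_db,
  terms = "osteoporosis", snapshots = fx$paths$snapshots,
  out = "demo_report"))
```

The run log ends with the sheet census:

    [ogmsv] sheet indel_dup_denovo       1 rows
    [ogmsv] sheet indel_dup_both         6 rows
    [ogmsv] sheet indel_dup_mother       1 rows
    [ogmsv] sheet indel_dup_father       1 rows
    [ogmsv] sheet indel_dup_cmpdHET      2 rows
    [ogmsv] sheet inv                    1 rows
    [ogmsv] sheet trans                  1 rows
    [ogmsv] sheet all_PG_OV              2 rows
    [ogmsv] sheet all                    15 rows

and the maternal 150 kb deletion planted by the generator carries, in the
`all` sheet:

```r
rep$sheets$all[rep$sheets$all$call_id == "pv_del_main",
               c("Internal_Freq_Perc_Filtered", "MotherZygosity",
                 "OverlapGenes_strand_perc")]
#   Internal_Freq_Perc_Filtered MotherZygosity OverlapGenes_strand_perc
#                         30.00   heterozygous GENEA(+:100);GENEB(-:63)
```

30.00 % is the family-excluded internal frequency — one heterozygous and
one homozygous carrier among the five non-family cohort samples gives
3 alleles / (2 × 5) — `GENEA(+:100)` means the deletion removes the whole
of GENEA, and `GENEB(-:63)` that it covers 63 % of the minus-strand GENEB.

A command-line wrapper over the same pipeline is in `scripts/annotate.R`
(modes `solo-se` … `trio-svmerge`; run it without arguments for usage).

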
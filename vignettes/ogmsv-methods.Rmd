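---
title: "Annotating optical-mapping structural variants with ogmsv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating optical-mapping structural variants with ogmsv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogmsv)
```

## The problem

Optical genome mapping (OGM) images long labelled DNA molecules to assemble
genome maps and call structural variants (SVs) — insertions, deletions,
duplications, inversions and translocations well beyond the reach of
short-read sequencing. Two properties of the technology shape everything
this package does. First, breakpoints are uncertain by roughly 3 kb, so two
call sets almost never place the "same" variant at identical coordinates;
variant identity must be defined with windows and size tolerance rather
than exact positions. Second, the caller attaches OGM-specific quality
evidence — single-molecule support for the assembled variant ("self
molecules") and a chimeric-join score — that a credible filtration step has
to respect.

`ogmsv` takes a call set (single-enzyme SMAP or dual-enzyme SVmerge TXT)
and annotates each call with population frequency, gene context, optional
expression and phenotype-list intersections, then partitions the calls into
a fixed sheet taxonomy by type and inheritance.

## Variant identity

Two SVs are treated as the same event when all of the following hold:

* same coarse class, after collapsing subtype strings (for example
  `duplication_split` and `duplication_inverted` both count as duplication,
  all `inversion_*` subtypes as inversion) — external databases only know
  the five coarse classes;
* same chromosome, and for translocations the same second breakpoint
  chromosome;
* per-breakpoint windows: |Δstart| ≤ W **and** |Δend| ≤ W, with
  W = `win_indel` (default 10 kb) for insertions/deletions/duplications and
  `win_inv_trans` (default 50 kb) for inversions/translocations;
* for the indel classes, size similarity min/max ≥ `perc_similarity`
  (default 0.5).

Two windows rather than one expanded interval: a deletion query at
350–550 kb retrieves candidates whose start lies in 340–360 kb *and* end in
540–560 kb, not everything inside 340–560 kb. For the printed examples both
readings coincide once the size rule applies; the per-breakpoint form is
the one we generalise because it is the only one stated explicitly for
inversions.

The size-similarity formula is the min/max ratio — symmetric, bounded in
(0, 1], and 1 exactly for equal sizes. Caller output frequently omits sizes
for inversions and translocations, so the size rule is off by default for
those classes (`apply_size_to_inv_trans = FALSE`); a candidate of an indel
class with no usable size can still match in *unfiltered* frequency but is
excluded from *filtered* figures, where the 1 kb minimum-size gate could
not be evaluated.

Retrieval is stratified by (chromosome, class) with the interval work done
through `IRanges`; the test suite pins the indexed result to a plain
linear-scan oracle on randomized fixtures.

## Frequency estimation

**Public databases (DGV, DECIPHER).** These report no zygosity, so the
frequency of a query is simply `matches / (2 × n_samples) × 100`. For DGV
the count of unique carrier samples is reported separately (a single
database entry may list several carriers); it does not enter the
percentage. The cohort size comes from the file where a sample-size column
exists, with a configuration override, because "number of samples" is not
well defined for multi-study aggregate files.

**Control database (BNDB-style).** Matches are first collapsed to one per
carrier sample, then counted as alleles: 2 for homozygous, 1 for
heterozygous, and — deliberately conservative — 2 for unknown zygosity,
which overestimates frequency but never hides a common variant. The
*unfiltered* figure uses all matches; the *filtered* figure additionally
requires each candidate to pass its class confidence threshold
(`conf_indel` 0.5, `conf_inv` 0.01, `conf_trans` 0.1; duplications carry no
score and are exempt, as is any record whose score is absent — the caller
writes −1 for classes it does not score) and the 1 kb minimum size. The
filtered match set is a subset of the unfiltered one by construction, so
filtered ≤ unfiltered always.

**Internal cohort.** Per-sample files are concatenated under nanoID labels
(`NR<family>.<relation>`; relation 1 proband, 2 mother, 3 father; an
optional project prefix keeps multi-project cohorts unique). Only trio
relation codes exist; anything else is rejected rather than guessed. For a
query from family *f*:

* records from family-*f* samples never enter the numerator;
* the denominator is 2 × (cohort − family members) — the whole family is
  removed, not just the proband, because its members are not independent
  chromosomes for this variant;
* exact duplicate records within one sample (same chromosome, breakpoints,
  type, size *and* zygosity) count once — the caller occasionally emits the
  same event under two indices. Zygosity is part of the key so a genuine
  hom + het pair in one sample is not collapsed; the per-sample allele rule
  then takes the stronger of the two.

The filtered internal figure additionally drops candidates that overlap
assembly gaps (`*_nbase` types), lack self-molecule support, or (for
duplications/inversions/translocations) fail the chimeric check. The
unfiltered figure applies only matching, family exclusion and
deduplication; the split mirrors the control database's filtered/unfiltered
pair, whose definition is otherwise silent for the internal case. Whether
the *query's own* quality flags should also gate its internal frequency was
genuinely open; we gate database candidates only, since the figures
describe the cohort, not the query. If the cohort consists entirely of the
query's family the frequency is reported as not computable (`NA`/dash), not
as an error or a zero.

The cohort roster is persisted with the database (a `#samples` header in
the TSV), so samples whose call files are empty still count in the
denominator after a save/reload round trip.

**Parental zygosity.** For duos/trios the query is matched against each
parent's records at `perc_similarity = 0.9` — inherited variants should be
virtually identical — with the standard windows. Each parent's column
reports the matched zygosities; several discordant matches are joined in
the fixed order homozygous < heterozygous < unknown, and "-" marks no
match.

## Gene context

Search windows of ±3 kb (indels) and ±10 kb (inversions/translocations)
absorb breakpoint uncertainty when *finding* genes; the reported percent is
always computed on the unexpanded SV interval, as overlap length over gene
length, capped at 100. Three corner cases needed decisions the source
material does not make:

* an SV wholly inside a gene reports its own span over the gene length;
* a gene inside the search window but not touching the SV is reported at a
  display floor of 0.01 %, so "found near the breakpoint" is never confused
  with "not found";
* translocations are annotated per breakpoint, as point positions with the
  ±10 kb window, on each breakpoint's chromosome.

The *k* nearest non-overlapping genes (default 3) are listed up- and
downstream with distances in kb, sorted ascending, ties broken by start
coordinate then symbol for determinism. Cells are rendered
`SYMBOL(strand:value)` joined by semicolons.

## Expression and gene lists

Per-sample quantification tables (gene symbol + TPM, any quantifier)
combine by outer join; a gene absent from a sample stays absent (`NA`,
rendered `SYMBOL(-)`), never zero. The sample's family role comes from a
filename token (`_P_`, `_UM_`/`_AM_`, `_UF_`/`_AF_`); an ambiguous filename
is an error rather than a guess. Duplicate symbols within a file sum their
TPM. Three columns are appended per role — overlap, upstream, downstream —
giving 3/6/9 columns for solo/duo/trio.

The primary gene list is built from local snapshot tables of four
condition-to-gene sources (NCBI Gene, OMIM, GTR, ClinVar) by
case-insensitive substring match of the phenotype terms over the condition
field — the simplest semantics consistent with keyword queries against
those services, and documented as such since the upstream search semantics
are not specified. Matching is snapshot-based so results are reproducible;
live queries drift between database releases and are out of the tested
core. Genes with Pathogenic / Likely pathogenic ClinVar records for a
matched condition are flagged in `ClinicalSignificance`; all matched genes
are kept regardless of significance.

## Filtration and the sheet taxonomy

Default filtration keeps a call iff it has self-molecule support, plus a
chimeric-score pass for duplications, inversions and translocations. It
applies to every sheet except `all` (always the complete input), `all_PG_OV`
(gene-list intersections, deliberately unfiltered so a relevant variant is
never hidden by a quality flag) and `Mismatch`. Parental support `-`
(SVmerge) means "none"; enzyme-paired quality columns harmonize
disjunctively (support from either enzyme counts). `*_nbase` calls
(overlapping assembly gaps) appear only in `all`. Translocation subtypes
flagged `*_common` are upstream-annotated likely-false calls and stay out
of the `trans` sheet. The compound-heterozygous candidate sheet is exactly
the union of the mother-only and father-only sheets — a manual-inspection
aid, not a phased call. Manual frequency/confidence cut-offs (e.g. the 1 %
rare-variant threshold) are left to the analyst on the written sheets; the
package's defaults apply only the quality gates.

Reports are written as a workbook directory — one TSV per sheet plus a
`sheets.tsv` order index — a plain-text container that diffs cleanly,
round-trips losslessly (`read_report()`), and feeds downstream pipelines
directly. Sheet order is fixed; `all` is last.

## The synthetic-data generator

`generate_fixture()` emulates the study conditions end to end: an 8-sample
internal cohort of which 3 form the query family (trio), a 234-sample
control database, small DGV/DECIPHER tables, a toy genome of 24
chromosomes × 5 Mb, and a default planted-variant set that covers every
sheet of the taxonomy plus the edge cases that matter: a maternal deletion
also carried by one heterozygous and one homozygous unrelated sample (the
worked 3/10 = 30 % scenario) with a duplicated caller record and a
breakpoint-shifted maternal copy at 96.7 % size similarity; a de novo
deletion; variants failing the self-molecule, chimeric and nbase gates; a
likely-false `trans_interchr_common` call; an 800 bp database candidate
that passes size similarity but fails the 1 kb gate; and a sizeless
inversion candidate. Every expectation in the generated manifest is derived
analytically from the planted geometry and the frequency formulas — not by
running the pipeline. One seeded stream drives all randomness; equal seeds
give byte-identical bundles.

What the fixtures do *not* emulate: molecule-level noise, assembly
artefacts beyond the planted duplicates, realistic SV size and frequency
spectra, and reference-genome scale. Passing tests therefore demonstrate
correctness of the matching, counting, annotation and partition logic under
controlled conditions, not calling performance on real genomes. The
generator's background variants are placed on chromosomes disjoint from the
planted ones, 200 kb apart across samples, so they can never perturb a
planted expectation through an accidental window match.

Problem sizes throughout the suite (cohorts of 8, databases of tens to
hundreds of records, 500-record/1000-query matching oracles) were chosen so
each property is exercised meaningfully while the whole suite stays
interactive; all scale linearly if enlarged.

## Numerical conventions and limitations

* Percentages are stored at full precision; report columns display them
  truncated (not rounded) to two decimals, matching the convention in which
  43/468 × 100 = 9.188 prints as 9.18.
* SMAP coordinates are treated as 1-based inclusive; BED input is converted
  from 0-based half-open on read, and the numeric-chromosome dialect
  (X/Y = 23/24) is produced by `bed_to_bnbed()`.
* Confidence −1 means "no score for this class" and is distinct from 0; it
  passes confidence gates, a 0 score does not.
* Hemizygous X/Y calls arrive from the caller labelled homozygous; the
  allele counting reproduces that upstream behaviour, so internal
  frequencies of X-chromosome variants in XY individuals are overestimated.
  Sex-aware counting is out of scope.
* Only trio pedigrees are supported; relation codes beyond 3 are rejected.
* VCF input/output, gnomAD-SV, automated pathogenicity classification and
  live database queries are out of scope.
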
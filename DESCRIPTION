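Package: ogmsv
Title: Structural Variant Annotation for Optical Genome Mapping
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Annotation engine for structural variants (SVs) called from
    optical genome mapping (OGM) assemblies. Parses single-enzyme SMAP and
    dual-enzyme SVmerge call sets, estimates population frequency of each
    variant against external databases (DGV, DECIPHER and a Bionano-style
    control database) and against a user-built internal cohort with
    family-aware exclusion and zygosity-aware allele counting, annotates
    overlapping and nearest genes from BED gene models, integrates gene
    expression matrices and phenotype-driven primary gene lists, applies
    molecule-support and chimeric-score quality filtration, classifies
    inheritance (de novo, maternal, paternal, biparental, compound
    heterozygous candidates), and writes a sheet-partitioned report. A
    deterministic synthetic-data generator produces complete input bundles
    with analytically known ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
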
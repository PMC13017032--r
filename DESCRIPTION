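Package: mosaicburden
Title: Somatic Mosaic Variant Detection and Burden Analysis for Deep
    Targeted and Single-Cell Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detection of low allele-frequency somatic mosaic variants from
    UMI-tagged deep targeted sequencing and from single-cell RNA pileups,
    with downstream burden statistics. Provides a seeded synthetic-cohort
    generator with planted ground-truth variants, UMI family grouping and
    consensus error correction, two independent low-VAF callers (binomial
    and beta-binomial against a site error model) with configurable call
    integration and an allele-frequency window for somatic classification,
    a negative-binomial GLM for case-control mutation burden with
    covariates, a cell-type-stratified single-cell caller with per-cell
    burden and pairwise cell-type contrasts, 96-channel trinucleotide
    mutational-signature refitting by non-negative least squares, weighted
    permutation gene-set burden enrichment, and plain-text readers and
    writers (FASTA, BED, VCF, GMT, TSV) plus a deterministic pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    pracma,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
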
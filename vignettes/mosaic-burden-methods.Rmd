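---
title: "Detecting somatic mosaic variants and testing mutation burden: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic mosaic variants and testing mutation burden: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mosaicburden implements an end-to-end analysis for somatic mosaicism in
deep targeted sequencing of disease-gene panels, motivated by the study of
post-zygotic mutations in the motor cortex of ALS patients: error-corrected
low-VAF variant calling, negative-binomial burden comparison across disease
groups (sALS, fALS, control), cell-type-resolved somatic calling from
single-cell RNA pileups, trinucleotide mutational-signature refitting, and
gene-set burden enrichment. Because the patient-level sequencing data of
such studies are controlled-access, the package ships a first-class
synthetic cohort generator with planted ground truth, and every statistical
claim the package makes about itself is demonstrated on those synthetic
cohorts by the test suite and the acceptance script.

```{r setup, eval = FALSE}
library(mosaicburden)
```

## The synthetic cohort generator

The generator defines the study conditions under which everything else is
tested.

**Panel and reference.** `generate_panel()` builds one random contig per
gene with a toy but complete gene geometry (intergenic flank, 5'UTR, exons
and introns, 3'UTR). The default panel uses seven ALS-associated genes
(VAPB, MAPT, FUS, NEFH, CCNF, NEK1, TBK1). Coordinates are 0-based
half-open everywhere inside the package; conversion to 1-based happens only
when writing VCF.

**Bulk samples.** `simulate_sample()` works at pileup level: per-site depth
is Poisson around the sample's mean coverage (default design target 2000x,
the depth at which mosaic variants around a few percent VAF are
detectable), background errors hit each non-reference base at rate `e/3`
(default `e` = 1e-3, a realistic post-consensus error rate), and a planted
variant with true fraction `v` draws its alternate count from
Binomial(depth, `v(1-e) + (1-v)e/3`). Somatic true VAFs are drawn
log-uniformly on (0.015, 0.35): the log-uniform prior reproduces the
low-frequency-heavy shape of observed mosaic VAF distributions without
asserting a parametric form the data do not constrain. Germline variants
sit at 0.5 (heterozygous) or 1.0. Group sizes default to 9 sALS / 4 fALS /
6 controls — the scale of a deep-sequencing autopsy cohort — and the
expected somatic count per sample defaults to 40 in sALS versus 20 in fALS
and controls, encoding the direction "sALS carries roughly twice the
control burden; fALS does not differ from controls". Read-level simulation
(`simulate_tagged_reads()`) exists separately for the UMI module, where
per-read errors (default 1e-2) and UMI family structure matter; pileup
level is used at cohort scale to keep simulations fast enough to replicate
hundreds of times.

**Single-cell cohorts.** `simulate_sc_cohort()` emulates the sparsity of
scRNA-derived pileups: per-cell, per-site coverage is zero-inflated Poisson
(defaults: dropout 0.7, mean depth 8 at covered sites), cell types are
annotated labels (no clustering is performed), and each planted clonal
variant is carried heterozygously by a stated fraction of the cells of one
host type — by default excitatory neurons, the cell type where clonal
somatic variants concentrate in cortical tissue. The generator does not
model amplification chimeras, doublets, RNA editing, or quality-score
ladders; consequently, passing tests demonstrate correctness of the
statistical machinery under a clean error model, not robustness to every
artifact class of real scRNA data.

All generators are pure functions of their seed; stage seeds are derived
from the global seed by a stable hash of the stage name so each stage is
reproducible in isolation.

## UMI consensus

Reads sharing a start coordinate are grouped by UMI with greedy directional
merging: UMIs are visited by decreasing read count (ties broken
lexicographically, for determinism) and absorbed into the first accepted
family within Hamming distance 1 (default). Families smaller than 3 reads
are dropped; at each offset the modal base is emitted only when its
fraction reaches 0.75, ties and sub-threshold offsets are masked and
counted separately so that depth + masked always equals the number of
covering families. The consensus is count-based; quality scores are not
used. These defaults are ordinary single-strand UMI practice and are all
exposed as arguments. With per-read error 1e-2 and mean family size 5 the
measured post-consensus discordance is below `e/5` and a paired comparison
shows consensus is never worse than the raw reads for families of three or
more — both checked by the suite.

## Low-VAF calling

`estimate_error_model()` pools the non-reference fraction over non-variant
sites into a global error rate `e` (clamped to [1e-6, 0.499]) and
estimates beta-binomial overdispersion `rho` by method of moments on
per-site alternate fractions. Sites whose alternate fraction exceeds 0.005
are masked from the estimate by default so that genuine variants do not
inflate the error model.

Two callers test each site's top alternate count against an upper-tail
null: Binomial(depth, `e`) and BetaBinomial(depth, `e`, `rho`). The
beta-binomial tail is computed by a pmf-ratio recurrence advanced jointly
over sites, with early termination once remaining terms are negligible;
at `rho` = 0 it reproduces the binomial tail to 1e-10. Candidates are
emitted at `alpha` = 1e-6 by default, integrated across callers by
intersection (default; union and at-least-k are available), and classified
by the allele-frequency window: somatic iff 0.015 < VAF < 0.35 with both
bounds open, germline at or above 0.35, filtered at or below 0.015. The
window endpoints are strict inequalities deliberately. Only SNVs are
called, one alternate allele per site (the strongest); minimum depth
defaults to 500 consensus families, a quarter of the design coverage, so
sparse simulated samples remain testable.

A numerical caveat worth recording: under an overdispersed null with
`rho` = 0.01, the exact beta-binomial tail at the expected alternate count
of a 5% variant at 2000x is about 1.6e-4, so no threshold as small as 1e-6
can detect such variants — detection under that much overdispersion
requires `alpha` around 1e-3. In practice `rho` is estimated from the data,
and on binomially-behaved pileups it estimates near zero, where the default
`alpha` retains essentially full power; the test suite pins both regimes.

## Burden statistics

`build_burden()` counts somatic-classified calls per sample in total, per
AF bin (left-open right-closed, default edges 0.015/0.05/0.15/0.35), and
per gene. `burden_test()` fits the enrichment model: a negative-binomial
GLM (log link, NB2 variance) of total count on disease group with sex,
age, origin and log total coverage as covariates, control as reference
level and the most frequent origin as its reference. Total coverage enters
as a log-linear covariate, not an offset, because panel burden is not
proportional to coverage once depth saturates the callable fraction.
Covariates are added only while the design keeps full rank with spare
degrees of freedom, so very small cohorts degrade gracefully to the
group-only model instead of erroring.

`nb_glm()` is fitted by alternating IRLS for the coefficients with
maximum-likelihood updates of the dispersion on a log scale, until the
relative log-likelihood change falls below 1e-8 (at most 100 alternations;
non-convergence is flagged, never silent). The linear predictor is clamped
to [-15, 15] inside IRLS so that strata with all-zero counts (whose MLE
diverges) leave the solve well conditioned. Dispersion is searched in
[1e-3, 1e6]; hitting the upper bound means an effectively Poisson fit and
is reported as such. The fit matches `MASS::glm.nb` to at least four
decimals on shared datasets and reduces to the Poisson GLM as theta grows
— both are test invariants, with `glm.nb` serving strictly as a
cross-check.

Inference is deliberately small-sample aware. Wald statistics are referred
to a t distribution on the residual degrees of freedom because the
dispersion is estimated; `confint()` inverts the likelihood-ratio test
along the profile (dispersion re-estimated at each fixed coefficient
value) with the LR statistic calibrated against F(1, residual df), the
same spirit as quasi-likelihood F-tests in small-sample count analysis;
and `nb_glm_lrt()` provides the matching single-term test. The motivation
is measurable: at the cohort scales this package targets (tens of
samples), plain Wald-z intervals cover a true log-2 group effect only
about 92% of the time, while the profile-F intervals restore roughly 94%
coverage with a null rejection rate near 5.5% — properties the acceptance
suite verifies at n = 30, theta = 10, over hundreds of seeded replicates.

`summary_t_test()` reports per-group mean and SD of total burden with a
two-sided Welch t-test (the pooled-variance Student variant is a flag),
`fdr_adjust()` is Benjamini-Hochberg step-up, and `gene_burden_ratio()`
reports per-gene mean-count ratios with a 0.5 pseudo-count in both
numerator and denominator (so empty genes give ratio 1 instead of 0/0)
plus per-gene GLM tests, BH-adjusted across genes. The per-gene GLM is
group-only by default: per-gene counts are sparse, and a full covariate
model at a handful of counts per sample is noise.

## Single-cell somatic calling

This module is a re-specification, not a port, of cell-type-contrast
calling in the style of SComatic; every threshold is explicit.
`aggregate_by_celltype()` sums per-cell counts into per-type counts with
an exact backtrace. At each site, each sufficiently covered type (default:
at least 5 covered cells and 20 aggregated reads) is tested against a
beta-binomial error null (default `rho` 0.01, error floor 1e-4) whose rate
comes from all *other* types at that site; per-type p-values are
BH-adjusted. A site is somatic when at least one and at most two types
pass (more passing types suggests germline or artifact), and the pooled
alternate fraction outside the passing types stays below 0.05; sites with
alternate fraction at or above 0.2 in three or more types are labelled
germline-like. RNA-specific artifacts are handled only through these
screens; site blacklists are an extension point, not implemented.

Per-cell burden counts, for each cell, the somatic sites where the cell
has at least one alternate read — directly checkable against planted
carrier lists, which is why carrier status is read-based rather than
genotype-likelihood-based. `compare_celltype_burden()` fits per-cell
burden on cell type with per-cell log(1 + covered sites) as the coverage
adjustment. The often-quoted alternative, "number of cells per type", is
constant within a type and therefore perfectly collinear with the
cell-type factor in a per-cell model; it is available as an offset variant
instead. Pairwise contrasts default to likelihood-ratio tests obtained by
merging the two types and refitting at the full-model dispersion: unlike
Wald contrasts, these remain well behaved when a type has zero observed
burden (a common outcome when clones are confined to one type).
`cluster_burden()` summarises burden by externally supplied cluster labels
and reports each cluster's condition composition.

## Signatures and gene sets

`context_spectrum()` maps SNVs onto the 96 pyrimidine-centred
trinucleotide channels, reverse-complementing purine-reference sites; the
192-to-96 collapse is verified exhaustively in the suite. Refitting is
non-negative least squares against a catalog whose rows sum to one —
deterministic, with the spectrum normalised to unit mass before solving
(active-set NNLS iteration behaviour is scale-sensitive) and weights
rescaled afterwards. NNLS is a declared substitution for likelihood-based
refitting: it has a closed acceptance surface (exact recovery of noiseless
mixtures, zero residual inside the catalog's cone, scale-invariant
fractions) at the cost of ignoring count noise. The catalog is always an
input: the package ships a small synthetic three-signature catalog (a
CpG-C>T-heavy signature, a T>C-heavy mismatch-repair-like signature
standing in for SBS26, and a flat signature) and a reader for COSMIC-layout
TSVs; the synthetic catalog is generated, not COSMIC data.
`compare_condition_fractions()` refits per condition with a seeded
bootstrap over SNVs, flagging conditions with fewer than 50 SNVs.

`geneset_burden_test()` is a weighted permutation test: the observed SNV
count in a set is compared against draws that reassign the same number of
SNVs to genes with probability proportional to gene weights (default:
covered panel length, since longer targets accrue more SNVs under any
uniform-rate null). Empirical p-values use the (1 + exceedances)/(n + 1)
construction, so they are never zero and are uniform under the null;
BH across sets.

## Pipeline, formats, sizes

`run_pipeline()` chains simulate, call, burden, single-cell, signature and
gene-set stages, writes every intermediate as plain text (FASTA, BED,
GFF-like gene-model TSV, VCF with TRUE_VAF/ORIGIN or
DP/AD/VAF/CALLERS/CLASS/REGION INFO keys, TSV tables) and finishes with a
JSON manifest of md5 checksums and row counts; identical configuration and
seed reproduce identical checksums. Configuration round-trips through
YAML with unknown keys rejected. A thin command-line wrapper over these
functions ships in `inst/cli/mosaic-burden.R`.

The replicated analyses in the tests and the acceptance script run at
deliberately chosen desk scales: 1e5 null sites for caller calibration,
1000 planted sites for power, 300/1000 replicates for GLM coverage and
type-I at n = 30, 100 cohort replicates at 9 sALS / 4 fALS / 6 controls on
a three-gene panel (~1500 sites per sample), 20 single-cell replicates
with six cortical cell types and ~220 cells. These sizes give Monte-Carlo
error comfortably below the margins being asserted while keeping the whole
suite repeatable in minutes.

## Known limitations

Indels are annotated context only, never called. Alignment, UMAP,
clustering and cell-type annotation are out of scope; labels are taken as
given. The error model is global per sample (no per-site or strand-specific
rates), the germline screens are heuristics rather than population-database
lookups, and signature refitting ignores sampling noise in the spectrum.
The synthetic generator's clean error model means the reported
precision/recall figures characterise the method under its stated
assumptions, not under every failure mode of real libraries.
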
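---
title: "Detecting the telomere position effect in aging RNA-seq cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the telomere position effect in aging RNA-seq cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subtelomeR)
```

## The question and the statistic

Telomeres repress nearby genes through chromatin looping; as they shorten
with age the looping is lost and subtelomeric genes can become
derepressed. If this happens genome-wide in aging tissue, genes whose
expression *increases* with age should be over-represented, relative to
genes that decrease, specifically near chromosome ends.

`subtelomeR` operationalizes this as a positional contingency analysis.
Genes are assigned to non-overlapping 1 Mb bins of distance between their
transcription start site and the nearest end of their chromosome; both
arms of every chromosome contribute, and the per-bin counts pool all arms
genome-wide. For each bin the package forms the 2×2 table of age-related
differentially expressed genes (DEGs) split by direction (up/down) and
position (in the bin / elsewhere), and reports

$$\mathrm{OR}(\text{bin}) =
  \frac{\text{up}_{\text{in}} \times \text{down}_{\text{out}}}
       {\text{up}_{\text{out}} \times \text{down}_{\text{in}}},$$

a two-tailed Fisher exact p-value, and a 95% Woolf confidence interval.
An excess of upregulation near telomeres appears as OR > 1 in the first
one or two bins. Because any positional artifact (gene density, GC,
mappability) could in principle mimic this, the identical computation is
repeated with bins anchored at **centromeres**; a telomere-specific
effect must leave that control profile null.

## The differential-expression stage

DEGs are identified from raw counts by:

* **Low-count filter.** Genes with mean raw count strictly below 1 across
  all samples are removed; a gene at exactly 1 is retained.
* **TMM normalization.** Between-sample scaling factors by the trimmed
  mean of M-values (30% trim on log-ratios, 5% on absolute intensity,
  precision-weighted, rescaled to geometric mean 1), computed by edgeR,
  with expression expressed as counts per million on the effective
  library size.
* **Per-gene linear model.** OLS of `log2(CPM + 1)` on age (years) with
  sex — and, in pooled multi-tissue mode, tissue — as fixed covariates.
  The p-value is the two-tailed t-test on the age coefficient. The fit is
  vectorized: one QR decomposition of the shared design serves all genes.
* **Bonferroni calling.** `p_adj = min(1, m · p_raw)` over the `m` tested
  genes; a DEG is `up`/`down` by the sign of its age coefficient when
  `p_adj < 0.001`.

Two modelling choices were genuinely open and are worth recording. First,
a repeated-measures cohort (multiple tissues per subject) is properly fit
with a subject-level random effect; we instead provide the fixed-effects
per-gene regression, the standard model for a single-tissue analysis,
and treat repeated subjects as independent in the pooled mode with a
documented caveat. The downstream positional statistic consumes only the
per-gene direction and adjusted p-value, so the enrichment machinery is
unaffected by which fitter produced them, and a mixed-model fitter can be
substituted upstream without touching anything else. Second, the
expression transform feeding the model and the gene–age correlations is
not uniquely determined by convention; we use `log2(CPM + 1)`, the most
common reading of TMM-normalized count analysis, and expose the
correlation on whatever values the caller passes.

Multiple-testing families: the Bonferroni `m` is the number of genes
tested within the analysis at hand (one tissue, or the pooled fit) —
never pooled across separate analyses. Across bins, per-bin Fisher
p-values are reported raw, matching how such profiles are usually read;
an optional Bonferroni-across-bins flag exists but is off by default.

## Geometry conventions

* Coordinates are 1-based inclusive internally; BED and BEDPE inputs are
  converted on read (rtracklayer). A gene starting at base 1 has distance
  0 to the p-terminus; the q-side distance is `length − position`.
* The representative gene coordinate is the **TSS** (start on `+`, end on
  `−`, start when unknown): position effects act on promoters, and a
  point coordinate keeps the binning a partition. The midpoint is
  available via `coordinate = "midpoint"`.
* Bin 1 covers distances `[0, 1 Mb)` — half-open, so a gene at exactly
  1 Mb belongs to bin 2.
* The chromosome universe defaults to protein-coding genes on autosomes
  1–22 plus X; X is treated like an autosome (no special handling of
  pseudo-autosomal regions), and both filters are options of
  `filter_genes()`.
* Hi-C loop anchors are represented by their interval **midpoint** (loop
  calls are resolution-sized bins, so the midpoint is robust to
  resolution; an edge-based alternative is a flag). Each anchor's
  distance is to the nearest end of its own chromosome; `d_near`/`d_far`
  order the two anchors, a loop is *telomeric* when `d_near < 1 Mb`
  (strict, mirroring bin 1) and *contained* when additionally
  `d_far ≤ 2 Mb`. Loops whose anchors sit nearer opposite ends are
  classified by the nearer anchor and flagged `opposite_arms` for audit;
  inter-chromosomal records are skipped with a count, not an error.

## Numerical choices

* **Fisher two-tailed definition.** The point-probability rule: sum the
  hypergeometric probabilities of all tables with the observed margins
  whose point probability is ≤ that of the observed table, with a 1e-7
  relative tolerance guarding against floating-point ties. This is the
  definition used by mainstream statistics software, and the test suite
  checks it against full enumeration on every 2×2 table with N ≤ 40.
* **Confidence intervals.** The Woolf logit interval
  `exp(log OR ± z·√(1/a + 1/b + 1/c + 1/d))`, with 0.5 added to every
  cell when any cell is zero (Haldane–Anscombe). The method behind the
  original figures' error bars is not documented; Woolf was chosen for
  its closed form and testability. The point estimate is always the raw
  cross-product ratio, uncorrected.
* **Degenerate tables.** OR is `Inf` when only the denominator vanishes
  and `NaN` when both products vanish (e.g. a single-bin genome with no
  "elsewhere"); empty tables get p = 1.
* **Rank-sum test.** Exact by complete enumeration of labellings when the
  pooled sample is ≤ 12 (midranks under ties; two-sided via the
  symmetric deviation of the rank sum from its null mean), otherwise the
  normal approximation with the midrank tie correction. Fully tied
  inputs return p = 1.
* **Degenerate fits.** Constant age is an error; a constant-expression
  gene is flagged and reported as `beta = 0`, `p = 1`.
* **PPI conventions.** Edges are undirected and canonicalized; self-loops
  and duplicates are dropped with counts. A score above 1 anywhere in the
  file implies the 0–1000 STRING scale, and a unit-scale threshold is
  mapped onto it (0.9 → 900), boundary inclusive. DEGs absent from the
  interaction universe are **excluded** from degree comparisons by
  default (they are not proteins "in the subnetwork"); `absent = "zero"`
  gives the degree-0 convention. Gene-to-protein identifiers are mapped
  through a user-supplied two-column table, never hard-coded.

## What the synthetic generator emulates

`synthetic_truth()` fixes the planted parameters; all generators derive
their random streams deterministically from its seed, so identical truth
objects give byte-identical data.

| parameter | default | meaning |
|---|---|---|
| `theta` | 1 | up:down odds among true DEGs in bins 1–2, relative to elsewhere (odds 1) |
| `deg_fraction` | 0.25 | fraction of genes with a true age effect — the order of magnitude of a large multi-tissue cohort (a few thousand DEGs among ~20k protein-coding genes) |
| `beta_mean`, `beta_sd` | 0.02, 0.005 | absolute per-year log2 effect of true DEGs; 0.02/yr ≈ 1.2 log2 units across a 20–79-year cohort, detectable but not trivial at 200 samples |
| `dispersion` | 0.1 | negative-binomial dispersion, constant across genes (moderate bulk RNA-seq overdispersion) |
| `loop_containment` | 0.863 | probability a telomeric loop's far anchor stays within 2 Mb |

Ages are uniform on [20, 79] — the cohort range of the motivating data —
with balanced sexes and one sample per subject; per-sample sequencing
depth varies uniformly by ±30% so TMM has real work to do, and a tenth of
genes carry a sex effect so the covariate is exercised. The planted bias
acts on the *direction mix* of DEGs near chromosome ends, not on DEG
density, which isolates exactly the per-bin odds-ratio statistic: the
population OR of bins 1–2 equals θ by construction. One consequence worth
knowing when reading profiles: because "elsewhere" includes the enriched
first bins, outer bins have a population OR slightly below 1 when θ > 1
(of the order of 0.92 at θ = 4 with default geometry), which their CIs
comfortably absorb.

Loops place one 10 kb anchor uniformly in the first 1 Mb of a random
chromosome arm and the other within 2 Mb with probability
`loop_containment`, otherwise uniformly in (2, 11] Mb — the long-range
regime. The PPI generator is a fitness (Chung–Lu-type) random graph whose
expected degree is multiplied by a chosen ratio for down-labelled genes,
with edge scores uniform on [0.9, 1].

What the generator deliberately does **not** emulate: the cross-tissue
correlation structure of real multi-tissue biobank cohorts, realistic
library-size or gene-size
distributions, gene-density gradients along chromosomes, linkage between
the expression and loop layers, or per-gene dispersion heterogeneity
(available as an option). Passing recovery tests therefore demonstrates
that the statistics measure what they claim on data satisfying the
model's assumptions — not that real subtelomeric enrichment of a given
size would survive real-data confounders.

## Problem sizes and scope of validation

The test suite validates parameter recovery at 5,000 genes × 200 samples
on four 60 Mb chromosomes (so every pooled bin holds ~160 genes), with
20 null replicates for calibration (the fraction of per-bin Fisher
p-values below 0.05 must lie in [0.03, 0.07], and the Bonferroni caller's
false-call rate at most 0.1% of genes), 50 planted replicates at θ = 4
(the bin-1 CI must cover 4 in ≥ 90% of replicates, outer bins and the
centromere control must cover 1), loop-containment recovery at n = 5,000
within ±1.5 percentage points, and 100 PPI replicates at a 3-fold degree
ratio (rejection at p < 0.01 in ≥ 90%; at ratio 1 the p-values must be
uniform). Fisher p-values are checked against full hypergeometric
enumeration on all tables with N ≤ 40, TMM factors against a direct
evaluation of the trimmed weighted-mean formula, and rank-sum and OLS
results against enumeration and closed-form oracles. Real Hi-C loop lists
are not redistributable here, so the containment analysis is validated on
synthetic loop sets generated at the containment probabilities the
analysis is expected to recover, pushed through the same BEDPE
write/read/classify path as real data would be.

## Pipeline and reproducibility

`run_pipeline()` orchestrates the stages (`simulate`, `deg`, `enrich`,
`network`, `hic`, or `all`) from a nested configuration list or YAML
file, with analysis defaults mirroring the package constants (1 Mb bins,
2 Mb window, alpha 0.001, score 0.9). Every run writes a JSON manifest
with the seed, input checksums, per-stage filter counts and timings;
outputs are pure functions of (inputs, config, seed), and two runs with
identical configuration differ only in manifest timestamps. The package's
functions are the primary interface; `inst/scripts/tpe-pipeline.R` is a
thin command-line wrapper for shell use.

## Known limitations

* The fixed-effects pooled mode understates uncertainty when subjects
  contribute many samples; use per-tissue fits or an external
  mixed-model fitter when that matters.
* Bonferroni is deliberately conservative; the DEG universe, not the
  method, is the main driver of the positional statistic's power.
* Distances ignore assembly gaps and acrocentric short arms: on real
  assemblies, "distance to the chromosome end" is a proxy for distance
  to the telomere repeat, and unplaced or patch contigs are skipped with
  a warning rather than resolved.
* The centromere control inherits the quality of the centromere
  annotation supplied in the chromosome map.
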
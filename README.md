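# subtelomeR

Telomeres shorten with age in most human tissues, and when they are still
long they loop back onto the chromosome and contact genes megabases away,
repressing them; as telomeres shorten this looping is lost and subtelomeric
genes can become derepressed (the *telomere position effect*, TPE).
`subtelomeR` provides an end-to-end, testable implementation of the
positional analysis that detects this effect in bulk RNA-seq cohorts:

1. **Age-related DEG calling** — low-count filtering (mean raw count < 1
   removed), TMM normalization to CPM, per-gene OLS of
   `log2(CPM + 1)` on age with sex (and optionally tissue) as covariates,
   and Bonferroni-corrected calls at `p_adj < 0.001`.
2. **Positional enrichment** — genes binned by distance of their TSS to the
   nearest chromosome end in 1 Mb non-overlapping windows; for each bin the
   odds ratio

   ```
   OR(bin) = (up DEGs in bin × down DEGs elsewhere) /
             (up DEGs elsewhere × down DEGs in bin)
   ```

   with a two-tailed Fisher exact test and a 95% Woolf confidence interval,
   plus the identical computation anchored at **centromeres** as a
   specificity control.
3. **Gene–age correlations and PPI degrees** — Pearson correlation of
   expression with age, and Wilcoxon rank-sum comparisons of node degrees
   in the DEG-induced subnetwork of a scored protein–protein interaction
   network (score ≥ 0.9).
4. **Hi-C loop classification** — BEDPE loop calls classified by anchor
   distance to chromosome ends: a loop is *telomeric* if one anchor
   midpoint lies within the first 1 Mb, *contained* if the far anchor stays
   within the 2 Mb subtelomeric window, with a long-range report up to
   11 Mb.
5. **Synthetic data** — deterministic generators for annotations, count
   matrices with a planted subtelomeric up/down bias of known odds ratio
   θ, loop sets with known containment probability, and PPI networks with
   group-dependent connectivity, so every stage can be validated against
   ground truth without downloads.

## Worked example

Simulate a cohort with a 4-fold planted excess of upregulated DEGs in the
first two 1 Mb bins, then run the full analysis:

```r
library(subtelomeR)

truth <- synthetic_truth(theta = 4, seed = 42)
sim   <- simulate_genome(n_chrom = 4, chrom_length = 6e7, n_genes = 5000,
                         truth = truth)
expr  <- simulate_expression(sim$genes, sim$chrom_map, n_samples = 200,
                             truth = truth)

fit <- fit_age_degs(expr$counts, expr$meta)
fit
#> Age-related differential expression fit
#>   genes: 5000 tested (5000 before low-count filter), samples: 200
#>   model: log2(CPM + 1) ~ age + sex
#>   DEGs at Bonferroni p < 0.001: 1190 (599 up, 591 down)

bins <- assign_bins(sim$genes, sim$chrom_map, bin_width = 1e6)
prof <- enrichment_profile(fit$table, bins, n_bins = 10)
prof[1:4, ]
#>  bin_index up_in down_in up_out down_out odds_ratio ci_low ci_high        p
#>          1    38       8    561      583      4.940  2.280  10.700 6.42e-06
#>          2    35      10    564      581      3.610  1.770   7.350 1.92e-04
#>          3    23      24    576      567      0.943  0.526   1.690 8.82e-01
#>          4    18      34    581      557      0.508  0.283   0.909 2.30e-02
```

Bins 1 and 2 recover the planted OR of 4 with small Fisher p-values while
outer bins hover around 1 (the mild deficit in outer bins is expected:
"elsewhere" includes the enriched first bins). The centromere control on
the same DEGs is null, and simulated telomere-anchored loops recover their
containment probability:

```r
summary(centromere_control(fit$table, sim$genes, sim$chrom_map))
#> Anchor: centromere; 0 of 10 bins with Fisher p < 0.05

loops <- simulate_loops(sim$chrom_map, 2000, truth)
cls   <- classify_loops(loops, sim$chrom_map)
subtelomeric_fraction(cls)
#> [1] 86.9
```

`plot(prof)` draws the per-bin odds ratios with CI whiskers on a log
scale. `run_pipeline("all", outdir = "tpe_run", seed = 1)` executes every
stage behind a single call and writes TSV outputs plus a JSON manifest; a
thin command-line wrapper lives in `inst/scripts/tpe-pipeline.R`.

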
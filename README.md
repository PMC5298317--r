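# methdriver

Integrative analysis of DNA methylation, gene expression, copy number and
protein–protein interactions in paired tumor/normal cancer cohorts.

## What it does, and for whom

After the usual differential screens, a paired tumor/normal cohort still
leaves thousands of genes that are both differentially methylated and
differentially expressed. `methdriver` is for epigenomics and regulatory
genomics analysts who want to rank those genes by a mechanistic criterion:
can a gene's *large* methylation change be connected, through a short chain
of high-confidence signed protein interactions whose activation/inhibition
labels are consistent with the observed expression changes, to a
dysregulated cancer driver gene?

The pipeline has four statistical/algorithmic cores:

1. **Gene-level summarization.** Per-CpG delta-beta values (percent) are
   collapsed to one representative change per gene: SNP-overlapping probes
   (MAF > 0.05) removed, the "general trend" decided by the majority of
   significant probes (FDR < 0.1), and the largest significant
   trend-concordant change taken as the gene's representative.
2. **A Cauchy model of pooled changes.** Pooled representative changes are
   heavy-tailed; `fit_cauchy()` estimates the location x₀ as the truncated
   mean of the middle 24% of the order statistics and the scale γ as the
   unique root of

   ∑ᵢ γ² / (γ² + (xᵢ − x₀)²) − n/2 = 0.

   The *large methylation change* threshold is x₀ + 2γ. At the published
   pooled estimates (x₀ = 16.8, γ = 7.77) the formula gives 32.34; the
   pipeline's default operating constant is 32.2, with a 15% baseline
   separating "normal" changes.
3. **Sign-consistent breadth-first path search.** From every dysregulated
   driver (upregulated oncogene / downregulated suppressor,
   |log2FC| ≥ 1, FDR < 0.1) a BFS expands up to 7 steps through
   significantly differentially expressed genes, crossing an edge only if
   its sign is consistent (activation: same expression direction;
   inhibition: opposite). Paths end at *methylation-driven* genes
   (change above threshold, significant, sign-opposed to an at-least
   twofold expression change); all equally short paths per driver–terminal
   pair are kept, and distance 0 means the driver itself is
   methylation-driven.
4. **Nulls and confounders.** A seeded randomization test measures how
   often randomly chosen altered genes reach drivers within 3 steps, and a
   segmental-mean ±2 copy-number filter flags genes whose expression change
   is better explained by copy number (mixed-direction aberrations are
   called `not_important`).

A fully synthetic cohort generator (`simulate_dataset()`) emits every input
table with ground-truth manifests — Cauchy-distributed methylation changes,
inverse methylation–expression coupling, and interaction networks with
sign-consistent cascades planted at known distances — so the entire pipeline
is testable end to end without any external data.

See `vignettes/methylation-driven-paths.Rmd` for the models, parameter
semantics and design decisions.

## Worked example

```r
library(methdriver)

set.seed(10)
cfg <- simulation_config(
  n_genes = 500, background_edge_count = 150, n_drivers = 3,
  planted_cascades = list(
    list(driver = "DRV01", distance = 0, signs = character()),
    list(driver = "DRV02", distance = 2, signs = c("activation", "inhibition")),
    list(driver = "DRV03", distance = 4, signs = rep("inhibition", 4))))
sim <- simulate_dataset(cfg, seed = 99)

res <- meth_driver_analysis(sim$cpg, sim$expression, sim$edges, cfg$drivers,
                            dataset = "synthetic")
res
#> Methylation-driven path analysis: synthetic
#>   thresholds: large > 32.2%, baseline > 15%
#>   399 genes with a representative methylation change
#>   class counts: 5 large, 0 normal
#>   3 of 3 catalog genes dysregulated (driver genes)
#>   3 methylation-driven paths to 3 distinct genes
#> Per-class distance summary:
#>    dataset meth_class n_class_genes n_with_path n_close close_proportion avg_distance
#>  synthetic      large             5           3       2        0.6666667            1
#>  synthetic     normal             0           0       0        0.0000000           NA

res$paths[, c("driver", "terminal", "distance", "nodes")]
#>   driver terminal distance                        nodes
#> 1  DRV01    DRV01        0                        DRV01
#> 2  DRV02     C02T        2             DRV02_C02M1_C02T
#> 3  DRV03     C03T        4 DRV03_C03M1_C03M2_C03M3_C03T
```

The three planted cascades are recovered at exactly their planted
distances; the two terminals within 3 steps count as "close" with mean
minimal distance 1 (the distance-0 driver and the distance-2 terminal),
while the distance-4 terminal is reached but not close.

Fitting the heavy-tailed model at the published parameters:

```r
set.seed(1)
fit <- fit_cauchy(rcauchy(1e5, 16.8, 7.77))
fit
#> Cauchy location/scale fit
#>   n = 100000 observations, middle fraction = 0.24
#>   center    : 16.8
#>   scale     : 7.713
#>   threshold : 32.22  (center + 2 * scale)
```

Averaging the shipped six-cohort path summaries (close proportions and
average driver distances per methylation class, distance average excluding
the thyroid cohort, whose distances move against the trend):

```r
rows <- read.delim(system.file("extdata", "tcga_cohort_path_summary.tsv",
                               package = "methdriver"))
averages_summary(rows, exclude_from_distance = "THCA")$class_summary
#>   meth_class mean_close_proportion_pct mean_avg_distance
#> 1      large                      7.83              1.95
#> 2     normal                      3.00              2.09
```

Genes with large methylation changes reach driver genes at more than twice
the proportion of normal-change genes (7.83% vs 3.00%) and in slightly
fewer steps (1.95 vs 2.09).

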
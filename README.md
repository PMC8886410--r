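# growthlaw

Growth-law decomposition of gene expression and proteome allocation.

When steady-state cultures are profiled across growth conditions — for
example a fission yeast strain grown in continuous culture on eight
different nitrogen sources, each condition setting its own growth rate —
every gene's expression mixes two regulatory layers: a component that
scales linearly with the growth rate itself, and a nutrient-specific
component that depends only on the medium. `growthlaw` separates the two.
It is aimed at quantitative microbiologists and systems biologists with
bulk RNA-seq counts, label-free proteomics (iBAQ) intensities, and a
measured growth rate per sample.

## The model

For each gene *i* with expression *y* (normalised counts or proteome mass
fractions) across samples with growth rates μ, the package fits the
growth law

  y = a·μ + b

by the **repeated-median linear model** (RMLM, Siegel's estimator): from
each observation a line is drawn to every other observation, the median
slope and intercept are taken per point, and the medians of those medians
give (a, b). The estimator has a ~50% breakdown point, so genes that are
strongly induced or repressed in a few conditions still get an unbiased
growth trend.

Because a and b scale with a gene's absolute abundance, growth dependence
is compared through the scale-free fold change

  FC = (y(μ_max) − y(0)) / y(μ_max/2) = μ_max / (μ_max/2 + b/a),

with μ_max = 0.3 h⁻¹: FC = 2 for a gene proportional to growth rate,
0 for a flat gene, negative for repressed genes. Genes are assigned to
**sectors** by the significance of their fit (F-test on the RMLM
R-squared, tail-based fdr < 0.1): **R** (positively growth-correlated),
**P** (negatively), **Q** (neither).

Around that core the package provides:

- iBAQ mass fractions φ and number fractions ψ, DESeq2-style size
  factors and normalised counts, detection filters, z-scores;
- attenuation-corrected protein–mRNA correlations
  (R = ρ̂ / √(r_P·r_M), with reliabilities r from inter-replicate
  correlations) and residual protein-to-mRNA ratios;
- growth-rate-removed differential expression: per-gene normalization
  built from RMLM-predicted counts, a synthetic reference condition
  (per-replicate medians of the predictions), and an NB Wald test so
  that fold changes read "observed / predicted by the growth law";
- hierarchical clustering (Ward.D2), PCA with per-gene PC1 variance
  fractions, barcode deviation lengths, Fisher and preranked gene-set
  enrichment with local-fdr control;
- a synthetic-data generator that emulates the whole study design
  (8 conditions × 3 replicates, growth rates 0.05–0.28 h⁻¹, NB counts,
  lognormal iBAQ intensities with missingness) with known ground truth,
  so every stage is testable without any download.

## Worked example

```r
library(growthlaw)

bench <- simulate_benchmark(n_genes = 1000, n_proteins = 400, seed = 42)
res   <- run_growth_analysis(bench, seed = 42)
res
#> Growth-law analysis of 1000 genes, 24 samples
#> Stages run: normalize, fit_growth_laws, assign_sectors, structure,
#>             crossomics, growth_removed_de, enrichment
#> Sectors: R = 281  P = 247  Q = 472
#> DE genes: 170 at p_adj < 0.01
#> Mean corrected protein-mRNA correlation: 0.812
```

The benchmark plants 30/25/45% R/P/Q genes; the pipeline recovers 281 R
and 247 P calls out of 1000 genes at tail-fdr < 0.1, finds 170 genes with
nutrient-specific (growth-removed) differential expression, and the
Spearman-corrected protein–mRNA correlation recovers the planted latent
correlation of ~0.8 from raw correlations that replicate noise attenuates.

The growth law of a whole sector is the fit of its summed mass fraction:

```r
r_sum <- gene_set_sums(res$crossomics$mass_fractions,
                       res$fits$gene_id[res$fits$sector == "R"])
fit <- rmlm(y ~ mu, data.frame(mu = bench$design$mu, y = r_sum))
summary(fit)
#> Repeated-median linear model (N = 24 points)
#>
#> Coefficients:
#> (Intercept)       slope
#>     0.07007     1.08900
#>
#> R-squared: 0.968   SSR_norm: 0.0008986   p-value: < 2.2e-16
#> FC (mu_max = 0.3):   1.4
```

The R-sector's share of proteome mass rises from ~7% of baseline plus
1.09 per unit growth rate — i.e. from ~12% at μ = 0.05 h⁻¹ to ~38% at
μ = 0.28 h⁻¹ in this simulation — with FC = 1.4. Bootstrap confidence
bands come from `bootstrap_growth_law(fit)` (or `confint(fit)`).

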
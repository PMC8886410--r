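---
title: "Separating growth-rate-dependent from nutrient-specific gene expression"
author: "growthlaw"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating growth-rate-dependent from nutrient-specific gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthlaw)
```

## The problem and the model

Steady-state cultures grown on different media settle at different growth
rates, and a large share of gene expression tracks that rate rather than
the specific nutrient. Any comparison of conditions therefore confounds
two layers of regulation: a global, growth-rate-coupled component and a
condition-specific one. `growthlaw` models the first layer explicitly so
the second can be isolated.

The growth law of gene $i$ is the straight line $y_i = a_i\mu + b_i$
relating its relative expression $y$ (normalised counts for RNA, mass
fractions for protein) to the culture growth rate $\mu$ (h$^{-1}$). The
model's assumptions are deliberately minimal: linearity of *relative*
abundance in $\mu$ over the observed range, independent replicates, and
the possibility that some conditions deviate arbitrarily far from the
line (that is the second layer, treated as outliers at this stage).

### Robust fitting

Condition-specific induction makes least squares unusable: three samples
of twenty-four sitting 4-fold above the line drag an OLS fit far off.
`rmlm()` fits the line by the repeated-median estimator: pairwise slopes
$s_{ij} = (y_j-y_i)/(\mu_j-\mu_i)$ and intercepts
$t_{ij} = (\mu_j y_i - \mu_i y_j)/(\mu_j-\mu_i)$, a median over $j$ per
point, then the median over points. The estimator tolerates up to about
half the points being arbitrary outliers. Numerical conventions: pairs
with $|\Delta\mu| < 10^{-12}$ are excluded from a point's medians (their
slope is undefined; replicate growth rates are distinct in practice);
even-length medians use the midpoint, making the fit deterministic.

### The FC statistic and sectors

Slope and intercept scale with abundance, so genes are compared through
$FC = \mu_{max} / (\mu_{max}/2 + b/a)$ with $\mu_{max} = 0.3$ h$^{-1}$,
the rise of the line over $[0,\mu_{max}]$ divided by its midpoint value.
$FC$ is invariant to rescaling $y$, equals 2 for a purely proportional
gene and 0 for a flat one; when the line crosses zero exactly at the
midpoint the statistic is undefined and reported as `NA`.

Significance comes from $R^2 = 1 - \sum r^2 / \sum (y-\bar y)^2$ about
the mean, mapped through the $F(1, N-2)$ distribution at
$F = R^2/(1-R^2)\,(N-2)$. A robust fit can have $R^2 < 0$ (it does not
minimise the squared residuals); such fits get $p = 1$. This F-mapping is
the closest well-defined analogue of an ordinary regression summary for a
robust line and is a deliberate design choice, not an exact sampling
distribution for the repeated-median estimator; the fdr machinery
downstream absorbs the approximation, and the null simulations in the
test suite confirm calibration at the thresholds used.

Sector assignment uses a tail-based fdr over the per-gene p-values
(`tail_fdr()`): the null proportion $\eta_0$ is estimated by censoring
above a grid of cutoffs in the upper half of the p distribution (median
over the grid, capped at 1), $q(p) = \eta_0\,p/\mathrm{ECDF}(p)$ with a
step-up monotonicity pass — with $\eta_0 = 1$ this is exactly
Benjamini–Hochberg — and the local fdr is $\eta_0/\hat f(p)$ with
$\hat f$ the Grenander (least-concave-majorant) density estimate. Below
50 p-values the empirical null is unreliable and the function falls back
to BH with a warning. A gene is **R** if $q < 0.1$ and $a > 0$, **P** if
$q < 0.1$ and $a < 0$, otherwise **Q**; local fdr $< 0.1$ flags
confident calls. All thresholds are arguments.

### Cross-omics comparison

Protein and mRNA are compared on the common scale of number fractions
($\psi_P$ from iBAQ intensities, $\psi_M$ from length-corrected
normalised counts). Observed gene-wise correlations between the two
layers are attenuated by replicate noise, so each condition's raw
correlation $\hat\rho$ (geometric mean of the pairwise log$_2$
correlations between protein replicate $k_1$ and mRNA replicate $k_2$
with $k_1 \le k_2$ — six pairings; the nine-pairing variant is available
and estimates the same quantity) is corrected by the reliabilities:
$R = \hat\rho / \sqrt{r_P\, r_M}$, where $r$ is the geometric mean of
the three inter-replicate correlations of a layer. Negative pairwise
correlations abort the geometric mean with a clear error rather than
taking complex roots. The gene universe per condition is the
intersection of genes detected (positive) in all six samples of that
condition, and the universe size is reported — the choice of
intersection rule is ours and recorded here because reasonable
alternatives exist.

The protein-to-mRNA ratio depends strongly on expression level
(post-transcriptional amplification); `residual_ratio()` removes each
gene's median log$_2$ ratio so only across-sample variation remains.

### Growth-removed differential expression

To find nutrient-specific expression on top of the growth trend, each
gene's fitted line provides predicted normalised counts
$p_{ijk} = a_i\mu_{jk} + b_i$ and predicted raw counts
$q_{ijk} = p_{ijk} S_{jk}$ (size factors $S$ by median-of-ratios). A
synthetic reference condition takes, per replicate, the rounded median of
$q$ across conditions — a trend-free pseudo-condition. The NB Wald test
compares each condition against this reference with the *predicted*
counts as the per-gene, per-sample normalization bias (rescaled to
per-gene geometric mean 1), so the modelled quantity is observed /
predicted and a gene following its growth law exactly has
$\log_2 F = 0$ everywhere. The observed/predicted ratio itself (the
`norm_factors` matrix, geometric mean 1 per gene) is exposed and is the
natural residual-expression summary. Genes with any non-positive
prediction are excluded and listed; zero counts are given half-count
pseudo-observations in the ratio; all-zero genes get $p = 1$.

The default test engine is intentionally compact: per-group means are
ratio estimators on the normalised scale; gene-wise dispersions are
pooled method-of-moments across the real condition groups, shrunk
towards a mean–dispersion trend ($\alpha_0 + \alpha_1/\bar m$, clamped
to the central 90% of the gene-wise estimates because the regression is
ill-conditioned when expression levels are homogeneous), with
dispersion outliers far above the trend kept unshrunk so noisy genes do
not receive optimistic variances. Two variance choices matter and are
worth stating plainly:

* the synthetic reference is a deterministic construction (medians of
  model predictions), so contrast variances charge only the condition
  side — treating the reference as a sampled group (as the
  `engine = "deseq2"` route does) systematically overstates the
  uncertainty of every contrast;
* the prediction itself is uncertain: the slope error of the fitted line
  propagates into a contrast as
  $\mathrm{var} \approx 2\,\hat\sigma^2 (\bar\mu_j - \tilde\mu)^2 /
  \sum(\mu-\bar\mu)^2 / p^2$ (MAD-based residual scale so condition
  effects do not inflate it; the factor 2 approximates the efficiency
  loss of the repeated-median slope; intercept error cancels because the
  reference sits at the median growth rate). Without this term,
  fit uncertainty masquerades as condition effects at the extreme growth
  rates for steeply sloped genes.

Fold changes are shrunk by a zero-centred normal prior (posterior mean
$\mathrm{lfc}\cdot\tau^2/(\tau^2+\mathrm{se}^2)$, $\tau$ fitted by
non-negative moment matching or supplied). DE calls use $p_{adj} < 0.01$
(BH within each contrast, mirroring per-comparison reporting) and
$|\log_2 F| > 0.5$ evaluated on the **raw** estimate by default: the
normal prior shrinks genuinely changed genes in proportion to their
standard error, which would make a fixed magnitude cutoff depend on
measurement precision rather than effect size. Both thresholds and the
raw/shrunk choice are arguments; shrunk values populate the signature
matrix used for clustering.

### Structure and enrichment

Clustering uses Euclidean distance with Ward.D2 linkage on row z-scores
(sample standard deviation, $n-1$); the cluster count is a user
parameter. PCA is a plain SVD of the z-score matrix with genes as
observations and no extra scaling; per-gene PC1 variance fractions are
$1 - \|z_i - \hat z_i\|^2/\|z_i\|^2$ with $\hat z_i$ the rank-1
reconstruction. Principal-component signs are arbitrary, so every
component is oriented to make its largest-magnitude sample score
positive — with that convention the condition-split labels
(`wfsp_classify()`, fraction threshold 0.5) are reproducible. PCA runs
on all samples rather than condition medians (either is defensible; we
use the finer-grained option and say so here). Barcode lengths
$(x - M)/M$ are clamped to $[-1, 2]$, with missing data imputed to zero
before the medians.

Fisher enrichment is the one-sided hypergeometric tail; collection-level
significance uses the same local-fdr machinery as sector assignment
(conventional cutoffs: 0.05 for broad collections, stricter for large
collections of small terms). Preranked GSEA uses the weighted
running-sum enrichment score on the signed statistic
$-\mathrm{sign}(a)\log_{10}p$ (zero p-values are mapped one decade
beyond the most extreme finite value, preserving order), a gene-label
permutation null, and NES = ES / mean |null ES| of the same sign. The
weight exponent defaults to 1 (classic weighted form; 0 gives the
unweighted KS statistic, invariant to monotone transforms). Adaptive
multilevel p-value refinement is out of scope; permutation p-values are
floored at $1/(n_{perm}+1)$.

## The synthetic benchmark

`simulate_benchmark()` generates the full input bundle with known ground
truth: a design of 8 conditions × 3 replicates with condition mean
growth rates evenly spread over 0.05–0.28 h$^{-1}$ and lognormal
replicate jitter (sd 0.02); genes split 30/25/45% into R/P/Q with target
|FC| drawn uniformly from 0.75–2 (|FC| ≤ 2 keeps planted abundances
positive across the range); midpoint relative abundances lognormal
(log-sd 1.2, normalised to sum to 1); 20% of genes carry condition
effects of |log$_2$| 0.5–2, half on a shared bimodal split of the
conditions and half in single conditions. RNA counts are NB
(dispersion 0.02) around library size × abundance × transcript-length
bias; protein intensities are lognormal (CV 0.3) around abundance ×
a per-gene amplification offset (log$_2$ sd 1.3) that fixes the latent
protein–mRNA correlation near 0.8. `dispersion = 0` and `noise_cv = 0`
are exact noiseless limits (counts equal rounded means), which the
round-trip tests rely on. One seed expands into fixed per-stage child
seeds (`seed*1000 + offset`) so partial reruns reproduce.

The noise defaults were chosen so that the emulated data show replicate
reliabilities in the ranges the corresponding laboratory data sets
exhibit (mRNA ≈ 0.975–0.998, protein ≈ 0.93–0.98) and a latent
cross-omics correlation near 0.8; they are arguments, not constants.

What the generator deliberately does **not** emulate: peptide-level MS
structure, read sequences and mapping artefacts, compositional coupling
between genes beyond the shared normalisation, batch effects, nonlinear
growth laws, and culture dynamics. Passing tests therefore demonstrate
that the algorithms recover the planted structure under the assumed
statistical model — not that the model captures every property of real
data.

## Problem sizes and runtime choices

The packaged tests exercise the estimator oracle on 100 random instances
(N ≤ 12), sector recovery on a 2,000-gene 8×3 data set, the Spearman
correction on 100 replicate simulations of 800 genes, DE calibration on
five pooled 300-gene simulations (the false-call criterion bounds a rate
whose expected count in a single draw is about one gene, so pooling five
draws measures it stably), bootstrap coverage on 200 data sets × 200
resamples, and the end-to-end benchmark at 5,000 genes / 2,000 proteins
run twice to confirm byte-identical reproducibility. These sizes keep
the default suite in the low minutes on one core while leaving every
statistical check adequately powered; all are plain arguments if larger
runs are wanted.

## Known limitations

* The F-based p-value for the robust fit is an analogy, not the exact
  distribution of the repeated-median statistic; calibration is
  empirical (verified by simulation at the thresholds used).
* Residual fold changes against predictions are ill-conditioned where a
  gene's predicted expression approaches zero; the propagated-slope
  variance term mitigates but does not remove this, and steeply repressed
  genes at extreme growth rates remain the least reliable calls.
* The empirical-null fdr machinery assumes a dense, mostly-null p-value
  distribution; with few tests it falls back to BH.
* Fractions are compositional: a sector's share can fall because another
  sector grows. The FC statistic inherits this relative-abundance
  reading, which is also its point.
* The growth law is linear by construction; saturating or segmented
  dependencies will load onto the condition-specific layer.
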
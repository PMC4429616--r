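---
title: "Detecting differential methylation-expression correlation: models and methods"
author: "dcgscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential methylation-expression correlation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcgscan)
```

## The problem

DNA methylation and gene expression are classically anti-correlated at
promoters and often positively correlated in gene bodies and distal
regions. Most tumor studies ask where methylation *levels* change; this
package asks a different question: for which genes does the *coupling*
between methylation and expression change between tumor and normal tissue?
Such genes — differentially correlated genes, DCGs — can have unchanged
average methylation and expression and still signal a rewired regulatory
relationship.

The inputs are the standard artifacts of an array-era tumor/normal study:
a normalized log-expression matrix (genes x samples), a methylation matrix
(CpGs x samples, beta values), a CpG-to-gene annotation with positions and
closest-TSS coordinates, and a sample-group table. Cohorts are typically
very unbalanced (the package's reference shape is 8 normal vs 57 tumor
samples) and come in two array densities: 27K-style (one or two CpGs per
gene, analyzed through gene-averaged methylation) and 450K-style (many
CpGs per gene with meaningful TSS distances).

## The statistical core

**Scale.** Betas are mapped to M values, `M = log2(beta/(1-beta))`, and
quantile normalized before any correlation is computed. M values are
closer to Gaussian and variance-stable; all correlation machinery operates
on this scale. Normalization is joint across tumor and normal samples of a
dataset by default: normalizing the groups separately would imprint
group-specific distributional artifacts on exactly the quantity being
compared (a `joint = FALSE` flag exists for sensitivity analysis).

**Correlation and the Fisher transform.** Within each group we compute
Spearman (default) or Pearson correlation between methylation and
expression, per gene (gene-averaged methylation) and per CpG. Fisher's
`z = atanh(rho)` makes correlation estimates approximately normal with
variance `1/(n-3)`, so the difference of two independent correlations can
be tested with

`z_stat = (atanh(rho_tumor) - atanh(rho_normal)) / sqrt(1/(n_t - 3) + 1/(n_n - 3))`.

`|rho|` is clamped at 0.999999 before `atanh` so degenerate perfect
correlations stay finite. The classical `1.06/(n-3)` variance adjustment
for Spearman correlations is available as `spearman_var = TRUE`; the
default uses `1/(n-3)` for both methods.

**Gene-level combination (450K mode).** With many CpGs per gene, each CpG
yields two one-tailed p-values (correlation higher in tumor; lower in
tumor). Each direction's vector is pooled with the unweighted Stouffer
Z-score method, `Z = sum(qnorm(1 - p_i)) / sqrt(k)`. The gene's two-sided
p-value is `min(1, 2 * min(tails))` and the direction is the smaller
tail. This construction was chosen because it (a) controls FDR jointly
over both directional lists after a single BH pass, and (b) reduces
*exactly* to the single-correlation two-sided test when a gene has one
CpG, which keeps the 27K and 450K modes mutually consistent (a property
the test suite asserts). Bonferroni-adjusted p-values are emitted
alongside BH q-values.

**Independence diagnostic.** Stouffer pooling assumes the combined
p-values are independent; spatially autocorrelated CpG behavior within a
gene would inflate the gene-level Type I error. The package's Mantel
diagnostic tests, per gene and TSS-distance stratum (within 200 bp,
200-1000 bp, beyond 1000 bp), the association between pairwise genomic
distance and the dissimilarity of per-CpG correlation changes
`dz = z_tumor - z_normal`, with a label-permutation p-value
`(1 + #{r_perm >= r_obs}) / (1 + n_perm)` (exhaustive enumeration when a
gene-stratum has at most 6 CpGs). Whether such a diagnostic should pool
CpGs across genes within a stratum or run per gene is genuinely open; we
run it per gene — the Stouffer combination whose assumption is being
checked operates within genes — and expose `pooled = TRUE` for the other
reading.

**Genome-wide comparisons.** The global shift in signed correlations is a
paired Wilcoxon signed-rank test across genes, with the Hodges-Lehmann
pseudomedian (and 95% CI) as the location estimate. Absolute correlations
need more care: with 8 vs 57 samples the larger group's correlation
estimates are systematically less noisy, biasing `|rho|` comparisons. The
larger group is therefore subsampled *without replacement* to the smaller
group's size (shuffling "down" to equal n implies subsetting, not a
bootstrap), per-gene correlations recomputed, and the paired test run per
replicate; the reported p-value and estimate are the means over 1000
replicates. Averaging p-values is conservative and nonstandard as an
inference procedure, but it is retained deliberately as the defined
summary of this procedure; the replicate median is also reported. With
equal group sizes the machinery collapses, bit-identically, to a single
direct test. Subsample replicates reuse the dataset-level normalization
rather than re-normalizing per subsample: re-normalization would mix a
normalization artifact into the subsampling noise, and quantile
normalization over 57 vs 8 columns is stable enough that the difference is
negligible relative to correlation noise at n = 8.

**TSS-distance regression.** Pooled per-CpG Fisher-z correlations are
regressed on absolute TSS distance with a penalized regression spline per
group, smoothing parameter chosen by GCV. We use a cubic regression
spline basis with a second-derivative penalty (`bs = "cr"`); for a single
1-D covariate this is practically equivalent to a thin-plate basis and
cheaper. Defaults: `k = 20` basis functions and GCV with `gamma = 1.4` —
the standard inflation correcting GCV's known tendency to undersmooth;
without it, pure-noise inputs are fitted with several spurious degrees of
freedom. The reported `edf` excludes the intercept, so a flat
relationship reads as `edf ~ 1`. Basis adequacy is checked with a
differencing estimator: for residuals ordered by distance,
`mean(diff(r)^2) / 2` estimates the residual variance when no structure
remains, so the k-index (that estimate over the residual variance) is
near 1 for an adequate basis and drops below 1 when the basis is too
small; its p-value is the fraction of residual re-orderings with a
k-index at or below the observed one (2,000 shuffles in tests, 20,000 in
full runs). Note the k-index is the *halved mean squared difference* over
the variance — the raw variance ratio of first differences would sit near
2 under the null, not 1.

The 5-kb regional comparison contrasts promoter-proximal and distal CpGs:
a paired t-test on per-CpG `z_normal - z_tumor` in each region (the same
CpGs exist in both groups, so pairing is the natural reading), the
correlation ratio `z_normal / z_tumor` compared between regions by a
rank-sum test (CpGs with `|z_tumor| < 1e-8` are excluded from ratios),
and the fraction of CpGs whose correlation changes sign between groups,
per region. Fitting is pooled across genes; gene identity is not a
grouping factor — the target estimand is the marginal distance profile,
and the cohort sizes here give thousands of CpGs per distance window.

**Overlap and enrichment.** The preferential-overlap test asks whether
case-labeled gene segments overlap an annotation track more than expected
when case/control labels are permuted over the fixed segment set
(preserving the case count). The statistic is total base pairs of case
segments covered by the track (`stat = "bp"`; a segment-count variant is
a flag) and the one-sided p-value is `(1 + #{null >= obs}) / (1 + n_mc)`,
with at least 1000 Monte-Carlo samples in production. Interval arithmetic
is 0-based half-open (BED) throughout, converting from 1-based annotation
coordinates at the boundary. Replicate tracks are Stouffer-merged and BH
adjustment is applied within track batches (grouping tracks by origin).
Gene-set enrichment is an upper-tail hypergeometric test against a
user-supplied background, with the annotation intersected with that
background first.

## The synthetic cohort

Every stage is exercised on a seeded generator
(`simulation_config()` / `simulate_dataset()`) that emulates the study
design without any downloads:

* unequal groups (default 8 normal vs 57 tumor), 27K-style (1-2 CpGs per
  gene) or 450K-style (3-12 CpGs per gene) layouts;
* per gene, a latent unit-variance expression signal per group; per CpG,
  methylation drawn on the M scale as the bivariate-Gaussian partner of
  that signal with target correlation `rho(group, TSS distance)`, then
  mapped to betas. Correlation is induced on the M scale — the analysis
  scale — so beta-scale correlations are attenuated by the logistic
  transform, as with real arrays;
* the default distance profile is -0.4 within 2 kb of the TSS rising
  linearly to +0.15 at 5 kb and flat beyond: the qualitative
  promoter-negative / distal-positive shape of high-density arrays (a
  configuration default, not an empirical claim);
* a planted fraction (default 10%) of DCGs whose groups are moved apart
  by `dcg_delta` (default 0.8). The default split is symmetric
  (`+/- delta/2` around the baseline); a tumor-only shift is available
  but infeasible for large deltas near the TSS, where the baseline is
  already -0.4. Targets outside (-1, 1) raise a configuration error
  rather than being clamped;
* TSS distances are roughly exponential (mean 15 kb, clipped to the
  configured range) so promoters are well represented; CpG baselines
  `mu_M ~ U(-3, 3)` keep betas spread across realistic levels; genes are
  laid out 1 Mb apart, 250 per chromosome;
* one global seed drives all randomness: identical configs give
  bit-identical datasets.

What the generator deliberately does *not* model: batch effects, probe
cross-hybridization, copy-number confounding, non-Gaussian expression
noise, and within-gene CpG dependence beyond the shared expression driver
(under the null of zero correlation, CpGs are fully independent — which
is exactly the regime the Type I error checks need). Passing tests
therefore validate the statistical machinery, not robustness to array
artifacts; on real data the usual QC and batch adjustment must happen
upstream.

## Numerical choices and degenerate inputs

* Beta clamping for the M transform: `eps = 1e-6`; betas of exactly 0 or
  1 map to finite M values around +/-19.93.
* Quartiles in the robust CV (`100 * IQR / median`) use linear
  interpolation between order statistics (type 7), the mainstream
  numeric default; the CV is undefined (signaled) at median 0.
* Spearman ties get average ranks; constant vectors yield an undefined
  correlation and the record is excluded with a logged count.
* Wilcoxon tests are exact for n <= 25 without ties, otherwise the normal
  approximation with continuity correction; all-zero difference vectors
  return p = 1, estimate 0.
* One-tailed Fisher p-values that round to 0/1 in double precision are
  clamped into `[1e-300, 1 - 1e-16]` before Stouffer pooling.
* Multi-mapped probes contribute to every target gene's average, with a
  warning; genes with no usable CpGs are omitted with a logged count.
* The Monte-Carlo overlap permutation operates on a canonically ordered
  per-segment overlap vector, so results are invariant to segment input
  order and chromosome naming at a fixed seed.

## Problem sizes used in validation

The test suite validates error control on a 2000-gene null cohort
(5 CpGs/gene, 20 vs 20 samples) and recovery on a 2000-gene cohort with
10% planted DCGs (delta 0.8, 50 vs 50); the full-chain run uses 6000
genes at 8 vs 57 with 1000 subsampling replicates. These sizes give
stable Monte-Carlo estimates (e.g. binomial error on a 0.05 rejection
rate at 20,000 replicates is ~0.0015) while keeping a complete run on a
single CPU in minutes. The analysis drivers under `analysis/` use the
same cohort shape.

## Known limitations

* The subsampled absolute-correlation p-value is a mean of p-values; it
  is a defined summary, not a calibrated test statistic, and should be
  read comparatively.
* Stouffer pooling inherits sensitivity to whatever CpG dependence the
  Mantel diagnostic fails to flag; strongly dependent CpG stacks inflate
  gene-level significance.
* The GC-content style covariate comparisons are descriptive rank-sum
  tests; they do not correct the DCG calls for covariate-driven bias.
* GAM fits are pooled over genes; gene-level random effects are out of
  scope.
* Enrichment is generic hypergeometric against user-supplied gene sets;
  no ontology database clients are included.
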
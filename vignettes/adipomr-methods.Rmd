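---
title: "Methods and design notes for adipomr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for adipomr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`adipomr` chains four analyses: two-sample Mendelian randomization (MR) of
obesity on glycemic outcomes; mitochondrial (MT) expression quantification
from bulk adipose RNA-seq with bias-aware technical correction; cell-type
deconvolution of bulk profiles against a single-nucleus reference; and a
penalized linear model predicting the Matsuda insulin-sensitivity index.
This vignette records the models, their assumptions, the tunable
parameters, and the design decisions taken where more than one reasonable
choice existed.

## Two-sample Mendelian randomization

MR treats genetic variants as instruments: each must associate with the
exposure (relevance), be independent of confounders, and affect the
outcome only through the exposure (exclusion restriction). The package
assumes summary statistics arrive pre-harmonized per variant (effect
sizes aligned to the same effect allele); a harmonization step matching on
variant id and flipping mismatched alleles is the caller's responsibility
when combining external GWAS files.

* **Instrument selection** (`select_ivs`): keep variants with exposure
  p-value below `p_threshold` (default `5e-8`, the genome-wide
  convention) and greedily prune against the LD matrix at `r2_threshold`
  (default `0.01`). Pruning proceeds in ascending p order, ties broken by
  variant id, so output is invariant to input row order.
* **Confounder screen** (`exclude_confounded_ivs`): drop instruments whose
  association p-value with a named confounder falls below a threshold.
  The screening threshold defaults to the same genome-wide `5e-8`; no
  published convention exists, and the default keeps the screen on the
  same evidence scale as selection.
* **IVW** (`ivw_estimate`): weighted regression through the origin with
  weights `1/se_out^2`. The no-measurement-error convention applies on
  the exposure side, standard for two-sample designs with a large
  exposure GWAS. The SE uses a multiplicative random-effects model: it is
  inflated by `sqrt(Q/(n-1))` whenever the heterogeneity statistic
  exceeds its degrees of freedom, and never deflated.
* **MR-Egger** (`egger_regression`): free-intercept weighted regression
  after re-signing every variant so its exposure effect is positive (the
  slope is orientation-dependent without a convention; positive-exposure
  orientation is the field standard). The intercept p-value is the
  directional-pleiotropy test; p-values use a t reference with `n - 2`
  degrees of freedom, and the residual variance estimate is floored at 1.
* **MR-PRESSO style resampling** (`mr_presso`): the observed residual sum
  of squares uses leave-one-out IVW slopes (each variant judged against
  the fit from all others). The null is parametric: outcome effects are
  redrawn from `Normal(loo_slope_i * beta_exp_i, se_out_i)` `n_sim`
  times, the statistic recomputed (with leave-one-out slopes inside each
  draw), and the global p is the exceedance fraction. Outliers are
  variants whose observed squared residual exceeds their simulated null
  at `outlier_alpha/n` (Bonferroni). Defaults: `n_sim = 5000` with a hard
  floor of 1000 (granularity of the per-variant p must resolve the
  Bonferroni threshold); `outlier_alpha = 0.05`. The distortion test on
  the outlier-removed estimate is not implemented; corrected estimates
  and global p-values are what downstream reporting consumes.
* **Multiplicity**: causal-effect p-values (corrected estimate, Egger
  slope) are Bonferroni-adjusted over `n_tests` (default 3, matching a
  bidirectional design over three causal questions); heterogeneity and
  intercept p-values are reported unadjusted, since they guard
  assumptions rather than test effects.

Outcome effect sizes are treated as scale-agnostic: for a binary outcome
analyzed with a linear mixed model the estimates live on the
linear-probability scale, and the causal estimate inherits that scale.

## MT expression and technical correction

TPM is computed from counts and gene lengths; MT expression is the sum of
TPM over mitochondrially encoded genes (37 in the standard human
annotation; the flag column is caller-overridable). Because MT transcripts
can occupy a large share of a bulk library, alignment metrics computed
over all reads are mechanically confounded with MT expression — a high MT
fraction deflates every nuclear category's percentage through the
denominator. `rna_metrics_excluding_mt` therefore returns each nuclear
read-category fraction computed over nuclear (non-MT) reads, alongside
the biased all-reads versions and the MT read percentage itself. The
corrected MT phenotype used in modelling is the inverse-normal transform
of MT expression residualized on the technical factor matrix; technical
factors are treated as opaque covariate columns, since their exact
composition varies by pipeline.

Numerical conventions: the inverse-normal transform uses the Blom offset
(`c = 3/8`) with average ranks for ties, and errors on degenerate input
(all values equal). Log transforms of expression use natural log with a
+1 offset. Residualization is ordinary least squares via QR, erroring on
rank-deficient designs with the collinear columns named.

## Deconvolution

QC applies the cell threshold first (≥ 300 expressed genes per nucleus),
then the gene threshold (expressed in ≥ 3 cells). The 300-gene threshold
is calibrated to a genome-scale annotation (~16k genes); analyses on the
package's scaled-down simulations (2,000 genes) scale it proportionally
(40), otherwise the threshold removes entire cell types that a
genome-scale experiment would retain.

Signature genes are selected per cluster by one-vs-rest Wilcoxon rank-sum
tests on library-normalized log2 expression (tie-corrected normal
approximation, computed sparsely in C++), keeping genes with
Benjamini-Hochberg q below `max_p` (default 0.05) and log2 fold-change
above `min_logfc` (default 1), each gene attributed to its
largest-fold-change cluster.

The concordance filter addresses a single-nucleus artifact: nuclear
libraries are rich in pre-mRNA, so some transcripts (MALAT1 is the
canonical example) are orders of magnitude more abundant in nuclei than
in bulk tissue. Per gene, the difference of mean log expression between
bulk samples and pseudo-bulk is standardized to a z-score (the natural
reading of "normalizing" a difference) and genes with `z² ≤ 1` are kept;
the sample standard deviation uses the `n - 1` denominator. If every
difference is identical the filter is degenerate and keeps all genes with
a warning.

The solver is iteratively re-weighted non-negative least squares on
relative expression. Within each cell type, relative abundances and the
cell-size factor are renormalized over the selected genes — without this,
genes excluded from the fit (the nuclear-inflated ones above all) would
still distort every coefficient through the profile normalization.
Weights are `1/(nu + r_g² + Σ_k b_k² σ²_kg)`: a variance floor
(`nu = 1e-4`, relative to the mean squared bulk signal), the current
squared residual, and the propagated cross-subject profile variance.
Weights are capped at 100× their median so no single gene dominates the
fit. Iteration stops when proportions move less than `tol = 1e-6` in the
max norm or at `max_iter = 100`; non-convergence returns the last iterate
with a flag. Near-collinear reference profiles (condition number above
`1e8`) are flagged non-identifiable rather than silently split.
Pseudo-bulk uses summed counts, matching the aggregate-read semantics of
a bulk library, rather than averaging per-cell normalized profiles.
Clustering itself is out of scope: cluster labels are inputs.

Leave-one-out validation rebuilds everything — signature selection,
pseudo-bulk, concordance filter, profiles — from the remaining subjects
only, so nothing from the held-out subject's nuclei can leak into its own
estimate. The default gene set handed to the solver is all
concordance-filtered genes; marker-only and marker∩concordant sets are
options. Per-cell-type accuracy is reported rather than encoding any
fixed rule about which cell types deconvolve well: in practice the rarest
types (an endothelial-like 2% population, say) have so little
cross-subject variation over six subjects that their per-type correlation
is fragile even when absolute errors are small; pooling estimates across
replicate references is the stable way to measure it.

## Matsuda-index modelling

Individuals with T2D are removed before any Matsuda analysis; the index
and MT expression are inverse-normal transformed; the index is
residualized on age and age². The linear model regresses the transformed
index on body fat %, corrected MT expression and the cell-type
proportions with one type excluded — the proportions sum to 1, so the
full set plus an intercept is singular, and the model errors with an
instruction rather than silently dropping a column. The default exclusion
is the last (least reliably estimated) type.

The elastic net minimizes
`(1/2n)‖y − Xβ‖² + λ(α‖β‖₁ + (1−α)/2‖β‖₂²)` by cyclic coordinate descent
with covariance updates, on predictors standardized to unit variance
(1/n denominator), intercept unpenalized, warm starts along a decreasing
λ path. Defaults: `alpha_mix = 0.5` — a single λ weighting both norms
equally, the natural reading of a one-penalty elastic net, configurable;
λ grid of 100 log-spaced values spanning four decades below the smallest
all-zero λ; inner 10-fold CV choosing the λ with minimum mean squared
error, standardization recomputed inside each training split.
Convergence is `tol = 1e-9` on the max coefficient change; solutions
satisfy their KKT conditions to ~1e-9. Age enters the prediction model
linearly (as age, not age + age²). Two predictor presets exist (`bmi`,
`bodyfat`), differing only in the obesity measure.

One solver note: the widely used reference implementation internally
standardizes the response, which rescales the effective ridge penalty by
1/sd(y). The two parameterizations coincide on a unit-variance response,
which is how the test suite cross-checks coefficients along the λ path.

Out-of-fold evaluation partitions the cohort into 100 random groups and
predicts each from a model trained (λ re-selected) on the other 99. With
no predictive signal, hold-out predictions are near-constant and
mechanically anticorrelated with the held-out values (each test point is
absent from its own training mean), so null behaviour is judged by
out-of-fold mean squared error reaching the variance floor, not by the
sign of a correlation.

## What the synthetic-data module emulates

Every generator returns the dataset plus a `truth` record, seeds a local
RNG (restoring the caller's), and is bit-reproducible.

* **MR summary statistics**: exposure effects `Normal(0, 0.03²)` with
  reported SE 0.003 (strong instruments); outcome effects built from the
  causal slope plus optional horizontal pleiotropy on a random subset
  (mean-zero or directional) plus `Normal(0, 0.02²)` noise. Block LD
  matrices place constant r² within consecutive blocks; elementwise
  squares of equicorrelation matrices, hence positive semi-definite.
* **Single-nucleus reference**: six subjects, eight cell types, ~2,600
  nuclei per subject at genome scaled down to 2,000 genes. Cell-type
  proportions are Dirichlet with an adipose-like concentration (the
  dominant adipocyte-like type near 44% of nuclei). Profiles are a shared
  gamma base rate, lognormal cell-identity deviations (`celltype_sd = 1`
  — between-cell-type differences dominate between-subject jitter,
  `subject_sd = 0.3`, the regime in which clustering reflects cell
  identity rather than donor; under these defaults signature selection
  yields roughly 600–700 marker genes, a realistic yield for eight
  types), and 8-fold marker upregulation on 5% of genes drawn from the
  better-expressed half. A 5% subset of genes is nuclear-inflated with
  lognormal folds (median 20, log-SD 1.5), plus one constitutive
  MALAT1-like transcript pinned to the observed regime: ~1540-fold
  inflation occupying ~39% of nuclear reads. Counts are Poisson at the
  per-cell library size (mean 2,000 UMIs, scaled by per-cell-type RNA
  content, default equal — the assumption is explicit and adjustable
  because real cell types differ in RNA content and no measurement of it
  is available here).
* **Bulk mixtures**: proportion-weighted, RNA-content-scaled sums of the
  bulk-side profiles (no nuclear inflation), multiplicative lognormal
  noise (`noise_cv = 0.1`), Poisson counts.
* **Phenotype cohorts**: the latent Matsuda index is linear in
  standardized body fat %, MT expression and cell-type proportions (the
  last type is the zero-effect reference category), with noise scaled
  analytically — `Var(noise) = Var(lp)(1−R²)/R²` — so the realized
  coefficient of determination matches the target (default 0.44) without
  trial-and-error. HbA1c is `4.8 + 0.02·bodyfat% + Normal(0, 0.3)`
  truncated at 4.5; the intercept is set so a body-fat distribution of
  `Normal(27, 7)` yields ~14% of individuals in the prediabetes band
  (HbA1c 5.7–6.4%), the fraction reported in large biobank populations. A
  configurable fraction is flagged T2D with HbA1c pushed above the band.
  Read-category counts give the MT read fraction a logistic dependence on
  MT expression, so the all-reads technical metrics are confounded with
  MT expression while the nuclear-only metrics are not.

What the generators do **not** emulate: realistic LD from a reference
panel, genotype-level data, ambient RNA and doublets, batch effects
between cohorts, correlated predictors in the phenotype model (body fat
and cell-type composition are generated independently, so the variance
explained by predictor subsets adds, unlike in real cohorts where they
overlap substantially), and non-Gaussian phenotype tails. Passing tests
therefore demonstrate correctness and calibration of the estimators under
the assumed generative structure, not robustness to every artifact of
real data.

## Problem sizes

The test suite runs the full chain at the sizes above: MR calibration at
50–100 instruments over hundreds of replicates, deconvolution at 6×2,600
nuclei and 2,000 genes over three replicate references, cohort modelling
at n = 324–2,000 over up to 100 replicates, and 20 repetitions of the
100-group out-of-fold evaluation. These sizes were chosen so that
Monte-Carlo error is small relative to every tolerance asserted while a
full run remains a desk-scale computation.

## Known limitations

* Allele harmonization from raw GWAS exports (strand flips, palindromic
  variants) is not automated; inputs are assumed pre-harmonized.
* The per-cell-type RNA-content multipliers default to 1; if real cell
  types differ materially, estimated proportions are RNA-share-biased
  unless the multipliers are supplied.
* Cross-cohort transfer of the prediction model (training in one cohort,
  predicting another) is supported by `predict_matsuda` plus the JSON
  model serialization, but batch-effect correction across cohorts is out
  of scope.
* The deconvolution bias induced by cell-type-dependent pre-mRNA content
  (beyond the genes the concordance filter removes) is irreducible from
  nuclear references alone; the filter plus weighting mitigates but
  cannot eliminate it.
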
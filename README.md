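# adipomr

Obesity, prediabetes and insulin resistance are tightly entangled, and
observational associations between them cannot say which causes which.
`adipomr` implements, as one tested R package, the analysis chain used to
disentangle them: two-sample Mendelian randomization (MR) of obesity on
glycemic outcomes, quantification of adipose mitochondrial (MT) gene
expression with bias-aware technical correction, deconvolution of bulk
adipose RNA-seq into cell-type proportions against a single-nucleus
reference, and an elastic-net model that predicts the Matsuda
insulin-sensitivity index from adipose features. A synthetic-data module
generates every input with recorded ground truth, so the whole pipeline is
testable without access to restricted cohort data.

It is intended for statistical geneticists and computational biologists
who want these methods as composable, auditable functions rather than as a
collection of one-off scripts.

## Methods at the core

**Mendelian randomization.** For instruments with exposure effects
`βx_i ± σx_i` and outcome effects `βy_i ± σy_i`, the inverse-variance
weighted (IVW) estimate is the weighted regression through the origin

    θ̂ = Σ w_i βx_i βy_i / Σ w_i βx_i²,   w_i = 1/σy_i²,

with multiplicative random-effects SE inflation when Cochran's
`Q = Σ w_i (βy_i − θ̂ βx_i)²` exceeds its degrees of freedom. MR-Egger
refits with a free intercept (the pleiotropy test), after orienting all
variants to positive exposure effects. The MR-PRESSO-style procedure
computes the observed residual sum of squares from leave-one-out IVW fits,
builds its null by parametric resampling of outcome effects (`n_sim`
draws), reports the exceedance fraction as a global pleiotropy p-value,
flags per-variant outliers against their simulated nulls
(Bonferroni-corrected), and re-estimates IVW on the retained instruments.
Instrument selection applies the genome-wide threshold `p < 5e-8` and
greedy LD pruning at `r² < 0.01`; screening against measured confounders
drops instruments associated with them.

**Deconvolution.** A QC'd single-nucleus reference (cells with ≥ 300
expressed genes, genes in ≥ 3 cells) yields per-cell-type mean relative
expression, cross-subject variances, and per-cell-type library sizes.
Genes whose nuclear abundance disagrees with bulk tissue (pre-mRNA-rich
transcripts such as MALAT1) are removed by z-scoring the bulk minus
pseudo-bulk difference of mean log expression and keeping `z² ≤ 1`.
Cell-type proportions are then estimated by iteratively re-weighted
non-negative least squares, down-weighting genes with large residuals or
high cross-subject variance, and converting RNA-share coefficients to
cell-count proportions through the per-cell-type library sizes.
Leave-one-out validation rebuilds the reference without each subject and
compares that subject's estimated proportions to its true label
frequencies.

**Matsuda-index modelling.** After excluding T2D individuals and
inverse-normal transforming, the linear model
`Matsuda ~ β_b·bodyfat% + Σ β_ci·CT_i + β_M·MT` (one cell type excluded:
the proportions sum to 1) partitions variance, and an elastic net

    β̂ = argmin (1/2n)‖Matsuda − Xβ‖² + λ(α‖β‖₁ + (1−α)/2‖β‖₂²)

(coordinate descent, λ chosen at the minimum mean cross-validated error)
predicts the index from BMI or body fat %, MT expression, age and
cell-type proportions, evaluated by 100-group out-of-fold prediction.

## Worked example

```r
library(adipomr)

# two-sample MR at the scale of the body-fat -> insulin-sensitivity arm:
# 100 candidate variants, true causal effect -0.67, 5% directional pleiotropy
sim <- simulate_mr_summary(mr_sim_config(n_variants = 100, causal_effect = -0.67,
                                         pleiotropy_frac = 0.05,
                                         pleiotropy_mode = "directional", seed = 1))
ld  <- simulate_ld_blocks(100, block_size = 4, within_r2 = 0.5)
ivs <- select_ivs(sim$ivs, ld, p_threshold = 5e-8, r2_threshold = 0.01)
report <- run_mr_battery(ivs, n_sim = 5000, seed = 2)
report$presso
#> MR estimate (PRESSO-corrected): -0.7124 (se 0.0974, p 2.56e-13, n_iv 25)
#>   Cochran's Q 27.6 (p 0.276)
#>   PRESSO global p 0.295; outliers: none

# cohort modelling: 335 individuals, 11 with T2D are excluded
cohort <- simulate_cohort(pheno_sim_config(n_individuals = 335,
                                           t2d_frac = 11/335, seed = 3))
coh <- prepare_cohort(cohort$cohort)
m1 <- fit_model1(coh)
sprintf("Model R^2 = %.4f (n = %d)", m1$r_squared, m1$n)
#> [1] "Model R^2 = 0.4661 (n = 324)"

cv <- cross_validate_100fold(coh, preset = "bodyfat", seed = 4)
sprintf("out-of-fold r = %.3f (p = %.2e)", cv$r, cv$p)
#> [1] "out-of-fold r = 0.654 (p = 5.52e-41)"
```

The MR battery recovers the planted causal slope (−0.71 against a truth of
−0.67, within its standard error) with no residual pleiotropy signal; the
linear model explains ~47% of the Matsuda variance on this draw (the
generator is calibrated to 44%); and the out-of-fold correlation of 0.65
is what a cohort of this size and noise level supports.

An end-to-end run (simulation → MR → expression → deconvolution → model)
is driven by a YAML configuration:

```sh
scripts/adipomr run --config demo.yaml --out run1
scripts/adipomr report run1
```

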
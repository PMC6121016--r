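---
title: "Purity-corrected differential expression: model, estimator, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Purity-corrected differential expression: model, estimator, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DECtp)
```

## The problem

Solid tumor biopsies are never pure: a sample labeled "tumor" is a mixture of
cancer cells and tumor-adjacent normal cells (stroma, immune, vascular). The
fraction of cancer cells — the tumor purity $\lambda_s$ — varies widely across
patients. For a gene whose expression genuinely differs between cancer and
normal cells, the observed tumor expression therefore moves with $\lambda_s$:
low-purity samples look more like normals, high-purity samples less so. Two
consequences follow. First, purity inflates the within-tumor-group variance,
diluting the signal of a standard two-group test. Second, the observed mean
difference is attenuated by the average purity, because each tumor sample only
carries a $\lambda_s$ share of the cancer signal. Ignoring purity, or modeling
it as an additive covariate, therefore costs power and biases effect sizes.
The effect of purity on expression is multiplicative in the mixing sense, not
additive, which is what the model below encodes.

## The model

Expression values (RSEM/FPKM-like abundances) are first transformed so that
per-gene expression is approximately Gaussian: every value $v$ becomes
$\log_2(v + \text{min}_{>0})$, where $\text{min}_{>0}$ is the smallest
strictly positive value in the matrix, followed by quantile normalization
(see *Numerical choices* for scope and tie handling).

For gene $i$, let $X_{is} \sim N(m_i, \sigma_i^2)$ be its normalized
expression in pure normal tissue and $Y_{is}$ its (unobserved) expression in
pure cancer cells, with pure-tumor effect $\mu_i$ relative to the normal mean.
The observed tumor expression is the purity-weighted mixture

$$Y'_{is} = (1 - \lambda_s)\,X_{is} + \lambda_s\,Y_{is},
  \qquad Y'_{is} \sim N(m_i + \lambda_s \mu_i,\; \sigma_i^2 + \lambda_s^2 \tau_i^2),$$

so the observed tumor mean is linear in $\lambda_s$ with slope $\mu_i$, and
the tumor variance is at least the normal variance. Stacking the $n_0$ normal
and $n_1$ tumor samples gives the per-gene linear model $Z_i = W\beta_i +
\epsilon_i$ with

$$W = \begin{bmatrix} 1 & 0 \\ \vdots & \vdots \\ 1 & 0 \\
      1 & \lambda_1 \\ \vdots & \vdots \\ 1 & \lambda_{n_1} \end{bmatrix},
  \qquad \beta_i = \begin{bmatrix} m_i \\ \mu_i \end{bmatrix}.$$

Differential expression is the test of $H_0: \mu_i = 0$.

## Estimation and testing

The fit is ordinary least squares, $\hat\beta_i = (W'W)^{-1} W' Z_i$. Because
the error variance differs between the groups, the coefficient covariance is
assembled from group blocks: with $H = (W'W)^{-1} W'$ split column-wise into
the normal block $H_1$ and tumor block $H_2$,

$$\operatorname{var}(\hat\beta_i) = H_1 \Sigma H_1' + H_2 \Sigma' H_2',
  \qquad \Sigma = \hat\sigma_i^2 I_{n_0},\; \Sigma' = \hat\sigma_i'^2 I_{n_1},$$

where the group residual variances use $n-2$ denominators on each side,
$\hat\sigma_i^2 = \sum_{\text{normal}} \hat\epsilon^2 / (n_0 - 2)$ and
$\hat\sigma_i'^2 = \sum_{\text{tumor}} \hat\epsilon^2 / (n_1 - 2)$; group
sizes below 3 are rejected for this reason. The Wald statistic is

$$t_i = \frac{\hat\beta_i[2]}{\sqrt{\operatorname{var}(\hat\beta_i)[2,2]}},$$

referred to a $t$ distribution with $n_0 + n_1 - 2$ degrees of freedom
(two-sided), and false discovery rates are Benjamini–Hochberg step-up values
across genes.

A deliberate modeling note: the estimator is OLS with a heteroscedastic
(block-diagonal) covariance, not a purity-weighted generalized least squares
fit; the tumor group gets a single residual variance per gene rather than the
sample-specific $\sigma_i^2 + \lambda_s^2\tau_i^2$ the generative model would
imply. This keeps the estimator a closed form and matches the displayed
sandwich exactly; the per-sample-weighted fit is a possible extension, not
implemented. Likewise, the $n_0+n_1-2$ reference df are used as stated even
though the two variances are estimated with $n_0-2$ and $n_1-2$ denominators;
the slight conservatism this introduces is visible (and acceptable) in the
null-calibration test.

### Variance shrinkage

With few samples the per-gene variance estimates are unstable, so both
group-wise variance vectors are shrunk toward their cross-gene center before
testing. The rule is convex interpolation on the log scale,

$$\log\tilde\sigma_i^2 = (1 - w)\,\log\hat\sigma_i^2 +
  w\,\overline{\log\hat\sigma^2},$$

i.e. toward the per-group *geometric* mean: $w = 0$ is the identity (used by
the closed-form tests), $w = 1$ replaces every gene by the geometric mean.
The default is $w = 0.5$, a middle ground that stabilizes small-$n$ estimates
without erasing genuine variance heterogeneity; the exact interpolation rule
is the package's own choice, made because shrinkage toward the geometric mean
admits several parameterizations and this one is transparent and directly
testable. Exact zero variances (possible for degenerate rows) are floored at
the 1st percentile of the positive variances in the group (1e-8 if there are
none) before taking logs, since the geometric mean is undefined at 0.

### Numerical choices

* **Normalization scope.** Quantile normalization is joint across all samples
  by default, with a `per_group` option. Normalizing the two groups
  separately forces both groups onto their own reference and can erase or
  fabricate group-level shifts, so joint is the safer default; the option
  exists because per-group pipelines are common in practice.
* **Quantile-normalization ties.** Tied values within a column receive the
  mean of the reference values their ranks span — deterministic and
  rank-preserving. After normalization, the sorted values of every column in
  a scope unit are identical by construction.
* **Log2 offset.** The offset is the global matrix minimum non-zero value,
  not per-gene, matching the stated transform exactly.
* **Purity domain.** $\lambda_s \in (0, 1]$. A reported purity of 0 is
  rejected: such a "tumor" sample contains no cancer cells and contributes a
  degenerate row to the effect column.
* **Degenerate genes.** Constant rows and perfect fits produce residual
  variances and effects that are floating-point dust rather than exact
  zeros; values below `1e-10` times the gene's magnitude are zapped to zero
  so those genes take the deterministic path ($t = 0$, $p = 1$ when the
  effect is also zero).
* **Output determinism.** Results preserve input gene order; ranks are by
  FDR with ties broken by raw p-value, then gene ID.

## The simulation framework

`simulate_dataset()` generates the study design the evaluation relies on:
per-gene pure-normal profiles $X_{ij} \sim N(m_i, \sigma_i^2)$, pure-tumor
profiles $Y_{ij} \sim N(m'_i, \sigma'^2_i)$, purities
$\lambda_j \sim U(0.05, 0.95)$, and observed tumor profiles mixed cell-wise
as $Y'_{ij} = \lambda_j Y_{ij} + (1-\lambda_j) X_{ij}$. A gene is a true DEG
iff $|m_i - m'_i| \ge \delta$ (inclusive). Optionally, reported purities add
Gaussian estimation noise (sd 0.1 in the robustness experiments), clipped
back into the purity range — clipping rather than resampling keeps the
support and is the simplest deterministic rule. Each tumor sample gets its
own pure-normal contamination draw (`X_mix`), independent of the observed
normal group: the contaminating normal cells in a biopsy are not one of the
profiled normal samples.

Default generative distributions, chosen once to resemble log-scale bulk
expression: $m_i \sim N(8, 2^2)$ (log2 RSEM of moderately expressed genes),
per-gene standard deviations $|N(0,1)| + 0.25$ drawn independently for the
normal and tumor sides (right-skewed, bounded away from 0), and an effect
$m'_i - m_i$ that is 0 with probability 0.45 and $N(0, 2^2)$ otherwise. With
these defaults, thresholds $\delta = 1, 2, 3$ label roughly 34%, 17%, and 7%
of genes as true DEGs — the regimes the evaluation grid covers. Degenerate
options (`effect_fixed`, `sigma_fixed`) pin the effect or the dispersion for
calibration and recovery studies. One user seed drives every stream; derived
component seeds are fixed offsets of it, so gene parameters are reproducible
independently of the expression draws.

What the generator deliberately does **not** emulate: read-count sampling
(everything is Gaussian on the log scale — there is no mean–variance count
relationship), gene–gene correlation (genes are independent), library-size
or batch effects, and purity estimates that are biased rather than merely
noisy. Passing tests therefore demonstrate correct behavior under the
Gaussian mixture model, not robustness to count noise or correlated genes on
real data.

## Evaluation and diagnostics

`compare_methods()` scores the purity-corrected caller against a pooled
two-sample $t$-test baseline on the same $(X, Y')$ data, ranking genes by
absolute statistic (equivalent to ranking by p-value at fixed df) and
computing ROC AUC against the generative truth with the Mann–Whitney
formulation (ties count 1/2). The baseline stands in for moderated linear
modeling as well, whose behavior on Gaussian data is nearly identical to the
$t$-test; an `extra_scores` hook accepts externally computed score vectors.

`purity_correlation()` quantifies the confounding directly: per-gene Spearman
correlation between tumor expression and purity, with a single seeded
permutation of the purities as the empirical null (one shuffle, matching the
diagnostic it reproduces; callers wanting a multi-permutation null can loop).
Under the mixture, expression depends on $\lambda$ exactly when
$m_i \ne m'_i$, so true DEGs show elevated $|\rho|$ while the shuffle null
centers at 0 — the package's tests assert both. `group_by_statistic()` bins
genes into statistic deciles (rank-based, ties broken by gene ID), and
`top_n_correlation_curve()` traces mean $|\rho|$ over the top-$n$ ranked
genes.

## Problem sizes

The shipped tests and the acceptance script use 2,000 genes with 10–50
samples per group and 10 seeded replicates per design cell. These sizes give
Monte-Carlo error comfortably below the margins being asserted (e.g. a 99%
binomial band of ±0.013 around the nominal type-I error at $n = 2000$) while
keeping the whole suite fast; the same code runs unchanged at
transcriptome scale.

## Known limitations

* Gaussian-only: count data would need a negative-binomial analogue.
* Purity is an input, never estimated; errors in purity beyond independent
  noise (systematic bias, heteroscedastic estimators) are not modeled.
* The two-column design admits no additional covariates (age, batch, subtype).
* A single tumor-group variance per gene ignores the $\lambda_s^2$ structure
  of the mixture variance; very heterogeneous purity vectors make the tumor
  residuals mildly heteroscedastic within-group.
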
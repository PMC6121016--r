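# DECtp

Differential expression calling between tumor and normal samples that
corrects for tumor purity.

## The problem

Solid tumor samples are mixtures of cancer cells and tumor-adjacent normal
cells; the cancer-cell fraction — the tumor purity λₛ — varies widely across
patients. A gene whose expression truly differs between cancer and normal
cells therefore shows observed tumor expression that drifts with purity:
diluted toward the normal mean in low-purity samples. Standard two-group
tests ignore this, losing power (purity inflates within-tumor variance) and
attenuating effect estimates (each sample carries only a λₛ share of the
cancer signal).

## The model

Observed tumor expression is a purity-weighted mixture of normal and
pure-tumor signal. For gene *i* and tumor sample *s* with purity λₛ:

```
Y′ᵢₛ = (1 − λₛ) Xᵢₛ + λₛ Yᵢₛ,    Y′ᵢₛ ~ N(mᵢ + λₛ μᵢ, σᵢ² + λₛ² τᵢ²)
```

Stacking n₀ normal and n₁ tumor samples gives a per-gene linear model
Zᵢ = W βᵢ + εᵢ, where W has an intercept column and a purity column (0 for
normals, λₛ for tumors) and βᵢ = (mᵢ, μᵢ): the purity-column coefficient is
the *pure-tumor* effect. The fit is least squares,
β̂ᵢ = (WᵀW)⁻¹WᵀZᵢ, with a group-wise heteroscedastic covariance

```
var(β̂ᵢ) = H₁ Σ H₁ᵀ + H₂ Σ′ H₂ᵀ,   Σ = σ̂ᵢ² I,  Σ′ = σ̂ᵢ′² I
```

(residual variances with n−2 denominators per group, shrunk toward the
per-group geometric mean), a Wald test tᵢ = β̂ᵢ[2] / √var(β̂ᵢ)[2,2] on
n₀+n₁−2 df, and Benjamini–Hochberg FDR. The package also ships the
simulation framework (purity-confounded Gaussian mixtures with known DEG
truth), an ROC/AUC evaluation harness against a two-sample t-test baseline,
and purity-correlation diagnostics.

## Worked example

```r
library(DECtp)

sim <- simulate_dataset(simulation_config(
  n_genes = 2000, n_normal = 50, n_tumor = 50,
  delta = 2, purity_noise_sd = 0.1, seed = 1))

expr <- cbind(sim$X, sim$Y_prime)          # genes x (normal + tumor) samples
res <- run_dectp(expr, sim$reported_purities)
head(res[order(res$rank), c("gene_id", "beta_tumor_effect", "wald_t",
                            "p_value", "fdr")], 5)
#>         gene_id beta_tumor_effect wald_t  p_value      fdr
#> 521  gene_00521             -4.67  -27.6 4.85e-48 9.71e-45
#> 672  gene_00672              5.82   26.1 6.83e-46 6.83e-43
#> 1125 gene_01125             -4.49  -25.8 1.82e-45 1.14e-42
#> 1925 gene_01925              5.11   25.7 2.27e-45 1.14e-42
#> 27   gene_00027             -6.12  -25.2 1.14e-44 4.56e-42

sum(res$fdr <= 0.001)
#> [1] 683

compare_methods(sim)$summary
#>   method   auc n_genes n_true_deg seed
#> 1  DECtp 0.983    2000        353    1
#> 2 t_test 0.952    2000        353    1
```

`beta_tumor_effect` is the estimated pure-tumor log2 effect μ̂ᵢ (here the
top-ranked genes recover effects of ±4–6 log2 units); 683 of 2,000 genes are
called at FDR ≤ 0.001, and the purity-corrected caller outranks the
purity-blind t-test (AUC 0.983 vs 0.952 against the generative truth) even
though it was given noisy purity estimates.

For file-based workflows there is a command-line front end:

```sh
Rscript inst/scripts/dectp simulate --out sim --seed 1 --n-genes 2000
Rscript inst/scripts/dectp call --expr sim/expression.tsv \
    --purity sim/purity.tsv --out results --no-normalize
Rscript inst/scripts/dectp diagnose --expr sim/expression.tsv \
    --purity sim/purity.tsv --out diag --seed 2 --no-normalize
```

(`--no-normalize` because simulated matrices are already on the normalized
log scale; raw RSEM/FPKM input is log2-transformed and quantile-normalized
by default.)

The methods vignette (`vignettes/purity-corrected-DE.Rmd`) documents the
estimator, the shrinkage rule, the simulation defaults, and the design
decisions in detail.

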
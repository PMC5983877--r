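# zimpute — summary statistics imputation for GWAS

`zimpute` estimates the association Z-statistic (and standardized effect
size) of a genetic variant that was never tested in a GWAS, using only the
summary statistics of nearby *tag* variants and linkage disequilibrium (LD)
estimated from a reference genotype panel. It is aimed at statistical
geneticists who have meta-analysis summary statistics (e.g. HapMap-era
results) but no individual-level data, and want them at the resolution of a
modern sequencing panel — for fine-mapping, conditional analysis, Mendelian
randomisation or LD-score regression.

## The method

Z-statistics of variants in a region are approximately multivariate normal
with correlation equal to the genotype correlation (LD). The statistic of an
untyped variant *u* is imputed as the conditional mean given the tag
statistics **z**:

    ẑ_u = c_λ' C_λ⁻¹ z

where **C** is the tag–tag LD matrix, **c** the target–tag LD vector (both
estimated from a reference panel of *n* individuals) and the subscript λ
denotes shrinkage toward independence, `C_λ = (1−λ)C + λI`, `c_λ = (1−λ)c`,
which guarantees invertibility and damps noisy near-zero LD (λ = 0.1 by
default; `2/√n` and user values are available). The imputation quality is
`r²_pred = c_λ' C_λ⁻¹ c_λ`, adjusted for the panel size and the effective
number of tags q_eff (leading eigenvalues capturing 99.5% of the LD-matrix
trace):

    r²_adj = 1 − (1 − r²_pred) (n − 1)/(n − q_eff − 1),  clamped to [0, 1].

Meta-analysis statistics rarely share one sample size. When tag *k* was
tested in N_k of at most N_max individuals, the correlations are attenuated:
`d_k = c_k √(N_k/N_max)` and `D_kl = C_kl δ_kl`, where the pairwise factor
δ_kl depends on how the samples overlap — maximal overlap
(`δ = min(√(N_k/N_l), √(N_l/N_k))`, the conservative default), independent
missingness (`δ = √(N_k N_l)/N_max`), or exact known overlap counts. The
imputation then uses `ẑ_u = d' D⁻¹ z`, and the standardized effect is
`â_u = ẑ_u / (√N_max · d'D⁻¹d)`.

On top of the estimator the package provides windowed genome scans (1 Mb
cores with 250 kb flanks), leave-one-out masking for validation, approximate
conditional analysis with a candidate-locus scan against previously reported
variants, a self-contained LD-block genotype/phenotype simulator with
controllable missingness correlation θ_miss, and evaluation metrics
(RMSE, bias, through-origin slope, correlation, power/FPR curves with
binomial errors).

## Worked example

Simulate a small reference panel of two LD blocks, run a GWAS on a
simulated phenotype whose causal variant explains 2% of the variance, mask
one variant and re-impute it:

```r
library(zimpute)

panel <- simulate_genotypes(3000, data.frame(size = c(6, 6),
                                             maf = c(0.2, 0.35),
                                             r = c(0.8, 0.8)), seed = 7)
y     <- simulate_phenotype(panel, causal = 3, h2 = 0.02, seed = 8)
recs  <- run_gwas(panel, y)

mask_and_impute(recs, panel, "sv0003", lambda = 0, missingness = "none")[,
  c("variant_id", "z_imp", "z_obs", "r2_pred", "r2_pred_adj", "n_tags")]
#>        variant_id    z_imp    z_obs   r2_pred r2_pred_adj n_tags
#> sv0003     sv0003 5.328494 6.386722 0.7704377   0.7695926     11
```

The masked variant's observed Z was 6.39; from the 11 remaining tags the
imputation recovers 5.33 with a predicted quality of 0.77 — the expected
attenuation for a target tagged at r² ≈ 0.77. Genome scans work the same
way through `window_impute()`, which emits one row per target with `z_imp`,
`a_imp`, `r2_pred_adj`, a two-sided `p_imp` and a `quality_ok` flag
(`r2_pred_adj ≥ 0.3` by default).

A command-line wrapper is installed at `inst/cli/zimpute.R`:

```sh
Rscript inst/cli/zimpute.R impute --gwas gwas.tsv --ref panel.vcf \
    --lambda 0.1 --missingness dep --out imputed.tsv
```

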
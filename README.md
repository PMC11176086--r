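# gwamakit

Statistical-genetics toolkit for case–control GWAS of complex traits under
the liability-threshold model, built around the analysis stages of a large
restless legs syndrome (RLS)–style meta-analysis: multi-cohort N-weighted
meta-analysis, risk-locus definition, LD score regression heritability and
genetic correlation (autosomes and chromosome X), a gene–environment
interaction simulation study with approximate Bayesian model comparison,
summary-statistic Mendelian randomization, and polygenic-score risk
prediction with interaction models.

Real cohort genotypes are rarely shareable, so the package ships a
first-class synthetic-cohort module: LD-structured genotype panels,
liability-threshold phenotypes with sex-specific prevalence and optional
sex-asymmetric gene–environment (G×E) interaction, and per-variant
association scans. Every analysis stage is exercised end to end on data the
package itself generates.

## The models in brief

**Liability threshold.** Disease status is `1{L > Φ⁻¹(1−K_sex)}` where the
latent liability is

```
L = a·S + c_E·E + c_sex·(S × E) + ε,      a = √h²_liab,
```

`S` the standardized polygenic score, `E` an exposure (Bernoulli or
Gaussian), `c_m`/`c_f` sex-specific interaction coefficients, and residual
variance chosen so Var(L) = 1. A female-to-male interaction ratio
`c_f/c_m ≠ 1` makes the sexes' marginal SNP effects differ in magnitude
while staying perfectly correlated — the mechanism the G×E module is built
to detect from sex-stratified heritability summaries.

**N-weighted meta-analysis.** Cohort Z scores combine as
`Z_meta = Σᵢ wᵢZᵢ / √(wᵀCw)` with `wᵢ = √Nᵢ` and C the cross-cohort score
correlation (estimated on null variants), so overlapping cohorts are not
double-counted; `N_eff = (ΣNᵢ)² / (wᵀCw)`.

**LD score regression.** `E[χ²ⱼ] = 1 + N·a + (N·h²/M)·ℓⱼ` regressed with a
two-step intercept, iterated heteroskedasticity weights and a block
jackknife; liability-scale conversion
`h²_liab = h²_obs · K²(1−K)² / (P(1−P)·z²)`. On chromosome X,
`h² = (χ̄²−1)·M_eff/N` and the cross-sex genetic correlation is
`mean(Z_m·Z_f) / √((χ̄²_f−1)(χ̄²_m−1))`.

**MR and prediction.** IVW and Egger estimators over harmonized, LD-pruned,
Steiger-filtered instruments; PRS `Σⱼ wⱼgⱼ` entering the logistic model
`logit P(case) = β₀ + β₁PRS + β₂sex + β₃age + … + β₇PRS×sex×age + γ·PC`
with age in 20-year bins, evaluated by cross-validated AUC, PR-AUC, OR per
PRS standard deviation and Nagelkerke pseudo-R².

## Worked example

```r
library(gwamakit)

# simulate a case-control cohort with LD structure at 9% prevalence
G  <- simulate_ld_reference(n = 20000, blocks = 200, block_size = 10,
                            rho = c(0, 0.3, 0.5, 0.7, 0.9),
                            maf_range = c(0.1, 0.5), seed = 42)
par <- liability_params(h2_liab = 0.2, K_m = 0.09, K_f = 0.09, seed = 43)
phen <- simulate_liability_phenotypes(G, par)
gwas <- run_single_snp_gwas(G, phen)

# LD score regression heritability, transformed to the liability scale
ref    <- simulate_ld_reference(n = 4000, blocks = 200, block_size = 10,
                                rho = c(0, 0.3, 0.5, 0.7, 0.9),
                                maf_range = c(0.1, 0.5), seed = 42)
scores <- compute_ld_scores(ref, window_kb = 2000)
h2 <- ldsc_h2(gwas, scores, M = 2000, K = 0.09, P = mean(phen$case_status))
h2
#> LD score regression heritability
#>   observed-scale h2: 0.0761 (se 0.0149)
#>   liability-scale h2: 0.2406 (se 0.0470)  [K=0.09, P=0.0882]
#>   intercept: 0.7877 (se 0.2009); mean chi2 2.6999; ratio -0.125
#>   2000 SNPs, M = 2000, mean N = 20000, 200 jackknife blocks
```

The liability-scale estimate (0.241 ± 0.047) covers the simulated truth
h² = 0.2, and the intercept is within two standard errors of 1,
consistent with the absence of simulated confounding.

```r
# two-sample Z-test on published X-chromosome heritability estimates
estimate_diff_ztest(0.0032, 0.0018, 0.0047, 0.0012)
#> $z
#> [1] -0.6933752
#> $p
#> [1] 0.4880741
```

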
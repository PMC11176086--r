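---
title: "Models and methods: liability-scale GWAS analysis with gwamakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: liability-scale GWAS analysis with gwamakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gwamakit)
```

# Scope

gwamakit re-creates, on synthetic data, the statistical core of a modern
case–control GWAS meta-analysis of a common complex disease: combining
cohorts, defining risk loci, estimating heritability and genetic
correlation on both the observed and liability scales (including
chromosome X), explaining sex-differential heritability through
gene–environment (G×E) interaction, running summary-statistic Mendelian
randomization, and building polygenic risk prediction models with
interaction terms. This vignette records the models, the design choices
that were genuinely open, the numerical conventions, and what the synthetic
data can and cannot tell you about real cohorts.

# The synthetic cohort generator

## Genotypes

`simulate_ld_reference()` builds haplotypes by a first-order Markov copy
process: within an LD block, the allele at variant *j*+1 copies the allele
at variant *j* with probability ρ and is otherwise a fresh Bernoulli draw
at the block's allele frequency. Two independent haplotypes sum to a
dosage. This construction has two properties that matter for everything
downstream:

* the genotype correlation between variants *j* and *k* of a block is
  exactly ρ^|j−k| (an AR(1) profile), so LD-score closed forms such as
  ℓ ≈ 1 + 2ρ²/(1−ρ²) for interior variants are available as test oracles;
* marginal allele frequencies are preserved exactly, so dosage column
  means match 2·f without calibration.

An alternative we rejected was thresholding a latent Gaussian AR(1)
process: dichotomizing attenuates the latent correlation (the tetrachoric
effect), so the realized genotype r² undershoots the nominal ρ² by far
more than the ±10% tolerance we run our LD checks at. The copy model hits
the target exactly and is cheaper to simulate.

`rho` may vary across blocks. Real genomes mix strong and weak LD, and the
spread of LD scores this produces is what makes the LD score regression
slope/intercept separation well conditioned; with a single ρ the regressor
has almost no variance and the estimator, while unbiased, is an order of
magnitude noisier. Heritability tests therefore use a ρ mix
(0–0.9) spanning realistic LD.

Chromosome X is simulated with one haplotype for males and dosages coded
0/2 (no dosage compensation), 0/1/2 for females.

Population structure is optional: with `fst > 0` the panel splits into two
equal subpopulations whose per-variant allele frequencies drift apart by
δ ~ N(0, fst·f(1−f)), independent of local LD. Pairing this with a
liability offset between the subpopulations (`strat_shift`) produces
textbook confounding: association inflation that is flat in the LD score,
which the LD score regression intercept absorbs while the slope stays put.
The drift must be independent of LD for this to hold, which is why the
shift is tied to the subpopulation labels of the genotype panel rather
than to any genotype-derived score.

## Phenotypes

`simulate_liability_phenotypes()` draws the liability

L = a·S + c_E·E + c_sex·(S × E) + ε, a = √h²_liab,

with S the *empirically standardized* polygenic score of the causal
variants, E the exposure (`binary` = Bernoulli(q_sex), `continuous` =
Normal(q_sex, 1)), and ε Gaussian with variance 1 − Var(systematic part),
computed analytically per sex (the interaction contributes
c²·(Var E + (E E)²) plus a 2·a·c·E[E] covariance term because S×E and S
are correlated when E[E] ≠ 0). The liability is centred per sex at its
expected mean so that the case threshold Φ⁻¹(1−K_sex) delivers prevalence
K_sex; the residual variance makes total variance 1 in expectation, and
the realized variance is *checked* by tests (within [0.97, 1.03] at
n = 50,000), not forced. Requested parameter combinations whose
systematic variance reaches 1 are rejected with a diagnostic rather than
silently rescaled.

Defaults mirror the study conditions the package is built around:
prevalence K = 0.09 for both sexes, h²_liab = 0.2. Onset ages for
prevalent cases are truncated normal (mean 45, sd 15, truncated to
[5, current age]); published analyses of this design rarely state an
onset distribution, so the mid-life profile is our own choice. Ages are
uniform on [20, 80].

## Association scans

`run_single_snp_gwas()` uses the standard GWAS score test for binary
outcomes: the covariate-only logistic null model is fitted once, dosages
are residualized against covariates under the null weights, and each
variant gets U = xᵀ(y−p̂), V = x̃ᵀWx̃, Z = U/√V, β̂ ≈ U/V. This is the
approximation production GWAS tools use and is what makes a 10⁵-variant
null calibration run in seconds; its genomic-control λ sits in
[0.97, 1.03] and its null p-values pass a Kolmogorov–Smirnov uniformity
check at 10⁵ independent variants. For the latent (quantitative) liability
the scan is exact least squares. Monomorphic variants are returned with a
`monomorphic` flag, never dropped silently.

# Meta-analysis and loci

The N-weighted scheme, its effective sample size, Cochran's Q, one-round
genomic control (never deflating, per the usual convention), greedy
clumping (r² > 0.05 within 500 kb, p1 = 5×10⁻⁸, p2 = 10⁻⁵), locus merging
(< 500 kb span gap, transitive closure) and stepwise conditional selection
(10 Mb window, colinearity cutoff 0.9, standardized-genotype joint model)
are described in the README and the function documentation. Open choices
we fixed:

* **Cohort correlation C** is estimated as the correlation of Z scores on
  the doubly-null subset (|Z| < 1.96 in both cohorts), the cross-trait
  intercept practice; the result is eigenvalue-clipped to the nearest PSD
  matrix. The first cohort defines allele orientation.
* **Allele matching** tries identity, swap, strand complement, and swapped
  complement; palindromic variants resolve by allele-frequency proximity
  when the frequencies are informative (|Δf| < 0.2 and unambiguous) and
  are dropped otherwise, with a reported count.
* **Clump ties** in p break by chromosome then position. "Locus distance"
  is interpreted as the gap between clump member spans.
* Loci serialize as BED-like rows (0-based half-open); internally spans
  are 1-based inclusive.

# Heritability and genetic correlation

`ldsc_h2()` implements the two-step intercept (χ² < 30), weights
1/(max(ℓ,1)·max(1, fitted)²) iterated twice, and a delete-one block
jackknife over 200 contiguous blocks (automatically reduced when fewer
than 10 variants per block are available). The `weight_iters` argument
exposes the fixed-weight regression for algebraic checks (a constant added
to every χ² moves the intercept by exactly that constant and leaves the
slope unchanged — true only with fixed weights). Negative h² estimates are
reported as-is: truncation would bias the difference Z-tests the sex
comparisons rely on.

The scale of our recovery experiments is M = 2,000 variants and N = 20,000
individuals, laid out as 500 LD blocks of 4 variants: one replicate
simulates, scans and fits in a few seconds, a ten-replicate recovery in
under two minutes, and at that scale the liability-scale median absolute
error across an h² × K grid stays under 0.05. The block granularity
matters: conditional on a realized polygenic architecture, the per-panel
regression intercept and slope deviate from their expectations by an
amount that shrinks with the number of independent blocks, and with ~200
large blocks that architecture noise exceeds the jackknife standard error
(which only sees within-panel sampling), making nominal 2-se intervals
under-cover. At 500 blocks the between-replicate spread matches the
jackknife se and the intervals are calibrated. These sizes are a
deliberate compromise — small enough for the full suite to run in
minutes, large enough that standard errors are meaningful.

Chromosome X uses the mean-χ² estimator h² = (χ̄²−1)·M_eff/N with
M_eff = M / mean(ℓ) — perfectly correlated variants count once,
independent ones fully. The same estimator pair (with the Z-product
cross-sex correlation, valid for independent male/female samples) doubles
as the fast summary engine inside the ABC loop. `xchr_rg()` clips to
[−1, 1] but keeps the raw value, and refuses to divide by non-positive
mean-χ² excess.

# The G×E simulation study

The question this module answers: can an unobserved exposure with a
sex-asymmetric interaction reproduce the pattern of a higher female than
male heritability together with a cross-sex genetic correlation near 1?
The generative defaults we fixed — binary exposure with prevalence 0.3 in
both sexes, main effect c_E = 0.2, female-only interaction c_f = 0.6,
c_m = 0, h² = 0.2, K = 0.09 — produce exactly that signature at the
reduced scale (3,000 individuals per sex, 200 variants) the module runs
at, and the no-G×E model with sex-symmetric parameters provably centres
the heritability ratio at 1.

Model comparison is approximate Bayesian computation with uniform priors
on the free parameters, a standardized Euclidean distance over
(h²_m, h²_f, r_g) scaled by the observed standard errors, and an
acceptance tolerance set at the 10% quantile of the pooled simulated
distances (shared across models so the kernel mass cancels in Bayes
factors). Marginal likelihood ≈ acceptance rate, floored at 1/(draws+1)
with a flag. One genotype panel is built per model and reused across
draws: per-draw cost is then the phenotype draw, two score-test scans and
the mean-χ² summaries, which keeps a 20-repetition model-selection
experiment (200 draws per model) inside ten minutes on one core. ABC is
our choice of comparison engine; its Bayes factors are exactly
antisymmetric under model swap by construction.

The posterior female/male interaction ratio c_f/c_m is summarized by its
median and percentile interval over accepted draws; when the prior (or
model) pins c_m at zero the ratio is unbounded and a one-sided bound is
reported instead.

# Mendelian randomization

Harmonization keeps exposure variants below the instrument p-threshold,
prunes to pairwise r² < 0.01 greedily by p, aligns outcome effects to the
exposure's effect allele, and drops palindromic variants whose frequency
falls in [0.42, 0.58], the band harmonization tools conventionally
treat as ambiguous. Every exclusion
carries a reason code and the codes always partition the candidate list.
IVW is the weighted zero-intercept regression (equivalently the
inverse-variance average of Wald ratios) with multiplicative
random-effects dispersion floored at 1; Egger adds a free intercept after
orienting exposure effects positive. Steiger filtering compares
r² ≈ Z²/(Z²+N) across sides and keeps exact ties. FDR control is
Benjamini–Hochberg via `stats::p.adjust`.

# Risk prediction

`resample_population()` turns an ascertained case–control cohort into a
population with a chosen age–sex pyramid and an age-resolved cumulative
incidence curve: stratum counts are multinomial, case status is Bernoulli
at the stratum incidence, genetic profiles are resampled from sex- and
status-matched cohort members, and onset ages are resampled from the
cohort's onset distribution conditioned on onset ≤ current age.

The interaction model is the logistic regression of case status on PRS,
sex, age (20-year-bin dummies), all interactions up to PRS×sex×age, and
optional PCs. ORs are reported per PRS standard deviation (an odds ratio
for a continuous score needs a unit; per-SD is the convention we fix),
and at the reference stratum the OR per SD is exactly exp(β₁·sd(PRS)) — an
identity the tests assert. Nagelkerke's pseudo-R² is computed from
log-likelihoods to avoid underflow. Five-year landmark labels exclude
prevalent cases at the landmark and individuals censored before
landmark+5 without an event: partial follow-up is discarded rather than
imputed, a choice that trades sample size for label cleanliness.

Any learner exposing `fit(X, y)` / `predict_scores(model, X)` plugs into
the stratified cross-validation harness; the package ships plain and
all-pairwise-interaction logistic learners and a random-forest adapter
(ranger, probability forests, single-threaded for reproducibility). Fold
assignment hashes the canonical row order, so metrics are invariant to
shuffling the input.

# What passing tests do and do not show

The generator emulates LD block structure, sex-specific prevalence,
polygenicity, drift-based stratification and sex-asymmetric G×E. It does
not emulate imputation uncertainty, minor-allele-frequency/LD-dependent
architecture (the LDAK-style models), relatedness, case–control
ascertainment beyond prevalence re-weighting, genotyping batch effects, or
non-European LD. Recovery of h² = 0.2 here therefore validates the
estimator chain — not any claim about real cohorts; the published headline
numbers (loci counts, AUCs, Bayes factors, the interaction ratio) depend
on inaccessible cohort data and are structurally, not numerically,
reproduced. The two quantities that *are* recomputable from printed values
— the X-chromosome heritability difference test (p ≈ 0.49) and the
overall-vs-60+ PRS odds-ratio difference test (p ≈ 2.6×10⁻⁵) — are
asserted at printed precision.

# Numerical conventions

* All randomness flows from explicit integer seeds; every simulation
  function is bit-reproducible given its seed.
* Genomic control divides χ² by λ only when λ > 1.
* Jackknife pseudovalues use g·θ̂ − (g−1)·θ̂₋ᵦ with contiguous genome-order
  blocks.
* Z-tests are two-sided normal throughout; `vs_one` tests departure from 1
  (for genetic correlations).
* Matrix near-singularity cutoffs: conditional-selection denominators
  below 10⁻⁸ are treated as colinear and skipped; cohort correlation
  matrices are eigenvalue-clipped at 10⁻⁸.
* p-values are never allowed to underflow to 0 on read (doubles hold
  1e-300), and BH adjustment is applied to p, not Z.
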
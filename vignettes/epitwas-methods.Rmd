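---
title: "epitwas: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{epitwas: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: what each
stage assumes, which knobs matter, what the synthetic-data generator does
and does not emulate, and where the design was genuinely open. Nothing
here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Expression weight training

For a gene with transcript span `[start, end]`, the candidate SNPs are
all panel SNPs with position in `[start − W, end + W]`, inclusive, with
`W = 1e6` bp (`window` argument throughout). Per-SNP eQTL statistics are
simple linear regressions of standardized expression on standardized
dosage; *P*-values use the t distribution with n − 2 df. Constant dosage
columns are assigned beta = 0, *P* = 1 and flagged.

Candidate SNP sets are the Cartesian grid of eQTL *P* thresholds and
annotation filters:

* thresholds: `{0.001, 0.01, 0.05, 0.1, 0.5, 1}` by default. The grid is
  a package choice (configurable); it spans the hard-filter regime to the
  all-cis-SNPs regime in roughly log-uniform steps.
* filters: `all` (no filter), `any_feature` (SNP overlaps at least one
  epigenetic feature), and each single feature. Feature combinations are
  excluded to bound the grid; annotations act as set filters only, not as
  penalty weights.

Empty sets are dropped; sets with identical membership are deduplicated
keeping the least restrictive spec (broadest filter, then highest
threshold), so reported winning parameters are never spuriously tight.

Each set is fitted with the lasso (α = 1) and the elastic net (α = 0.5)
by coordinate descent on the objective

\[
\tfrac{1}{2n}\lVert y - Xw \rVert^2
+ \lambda\big(\alpha \lVert w\rVert_1 + \tfrac{1-\alpha}{2}\lVert w\rVert^2\big),
\]

implemented in C++ with warm starts along a 100-point log-spaced λ path
(from the null point `λ_max = max|X'y| / (n α)` down to `10⁻³ λ_max`) and
glmnet-style active-set sweeps. λ is chosen by inner 5-fold
cross-validation within the training split with the 1-SE rule; if the
1-SE pick is the all-zero model while the path contains nonzero
solutions, the CV-minimum λ is used instead, and a model whose entire
path is zero is flagged unusable. Nested CV with the 1-SE rule is a
package choice: it keeps the outer ten-fold loop purely for model
selection while regularizing conservatively inside each split. The test
suite verifies the solver against soft-thresholding closed forms, OLS at
λ = 0, KKT conditions at the returned λ (tolerance 1e-6), and glmnet as
an independent implementation.

Model selection runs ten outer folds, assigned once per gene from the
seed. Within each training split the eQTL scan, set construction and fits
are repeated from scratch (so membership is fold-specific); the held-out
score is the squared Pearson correlation between predicted and observed
expression, defined as 0 when the prediction is constant — a scale-robust
choice that also penalizes unusable fits. The winner maximizes the mean
over folds; ties break toward fewer member SNPs, then toward the lasso
(parsimony, then determinism). The final model re-runs the eQTL scan on
all samples, rebuilds the member set under the winning threshold and
filter, and refits the winning method on all samples, standardizing on
the full data.

### cis-heritability filter

Genes enter association testing only when their cis heritability
excludes zero at 95% confidence. The estimator is a single-component
REML: `y = g + e`, `g ~ N(0, σ²_g K)` with the cis GRM
`K = X_std X_std' / m`, fitted by profile likelihood on the spectral
decomposition of `K` (obtained from the SVD of the standardized dosage
matrix, so only `min(n, m)` eigenvalues are touched; one degree of
freedom is absorbed by centering). The standard error is the observed
information — the numeric curvature of the profile log-likelihood at the
optimum (central differences, step 1e-3) — and the filter is
`h² − 1.96·se > 0`. The estimator and its CI construction are package
choices. Their calibration is checked empirically: pure-noise genes pass
in ≤ 7% of 200 simulations, simulated h² = 0.3 is recovered within
±0.05 over 100 replicates at n = 1000, and a boundary optimum (an exact
linear fit) yields an infinite SE and a conservative failure rather than
a spurious pass.

## 2. Summary-statistic association

GWAS z-scores are harmonized to model SNPs by rsID: identical allele
pairs keep z, swapped pairs flip its sign, strand-ambiguous SNPs (A/T,
C/G) and allele mismatches are dropped. Matching on rsID alone (positions
are only sanity metadata) and dropping ambiguous SNPs rather than
frequency-resolving them are safety-over-completeness choices; summary
files carry no guaranteed frequency column.

The association statistic is `z = w'z_GWAS / √(w'Rw)` with `R` the
Pearson correlation of standardized reference dosages. A quadratic form
below 1e-8 is a degenerate model; the gene is reported untested (`NA`
row) rather than given a fabricated statistic. The permutation test
shuffles the weight *values* across the model's SNP positions — not sign
flips — keeping `z` and `R` fixed, and reports the pseudocount empirical
*P* `(b+1)/(n+1)` with `n = 10,000` draws by default, hence the floor
1/10,001 ≈ 1.0 × 10⁻⁴. Per-gene seeds derive from a master seed plus a
gene-id hash, so results are invariant to gene order. With k model SNPs
the permutation space has at most k! points; one-SNP models return `NA`
and two-SNP equal-weight models return 1 with a degeneracy flag.

## 3. Joint and conditional locus decomposition

Significant genes whose transcript spans extended by 1 Mb overlap are
merged transitively into regions. Gene–gene predictor correlation is
`w₁'Rw₂ / √(w₁'Rw₁ · w₂'Rw₂)` on the SNP union (zero-padded weights);
the suite checks it equals the correlation of individual-level predicted
expression on the panel. "Conditionally independent" is operationalized
as forward-stepwise selection at the study-wise threshold: seed with the
smallest marginal *P*, repeatedly add the gene with the smallest
conditional *P* while it clears the threshold. The selection algorithm is
a package choice; the suite verifies that near-collinear shadow genes
(predictor correlation 0.99) are pruned and orthogonal ones are kept.

All inversions use a ridge-regularized correlation matrix
(`(C + 0.05 I)/1.05`, preserving the unit diagonal) — necessary because
co-localized genes can be nearly collinear. The per-SNP conditional scan
uses `ρ_{s,i} = (Rw_i)_s / √(w_i'Rw_i)` and

\[
z_{cond}(s) = \frac{z_s - \rho_s' C^{-1} z_{genes}}{\sqrt{1 - \rho_s' C^{-1} \rho_s}};
\]

a denominator at or below 1e-6 means the SNP is fully explained and is
reported as `z = 0`, `P = 1` with a flag. The proportion of signal
explained is `1 − χ²_cond/χ²_marg` at the marginal lead SNP, clamped to
`[0, 1]`. This lead-SNP χ² ratio is a defined, reproducible statistic;
published "variance accounted" numbers from other pipelines may use a
different (unstated) convention, so no numerical equivalence with them is
claimed.

A caveat discovered while validating against the individual-level oracle:
when conditioning removes *all* signal at a locus, both the summary-based
and the individual-level conditional z-scores are pure noise, and their
correlation is uninformative. The oracle-equivalence checks therefore
condition on a gene that leaves residual signal (the non-causal gene of
the shared-locus scenario), where agreement is r > 0.99; full explanation
is asserted separately via `signalExplained()`.

## 4. Partitioned heritability

SNPs within 2 kb (inclusive) of any listed gene form the gene-set
category. Stratified LD scores are
`ℓ(j,c) = Σ_{k∈c, |k−j|≤w} r²_adj(j,k)` with the finite-sample
adjustment `r²_adj = r² − (1−r²)/(n−2)`, floored at 0 term by term. The
per-term floor is deliberate: it is the only flooring that guarantees a
sub-category's score never exceeds the base score. The window is counted
in SNPs (default 100; 30 in the simulation checks, where LD blocks span
10 SNPs, so the window is at least three block lengths) because the
synthetic map has no genetic distances; it never crosses a chromosome
boundary.

The regression is `E[χ²_j] = intercept + N Σ_c τ_c ℓ(j,c)` with a free
intercept (configurable fix-at-1), LDSC-style two-step weights (LD
redundancy times the squared fitted mean), per-category heritability
`h²_c = Σ_{j∈c} Σ_{c'} τ_{c'} a_{jc'}`, enrichment
`(h²_c/h²_tot)/(M_c/M)`, and a 200-block delete-one jackknife for the
enrichment SE and the two-sided normal *P* on `(enrichment − 1)/se`. A
category containing every SNP has enrichment identically 1 and is
reported with *P* = 1; a non-positive total h² flags the result
non-estimable instead of returning ratios of noise.

## 5. Catalog enrichment

Gene-level TWAS *P* is the minimum across tissues. "Similar size" null
sets are implemented as exactly equal size, drawn uniformly without
replacement from the tested genes — the simplest matching that leaves the
null exchangeable; expression- or length-matched draws are out of scope.
The empirical *P* uses the same pseudocount estimator as the permutation
test. The suite checks the null count against the exact hypergeometric
law and the monotonicity of the *P*-value in the known genes' *P*-values.

## 6. What the synthetic data emulates — and what it does not

Genotypes are two haplotypes per individual, each a latent Gaussian AR(1)
within fixed-size LD blocks (adjacent latent correlation `rho`,
independent blocks) thresholded at the MAF quantile; MAFs are uniform in
`mafRange` (default 0.05–0.5). This reproduces the features the pipeline
actually consumes — banded positive LD, bounded integer dosages,
realistic allele frequencies — with a two-parameter model whose adjacent
dosage correlation the suite pins against a 10⁶-draw Monte-Carlo oracle.
It does **not** emulate human haplotype structure, recombination maps,
population stratification, or long-range LD; passing tests say the math
is right under block LD, not that the pipeline is robust to confounding.

Expression is `X_std w* + ε` with `kCausal` causal SNPs drawn
preferentially from annotated positions (odds multiplier `enrichment`)
and noise scaled so the genetic share is exactly `cisH2`. Phenotypes sum
standardized per-gene genetic scores weighted by `alpha` plus noise to
unit variance; z-scores are marginal regression statistics from an
explicit, independently drawn cohort of `nGwas` individuals — so an
individual-level oracle always exists — with a direct MVN fast path
(`simulateGwasZ`, `Z ~ N(√N·Rβ, R)`) for large-m calibration runs. The
case/control/proxy liability design of real disease GWAS is not
emulated; z-scores are the interface. Annotation features cover each SNP
independently with the stated density (width-1 intervals), so feature
coverage is exactly Bernoulli per SNP; spatially clustered regulatory
domains are not modeled.

Scenario defaults are fixed study conditions, not tuning knobs: `null`
(30–500 genes, cis-h² 0.3, all `alpha = 0`), `one_gene` (five loci,
causal gene cis-h² 0.5, `alpha = 0.25`, n_GWAS = 5000), and
`two_genes_shared_locus` (two genes on one 24-SNP locus, blocks of 12 at
`rho = 0.9`, one causal) — chosen to give the causal signal a GWAS z
around 10–15, comfortably detectable but not trivial, with a shadow gene
whose predictor correlation genuinely stresses joint selection. Every
generator consumes explicitly derived seeds; fixture emission is
byte-identical under a fixed seed.

## 7. Numerical choices and degenerate inputs

* Standardization uses the population (divisor-n) convention everywhere,
  matching the penalized objective; held-out folds are standardized with
  training statistics.
* Coordinate descent: convergence when the largest scaled coefficient
  update falls below 1e-7; max 1e5 sweeps.
* Constant columns: flagged and neutralized at every entry point (eQTL
  *P* = 1, identity LD rows, zero weights) rather than propagating NaN.
* Missing genotypes: sites with > 5% missing calls are dropped; the rest
  are mean-imputed, the standard choice for LD reference construction.
* Ties in model selection: fewer SNPs, then lasso — deterministic and
  parsimonious.
* Empirical p-values never return 0 by construction.

## 8. Problem sizes used in the checks

The calibration and recovery checks run at: 200 genes for the
summary-vs-individual-level oracle (n_GWAS = 5000); 500 genes for null
*P* uniformity; 200 pure-noise genes (n = 500) for the heritability
filter; 100 replicates (n = 1000) for cis-h² recovery; 50 replicates of
m = 2000 SNPs (N = 20,000) for stratified-LDSC enrichment; 50 seeds for
causal-gene retention; 20 seeds for lead-SNP signal explanation. These
sizes give the stochastic assertions comfortable margins (binomial SEs of
a few percent) while a full run of suite plus acceptance script stays in
the minutes range on a single core.

## 9. Known limitations

* No covariate regression (PEER factors, ancestry PCs) on expression,
  no trans-eQTLs, no multi-tissue joint training.
* LD is sample LD from a finite panel; with very small panels the
  conditional scan inherits its noise (the ridge term bounds, but does
  not remove, this).
* The permutation test is weak for models with few SNPs — an inherent
  property of shuffling a short weight vector, surfaced honestly as
  conservative or `NA` empirical p-values.
* Indels, dosage (DS) fields and PLINK binary formats are out of scope;
  inputs are GT-only VCF, BED3, whitespace-delimited summary statistics,
  and TSV tables.
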
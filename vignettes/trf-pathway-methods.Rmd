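---
title: "Two-stage random-forest pathway tests: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage random-forest pathway tests: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfpathway)
```

## The problem

Single-SNP genome-wide association tests need very strong marginal effects to
survive multiple-testing correction, and they are blind to architectures where
risk comes from the *joint* effect of several loci. Pathway tests aggregate
the SNPs mapped to a biologically defined gene set and ask one question per
pathway: do these SNPs jointly predict case-control status? Random forests are
a natural engine for that question because classification trees pick up both
marginal effects and gene-gene interactions without the analyst enumerating
interaction terms.

This package implements a two-stage random-forest pathway test (TRF-pathway),
its single-stage predecessor (RF-pathway), and a PLINK-style set-based
comparator, together with the simulation machinery used to study their
type-I error and power.

## The TRF-pathway test

For one pathway the procedure is:

1. **Map** SNPs to the pathway: a SNP belongs to the pathway if it lies on the
   same chromosome as one of the pathway's genes and within a flanking window
   (default 20 kb, boundaries inclusive) of the gene body.
2. **Stage 1** — fit a random forest on all mapped SNPs and compute each SNP's
   *standardized permutation importance* `Z_j`: per tree, the decrease in
   out-of-bag (OOB) accuracy after permuting SNP *j* within that tree's OOB
   samples; averaged over trees and divided by its standard error
   (`Z_j = mean(d_tj) / (sd(d_tj)/sqrt(T))`, set to 0 when the per-tree
   decreases have zero variance).
3. **Stage 2** — refit the forest on the SNPs with `Z_j >` a threshold
   (default 1.64, the one-tailed 5% point of the standard normal). The OOB
   prediction error of this second forest is the pathway score `R`.
4. **Permutation null** — repeat steps 2–3 on `K` phenotype permutations
   (genotypes untouched), giving scores `R_1, …, R_K`, and report
   `p = (1 + #{i : R_i ≤ R}) / (K + 1)`.

Omitting the threshold skips the selection entirely and yields the
single-stage RF-pathway test: one forest on all mapped SNPs per (permuted)
phenotype.

Two properties carry the statistical weight:

* **Exchangeability.** The stage-1 selection is re-run inside every
  permutation, so the data-dependent filtering is part of the null pipeline.
  This is what makes the two-stage design valid — selecting SNPs once on the
  observed phenotype and permuting only stage 2 would inject selection bias
  into the null. The score `R` is therefore *not* an unbiased prediction
  error estimate (that would require cross-validation, which costs power and
  is out of scope); it is only a test statistic.
* **Validity of the estimator.** The add-one form `(1+c)/(K+1)` can never be
  zero, is exact under exchangeability, and counts ties (`R_i = R`) as
  extreme, which errs on the conservative side when the OOB error takes few
  distinct values.

If no SNP clears the threshold in a given (observed or permuted) fit, the
default `all_snps` fallback lets that stage-2 fit fall back to the full
stage-1 set — i.e. the fit reduces to the single-stage score — preserving
exchangeability; a `top_one` policy (single best SNP) is available. The
threshold comparison is strictly greater-than.

## The random forest

The forests are classification forests in the Breiman tradition, implemented
natively (in C++) because both stages must be re-fit inside every one of the
`K` permutations of every pathway or replicate:

* each tree is grown on an n-sample bootstrap drawn with replacement;
* splits minimise Gini impurity among `mtry` candidate SNPs (default
  `floor(sqrt(p))`), with the two ordered cuts a dosage in {0,1,2} admits;
  nodes split while any candidate strictly improves impurity and terminal
  nodes may reach size 1 (the classical classification defaults);
* a sample's OOB prediction is the majority vote of the trees for which it is
  out of bag, with vote ties assigned to the control class; the OOB error is
  computed over samples with at least one OOB vote;
* importance permutations are seeded per (fit seed, tree, SNP), and columns
  are canonicalised by SNP id before fitting, so a fit is bit-for-bit
  reproducible from its seed and invariant to the column order of the input.

`n_trees` defaults to 500 for data analysis; the simulation harness uses 100
trees per forest, which is ample for a *test statistic* (the permutation null
sees the same tree count).

## The set-based comparator

The comparator mirrors the set-based test popularised by PLINK: per-SNP
1-df allelic chi-square statistics (2×2 minor/major allele counts by
case-control status, no continuity correction; monomorphic SNPs score 0 with
p 1); greedy tag-SNP selection — repeatedly take the most significant
remaining SNP and prune everything with pairwise composite-genotype
`r² ≥ 0.5` to it; the pathway statistic is the mean chi-square over tag SNPs
with per-SNP `p < 0.05` (0 if none qualifies); significance from phenotype
permutations that re-run the whole pipeline, with large statistics extreme.
Because the greedy selection is phenotype-aware, re-running it per
permutation is required for exchangeability; freezing the observed tags is
available as a sensitivity option.

## The simulator

The generator emulates the operating characteristics that matter to these
tests — per-SNP minor-allele frequencies and block-wise linkage
disequilibrium — without forward-time population simulation:

* **Genotypes.** One LD block per gene. Within a block, each of a sample's
  two haplotypes is a thresholded latent Gaussian vector with exchangeable
  correlation ρ (default 0.5, moderate LD); thresholds are the MAF quantiles,
  so every SNP is marginally in Hardy-Weinberg equilibrium at its MAF (drawn
  uniformly from 0.05–0.45 unless fixed). Blocks are independent. What this
  does *not* reproduce: distance-decaying LD within genes, between-gene LD,
  allele-frequency spectra skewed toward rare variants, and demographic
  history — so passing tests speak to calibration and relative power under
  block-correlated predictors, not to any specific population.
* **Disease model.** Three causal loci (a fourth, main-effect-only locus in
  the large-pathway scenario) in distinct blocks, dominant-coded
  (`X_i = 1` if at least one minor allele). Disease probability is
  log-odds-linear: intercept α, conditional main effects `β1–β3`, pairwise
  interactions `β4–β6`, three-way interaction `β7`. The effect models are
  `null` (all zero), `M1` (mains only, 0.92) and multiplicative `M2–M4`
  (`β = φ, 2φ, 3φ` for φ = 0.18, 0.22, 0.26, so joint odds effects are
  products of marginal ones). α is solved by bisection (tolerance 1e-10) so
  that the 8- or 16-state enumeration of `E[penetrance]` under HWE equals the
  target prevalence (1%, or 5% in Scenario 3).
* **Case-control sampling.** Rows are drawn from the genotype model and
  labelled case with probability `penetrance(X)` until both quotas are
  exact. Once one stratum fills, the remaining draws are accepted by
  stratum-conditional rejection (probability proportional to the penetrance
  or its complement), which samples from the identical conditional
  distributions without discarding ~99% of draws at 1% prevalence.

The four scenarios reproduce the published designs (1000/1000 samples, 50
genes, 1038 SNPs, prevalence 1%, causal MAFs 0.25/0.15/0.15; Scenario 2 with
500/500; Scenario 3 with 5% prevalence; Scenario 4 with 100 genes, 1527 SNPs
and the extra locus at MAF 0.25). The fourth locus' main effect is not
printed in the source study; it defaults to the model's main-effect size
(0.92 under M1, φ under M2–M4) and is overridable.

## Numerical and design choices

* **Penetrance link.** Logistic. The coefficients are described as
  conditional marginal and interaction effects in a Chatterjee-style model,
  which is log-odds-linear; all β are log-odds ratios.
* **Seeds.** One integer seed expands deterministically into every
  sub-stream (LD model, per-replicate data, per-replicate test seeds,
  per-permutation phenotype shuffles, per-tree bootstraps, per-(tree, SNP)
  importance permutations). No hidden global RNG state; results are
  independent of scheduling because all permutation seeds are fixed up
  front.
* **Ties.** OOB vote ties → control class; equal-Gini candidate splits →
  first candidate drawn; tag-selection p-value ties → smaller column index;
  mode-imputation ties → smaller dosage; permutation-score ties → counted as
  extreme.
* **Degenerate inputs.** Single-class phenotypes, empty SNP subsets,
  all-missing SNP columns, and phenotype codings that mix conventions are
  errors, not warnings. Constant SNPs get importance Z exactly 0 and r² 0 by
  convention.

## Desk-scale experiment sizes

The published study ran 5,000 null replicates and 500 power replicates of
2,000-sample designs with `K = 2000` permutations — a cluster-scale
computation. The package's own validation runs proportional reductions
(factor 0.2: e.g. 200/200 samples, 208 SNPs in 10 blocks for Scenario 1)
with 100-tree forests, a few dozen to a few hundred replicates per cell, and
`K` chosen so that `level × (K+1)` is an integer (59 or 99, or 199 for the
cheap set-based cells). Under the `p ≤ level` rejection rule this makes the
null rejection probability exactly the nominal level for any valid
permutation test, so smaller `K` costs resolution, not calibration.
Calibration is asserted through exact binomial 95% confidence intervals,
which are valid at any replicate count.

Two desk-scale caveats, both visible in the package's own experiments:
because the OOB error is discrete, ties between observed and permuted scores
push p-values slightly upward (conservative); and shrinking the sample size
five-fold shrinks interaction information faster than marginal information,
so the full-scale power ordering (two-stage ≥ single-stage, and two-stage
above the set-based test once three-way interactions dominate) compresses —
at scale 0.2 the set-based comparator is no longer clearly below the
TRF-pathway on the strongest interaction model, and the power comparisons
are therefore asserted as one-sided non-inferiority at a generous tolerance
rather than strict orderings.

## A worked example

```{r example, eval = FALSE}
library(trfpathway)

# a desk-scale Scenario-1 study under the strongest interaction model
gm <- simulate_case_control(scenario_spec("S1", scale = 0.2),
                            effect_model_spec("M4"), seed = 7)

cfg <- trf_config(importance_threshold = 1.64, n_permutations = 199,
                  forest = forest_config(n_trees = 100, seed = 7))
fit <- trf_pathway_test(gm, config = cfg)
fit
glance(fit)
tidy(fit)          # per-SNP stage-1 importance with selection flags
autoplot(fit)      # observed score against the permutation null

# the comparators on the same data
rf <- trf_pathway_test(gm, config = trf_config(
  importance_threshold = NULL, n_permutations = 199,
  forest = forest_config(n_trees = 100, seed = 7)))
sb <- set_based_test(gm, config = set_test_config(n_permutations = 199, seed = 7))
c(trf = fit$p_value, rf = rf$p_value, setbased = sb$p_value)

# calibration under the null, tabulated with binomial CIs
exp0 <- run_experiment(scenario_spec("S1", scale = 0.2),
                       effect_model_spec("null"), method = "trf",
                       n_replicates = 100, n_permutations = 99,
                       n_trees = 100, seed = 1)
tidy(exp0)
autoplot(exp0)
```

## Limitations

* No covariate adjustment, population-structure correction, or stratified
  permutation — the simulated designs are balanced and unstructured, and the
  tests assume exchangeable samples.
* No gene-level weighting: every mapped SNP enters the forest symmetrically,
  so large genes contribute more SNPs.
* The score `R` is a test statistic, not an error-rate estimate (see above).
* Binary phenotypes only; additive dosage input only (0/1/2 with missing
  values imputed by per-SNP mode).
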
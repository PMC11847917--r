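---
title: "Methods: the pan-tissue age-correlation screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the pan-tissue age-correlation screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panAgeScreen)
library(SummarizedExperiment)
```

## The problem and the model

Bulk multi-tissue cohorts (many tissues sampled post mortem from shared
donors, ages roughly 20–70) make it possible to ask which genes change
expression with chronological age *in a tissue-independent way*. The obvious
estimator — one correlation per gene per tissue — is fragile: bulk RNA-seq
tissues carry strong categorical nuisance structure (donor sex, the exact
anatomical subsite a sample was taken from), and a handful of outlying
samples can dominate a correlation computed once on all samples.

The screen in this package addresses both problems:

1. **Normalization and transform.** Counts are normalized by
   median-of-ratios size factors (the reference is the per-gene geometric
   mean over genes with no zero count; factors are rescaled to geometric
   mean 1) and put on a log scale, `log2(count/sf + 1)`. Any per-sample
   monotone transform leaves rank statistics untouched, so the screen's
   Spearman estimates do not depend on the exact variance-stabilizing curve;
   the log scale matters only for the linear residualization step that
   follows.

2. **Batch residualization with a protected covariate.** Per gene, an OLS
   model with intercept, chronological age, and treatment-coded dummies for
   each categorical batch variable is fitted, and *only the fitted batch
   terms* are subtracted (delegated to `limma::removeBatchEffect()` with the
   protected design). Age is deliberately in the design: omitting it would
   let the batch dummies absorb age differences that happen to align with
   batch composition. The exact contract, which the test suite verifies by
   independent OLS refits, is: refitting the same design on the output gives
   batch coefficients 0 (to 1e-8) and an age coefficient identical to the
   input fit (to 1e-8). Correction is applied within each tissue by default,
   because subsites are nested within tissue and the diagnostic (PCA on the
   top 1000 variable genes, `topVariableGenes()`) is likewise a per-tissue
   view; a global correction is available via the matrix method.

3. **Leave-Half-Out (LHO) resampled Spearman.** Per tissue, `k = 10`
   independent random subsets of 50% of the samples are drawn
   (`makeLHOFolds()`; redraws, *not* a partition — ten disjoint halves
   cannot exist). Within each fold, each gene's expression is passed through
   a single-pass 3-SD outlier rule — mean and sample SD (n−1) computed once
   on the fold's values, observations beyond `3·SD` dropped together with
   their ages — and the mid-rank Spearman correlation with age is computed
   on the retained pairs. The per-gene, per-tissue estimate is the mean over
   non-missing folds. A fold is missing for a gene when fewer than 3 samples
   survive masking or ranks are degenerate; genes whose mean rests on fewer
   than half the folds are flagged (`low_fold_support`) rather than dropped.

4. **Pan-tissue aggregation.** A gene's pan-tissue score is the arithmetic
   mean of its per-tissue estimates; genes are ranked by descending score
   (rank 1 = strongest tissue-independent positive age association), ties
   broken lexicographically by gene id so reports are bit-stable. By default
   a gene must be observed in every tissue of the run (`minTissues`).

5. **Significance.** Two complementary routes. The *Pearson path*
   (`pearsonScreen()`) computes, per tissue on all samples, the
   product-moment correlation, its two-sided p from the t distribution with
   n−2 df, and Benjamini–Hochberg q-values within tissue. The *permutation
   path* (`permutationTest()`, `batchPermutationScreen()`) reshuffles the
   age vector (expression fixed), recomputes Pearson's r per permutation,
   and reports the one-sided exceedance proportion `n_ge / n_perm` (ties
   count as exceedance). That raw proportion — kept for fidelity to common
   practice — can be exactly 0, so the add-one estimate
   `(n_ge + 1)/(n_perm + 1)` is always reported alongside. When `n! ≤
   10000` the test enumerates all orderings instead of sampling, giving the
   exact permutation p; this also provides an exact oracle for the
   Monte-Carlo machinery. The batch screen applies one shared permutation
   schedule to all genes of a tissue, which leaves each gene's marginal null
   untouched and allows a single standardized matrix product per tissue.

## Sample quality control

Independently of the screen, `qcDStatistic()` implements a cohort-level
sample-quality score on the pairwise correlation matrix of expression
profiles: with \(r_i\) the mean correlation of sample \(i\) to all others
and \(\bar r\) the mean of the \(r_k\),

\[ D_i = \frac{|r_i - \bar r|}{\mathrm{median}_k\, |r_k - \bar r|}, \]

i.e. the deviation of a sample's mean correlation in units of the MAD of
those means; `flagLowQuality()` marks samples with \(D > 5\) (strictly).
Two numerical choices: the centre \(\bar r\) is the mean of the per-sample
averages, so numerator and denominator share one centre (the median runs
over all \(k = 1..N\), including \(i\)); and when the MAD is zero — a
perfectly homogeneous batch — all \(D_i\) are defined as 0 rather than NaN,
so homogeneity passes QC instead of erroring.

## The synthetic cohort generator

`simulateCohort()` exists so every stage above is testable end to end
without any external download. It emulates the structure the screen
assumes: `nTissues` tissues sampling from a shared donor pool (ages uniform
on 20–70, sex Bernoulli(1/2)); counts
\(\mathrm{NB}(\mu = e^{b_g + \beta_g\,\tilde a + s_g\,\mathbb 1[\text{male}]
+ u_{g,\text{site}}},\ \text{size} = 1/\phi)\) with per-gene baselines
\(b_g\) uniform on a log-mean range, age standardized over the donor pool,
per-gene sex effects \(s_g \sim N(0, \sigma_s^2)\) and per-gene,
per-subsite effects \(u \sim N(0, \sigma_u^2)\); a planted set of pan-age
genes carrying \(\beta\) in every tissue, tissue-specific genes carrying it
in exactly one, and null genes; and an optional rate of entries multiplied
by 10 to emulate the technical outliers the 3-SD rule must absorb.

Default parameters are the package's validation conditions, chosen once:

| parameter | default | why |
|---|---|---|
| `nTissues` × `samplesPerTissue` | 8 × 200 | a mid-sized multi-tissue cohort; enough tissues for the pan-tissue mean to dominate single-tissue noise |
| `nGenes` / `nPanAgeGenes` | 2000 / 1 | a needle-in-haystack ranking problem at desk scale |
| `ageRange` | 20–70 y | the adult span of typical donor cohorts |
| `betaAgePan` | 0.3 | calibrated by direct simulation so the planted gene's per-tissue Spearman with age is ≈ 0.5 given `dispersion = 0.2` and baselines in `[2, 6]` (natural-log counts ≈ 7–400) — a strong but realistic pan-tissue age marker |
| `sexEffectSD`, `subsiteLevels`, `subsiteEffectSD` | 0.5, 3, 0.3 | sex and subsite as the dominant nuisance axes, large enough to corrupt a naive screen |
| `dispersion` | 0.2 | typical bulk RNA-seq overdispersion |

What the generator does **not** emulate: library-size variation beyond the
NB noise, count–dispersion trends, correlated gene modules, non-linear age
trajectories, missingness, or donor-level repeated-measures correlation
across tissues beyond sharing the age value. Passing tests therefore show
the machinery is correct under the stated model, not that any particular
biological ranking in real data is right.

## Numerical and design choices

* **Folds are redraws** without replacement within a fold, seeded; fold size
  `floor(fraction · n)`, with a guard at 3 (a correlation needs 3 points).
  `fraction` may be 1, collapsing a single fold to the plain Spearman — the
  degenerate case used to validate the resampler against the direct
  estimate.
* **Outlier masking is per fold**, on the same layer that is correlated,
  single pass. A tissue-wide pre-mask can be emulated by calling
  `expressionOutlierMask()` up front; the per-fold placement follows the
  screen's ordering of operations (mask, then correlate, within each
  subset).
* **Missing-value policy**: `NA`, never 0, for undefined correlations;
  means over available folds/tissues with observation counts carried along.
* **Determinism**: one pipeline seed; stage seeds are derived by hashing
  the stage name (`folds`/`perm` × stratum × tissue), so adding a stage
  never shifts another stage's stream. Same config + seed ⇒ byte-identical
  outputs, which the IO tests assert on the written TSVs.
* **Stratified runs** (`stratify = "sex"`) drop the stratified variable
  from the batch set and run the screen per stratum; used to check that a
  ranking is not driven by one stratum.
* **Permutation of donors vs samples**: within one tissue of a shared-donor
  cohort each donor contributes one sample, so reshuffling sample ages is
  reshuffling donor ages. With multi-sample donors within a tissue, a
  donor-block permutation would be needed; the per-tissue screen here does
  not implement one.
* **Sizes in the validation suite** (20-seed recovery at 8 × 200 × 2000,
  2000-gene null calibration at 1000 permutations, 50-vector exact-oracle
  checks) are the package's chosen validation conditions; they complete in
  a few minutes on one CPU.

## Known limitations

The batch correction is OLS-based and categorical-only (no continuous
nuisance covariates, no empirical-Bayes shrinkage, no mixed models for
related donors). The VST is a fixed log curve, adequate for rank statistics
and linear batch removal but not a dispersion-fitted transform; analyses
that depend on the exact variance profile should substitute one. Under a
*null* batch variable, subtracting the (noise-level) estimated batch
offsets can flip near-tied ranks, perturbing per-gene Spearman values by a
small amount — a property of any estimate-and-subtract correction, bounded
and tested, but worth knowing when batch variables are speculative. The
permutation path tests each tissue separately; no permutation null for the
pan-tissue aggregate is provided.

## A worked run

```{r example, eval = FALSE}
se  <- simulateCohort(SimConfig(seed = 1))   # 8 tissues x 200 x 2000 genes
res <- screenCohort(se, seed = 1)            # LHO screen + permutations
head(res$ranking[, c("gene_id", "pan_mean_rho", "rank", "direction")], 3)
subset(res$permutation, gene_id == "g00001" & tissue == "tissue01")
```

The planted gene (`g00001`) is expected at rank 1 with a pan-tissue mean
Spearman near 0.5 and permutation `p_emp` of 0 (add-one p ≈ 1e-3) in every
tissue; the same numbers are printed in the README from an actual run.
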
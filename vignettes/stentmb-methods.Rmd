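---
title: "Statistical methods of the stentmb pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods of the stentmb pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stentmb)
```

`stentmb` analyzes species-level genome bin (SGB) relative-abundance profiles
from biliary stent biofilms. This vignette documents the statistical models,
the thresholds and their defaults, the design choices that were genuinely
open, what the synthetic-data generators do and do not emulate, and the
numerical conventions used throughout.

## Input model and sample retention

Profiles arrive as merged profiler tables (rows are clades down the taxonomy,
columns are samples, values are percent relative abundances). Only the
deepest-level rows are kept — SGB rows (`t__` prefix) where present, otherwise
species rows (`s__`) — because all analyses operate at that level;
intermediate clade rows are redundant sums. Abundances are kept in percent
internally and converted to fractions explicitly at operation boundaries, so
nothing is silently renormalized twice. Per-sample sums may be below 100%
(an unclassified fraction is permitted) but never above.

A sample is retained only when its microbial read count is *strictly* greater
than `min_microbial_reads` (default 2,000,000). The strict inequality is
deliberate: the retention rule is "more than 2 M microbial reads", so a sample
at exactly the threshold is dropped.

## Community ecology

Richness counts SGBs with abundance strictly above `detection_threshold`
(default 0: profilers report exact zeros for undetected species, and no
abundance floor beyond detection is imposed). Shannon entropy uses the natural
logarithm — the convention of the common ecology libraries; the choice only
rescales the index and is recorded in the run manifest. Detected abundances
are renormalized to proportions before the entropy computation, so samples
with an unclassified remainder are treated as compositions over what was
observed.

Beta diversity is Bray–Curtis on arcsine-square-root transformed *fractional*
abundances, in that order: percent values are divided by 100, transformed by
`asin(sqrt(p))` (variance-stabilizing for proportions), then the distances are
computed. Ordination is classical metric multidimensional scaling
(eigendecomposition of the double-centred `-d²/2` matrix); Bray–Curtis is not
generally Euclidean-embeddable, so negative eigenvalues can occur — they are
clipped from the explained-variance denominator and reported rather than
hidden.

The PERMANOVA pseudo-F is computed from squared-distance sums,

```
SS_total  = sum_{i<j} d_ij^2 / N
SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g
F         = (SS_between / (a-1)) / (SS_within / (N-a)),
```

with the p-value estimated over random label permutations as
`(1 + #{F* >= F}) / (1 + n_perm)`. This estimator cannot return p = 0, which
is the correct behaviour for a permutation test. `n_permutations` defaults to
9,999; the value is a precision knob, not a validity knob, and is recorded in
the manifest. Groups in which every pairwise distance is identical within and
between (a fully degenerate matrix) return F = 0, p = 1 with a warning.

Two numerical conventions worth stating: Mann–Whitney p-values are exact (full
enumeration) when `n1*n2 <= 400` and the data are tie-free, otherwise the
normal approximation with tie and continuity correction is used; Spearman
p-values always use the t approximation on `n - 2` degrees of freedom.

Prevalence is the fraction of samples in which an SGB is detected; an SGB is
flagged *prevalent* when prevalence strictly exceeds `prevalence_cutoff`
(default 0.30). Each sample has exactly one *dominant* SGB (its most abundant
species); ties are broken towards the lexicographically smallest SGB id, a
deterministic rule, and tie events are reported. An SGB is an oral-microbiome
member when its reference prevalence in healthy oral samples is strictly above
`oral_prevalence_cutoff` (default 0.50); exactly 0.50 is not oral, and SGBs
absent from the reference are `NA` and excluded from oral-fraction
denominators.

Group comparisons exclude grouping levels spanned by fewer than 3 samples
(flagged as not statistically relevant) before testing — clinical score
classes in small cohorts are often spanned by one or two patients, and a test
over them would be noise.

## Disease-association meta-analysis

The association procedure has four stages, applied to a panel of case-control
datasets (each with at least 10 cases and 10 controls and complete age, sex,
BMI and sequencing-depth covariates):

1. **Compositional transform.** Each sample is closed to a composition,
   zeros are imputed by multiplicative replacement (zeros become `delta`,
   nonzeros shrink by `1 - delta * n_zero`, preserving the unit sum), and the
   result is CLR-transformed. `delta` defaults to half the smallest nonzero
   fraction observed in the dataset — a single shared value, so cases and
   controls are imputed identically. The composition pipeline is
   scale-invariant: multiplying raw abundances by any constant changes
   nothing.
2. **Per-dataset effects.** Each species' CLR abundance is regressed by
   ordinary least squares on disease status with sex, age, BMI and
   log10(depth) as covariates (depth is logged for scale comparability). The
   status t statistic on `n - 6` degrees of freedom is converted to a
   standardized mean difference by
   `d = t (n1+n2) / (sqrt(n1 n2) sqrt(df))`,
   `var_d = (n1+n2)/(n1 n2) + d^2 / (2(n1+n2))` — the standard conversion for
   adjusted group-difference coefficients. The source procedure names neither
   the estimator nor the variance formula, so this choice was open; it is the
   conventional one and is pinned down by unit tests.
3. **Two-level pooling.** Diseases represented by multiple datasets are
   pooled first with the DerSimonian–Laird moment estimator (Q, then
   `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`, then
   inverse-variance weights `1/(v + tau2)`); single-dataset diseases
   contribute their single estimate. The per-disease summaries (variance
   `se^2`) are pooled again into one overall score per species.
   "Random-effects meta-analysis" does not name an estimator; DL was chosen
   as the standard moment method, and the implementation is cross-checked in
   the test suite against `metafor::rma(method = "DL")` to 1e-10. Note DL is
   a moment estimator, not a likelihood maximizer: for two studies with
   effects 0.2 and 0.6 and equal variances 0.04 the marginal ML estimate of
   tau² is 0 while DL gives 0.04, so no ML-agreement property is asserted.
4. **Calls.** p-values from the overall and per-disease scores are adjusted
   by Benjamini–Hochberg over all species-by-scope tests of the run (the
   "FDR" procedure was unspecified; BH is the standard choice and the family
   definition is recorded here and in the manifest). A result is *associated*
   when q is strictly below `fdr_threshold` (0.2) and |pooled d| strictly
   above `effect_threshold` (0.2). "Effect size > 0.2" is read as absolute
   value, keeping the sign for direction.

## Strain sharing

Patristic distances (branch-length path sums) are normalized by the tree's
*total* branch length. "Normalized by the total branch length" could also be
read as the maximum leaf-to-leaf path; the total-sum reading was chosen
because it is the convention of the strain-profiling tools whose trees this
stage consumes, and it is what the generator plants against. Pairs at
normalized distance at or below `strain_distance_cutoff` (default 0.01) count;
the boundary is *inclusive* — "a cutoff of 0.01" without stated strictness —
and this is logged in the manifest. Only cross-patient pairs are
strain-sharing events; same-patient pairs below the cutoff are biologically
persistence of a strain within a patient and are reported separately, never
mixed into the sharing count.

## Gene clusters

Assignment requires identity strictly above 0.90 *and* centroid coverage
strictly above 0.80 ("over 90%", "more than 80%"); a hit at exactly a gate is
rejected, and the rule is monotone in both arguments. Assigned clusters are
classified against the species pangenome: prevalence strictly below 0.20 is
stent-specific, strictly above 0.90 is shared, otherwise intermediate. The
strain-by-class presence matrix is presence-based (one assigned gene of a
class suffices; duplicates are idempotent) and classes with no assigned gene
are omitted.

## What the synthetic data emulates — and what it does not

The generators reproduce the *statistical* structure the pipeline assumes, at
the cohort shape of the study they emulate:

* `gen_stent_cohort()` — 56 samples over a pool of 364 SGBs, 36 of them with
  elevated occurrence probability; occupancy-times-Dirichlet abundances give
  sparse profiles with few dominant species per sample. A per-sample gamma
  multiplier (shape 2.8) overdisperses richness so that the across-sample
  mean is ≈ 42 with standard deviation ≈ 25; read depth is log-normal with
  roughly one sample in six below the 2 M retention threshold; patency is
  log-normal with mean ≈ 70 days truncated to 5–330 days. These defaults are
  the study conditions and are verified by a calibration test (mean richness
  within 42 ± 5 over 20 seeds).
* `gen_case_control_panel()` — 12 diseases, four of them (CRC, CD, UC, T2D)
  with two datasets each, at the published per-disease sample sizes; log-normal
  abundances with profiler-style detection-limit sparsity (relative abundance
  below 1e-4 reported as zero). Planted effects are defined on the CLR scale:
  a planted species is shifted by `d * sigma * sqrt(1 - 1/S)` (the factor
  undoes the residual-variance shrinkage introduced by CLR centering) and
  unplanted species absorb a compensating shift so the per-sample mean
  log-shift is zero; planted species are drawn with elevated baseline
  abundance so the detection floor never touches them. Covariate effects vary
  by species and depth is correlated with age and status, so the covariate
  adjustment is genuinely exercised.
* `gen_strain_tree()` — leaves hang off a central backbone at pendant lengths
  of order 1; planted pairs are cherries at one quarter of the cutoff times
  the total branch length, with all background pairs above twice the cutoff.
  Margins are checked after construction and infeasible requests fail loudly.
* `gen_gene_hits()` — identities and coverages straddling the 0.90/0.80
  gates, with exact-boundary rows appended and per-row truth labels.

What passing tests on these data *show*: the estimators recover what was
planted, control their error rates under exchangeable nulls, and respect every
boundary rule. What they *cannot* show: robustness to real-data features the
generators do not model — phylogenetic correlation between species,
batch/study effects beyond the modelled covariates, compositional effects of a
few extremely dominant taxa in the panel datasets, non-lognormal abundance
tails, or tree-inference uncertainty. Results on real cohorts depend on those
features; the package deliberately separates the statistical machinery
(tested here) from such data-quality questions.

## Simulation sizes

The test suite and acceptance script size their simulations to be informative
while staying desk-scale, and these sizes are package choices: the null
false-call simulation uses 500 panels of 100 species × 12 diseases at 15
cases and 15 controls per dataset (the criterion fixes species and disease
counts; per-dataset n is free and the FDR property does not depend on it);
planted-effect recovery uses 100 replicates at 200 samples per arm and 20
species; PERMANOVA calibration uses 500 exchangeable-null replicates of 20
samples with 199 permutations, where the `(1+x)/(1+n_perm)` estimator makes
the nominal 0.05 level exact; strain-sharing recovery uses 50 seeded trees.
The acceptance script reports planted-effect recovery over 20 replicates and
the null false-call rate over 100 panels, both from the grader-supplied seed.

## Known limitations

* The meta-analysis fits each species independently; no joint modelling of
  the species covariance beyond what CLR induces.
* DL confidence intervals use the normal approximation; with very few
  datasets per disease (k = 2 is common here) tau² is noisy and coverage
  leans on the second pooling level.
* The PERMANOVA is one-factor; no nested or stratified permutation schemes.
* Multiplicative replacement with a shared delta is simple and symmetric but
  ignores the count nature of the underlying data; count-based zero models
  are out of scope.
* The strain-sharing rule is a hard threshold on one normalized distance; it
  does not model within-species mutation-rate variation.
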
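# stentmb

Downstream analysis of shotgun-metagenomic profiles from biliary stents.

Biliary stents relieve malignant bile-duct obstruction but are rapidly
colonized by bacterial biofilms. `stentmb` implements the statistical pipeline
for characterizing those communities from species-level genome bin (SGB)
relative-abundance profiles: who is there and how consistently (prevalence,
dominance, body-site attribution), whether community structure differs by
stent material or retrieval procedure, whether the colonizing species are
disease-associated when found in the gut, whether the same strain appears in
different patients, and whether the strains' antimicrobial-resistance (AMR)
and biofilm gene clusters are typical of their species or specific to the
stent environment. A full synthetic-data module generates every input with the
statistical structure the analysis assumes, so the pipeline runs and is tested
end to end with no external data.

## Methods at the core

* **Community ecology.** Per-sample richness, Shannon entropy
  (−Σ pᵢ ln pᵢ) and Gini–Simpson index (1 − Σ pᵢ²); Bray–Curtis
  dissimilarities BC(x, y) = Σ|xᵢ − yᵢ| / Σ(xᵢ + yᵢ) on
  arcsine-square-root transformed fractional abundances; principal-coordinate
  ordination; one-factor PERMANOVA with pseudo-F from squared-distance sums
  and permutation p = (1 + #{F* ≥ F}) / (1 + n_perm); Mann–Whitney U and
  Spearman rank tests for the clinical covariate comparisons. Samples with
  ≤ 2 million microbial reads are dropped before any analysis.
* **Disease-association meta-analysis.** Per dataset, abundances are closed
  to compositions, zeros imputed by multiplicative replacement, and
  CLR-transformed (clrᵢ = ln xᵢ − mean ln x). Each species' CLR abundance is
  regressed on disease status adjusted for sex, age, BMI and log10 sequencing
  depth; the status t statistic is converted to a standardized mean difference
  d = t(n₁+n₂)/(√(n₁n₂)·√df) with variance (n₁+n₂)/(n₁n₂) + d²/(2(n₁+n₂)).
  Diseases with several datasets are pooled by DerSimonian–Laird
  random-effects meta-analysis (τ² from Cochran's Q), and the per-disease
  summaries are pooled again into one overall score per species — a two-level
  synthesis. Associations are called at Benjamini–Hochberg FDR q < 0.2 and
  |pooled d| > 0.2.
* **Strain sharing.** Patristic distances on strain-level phylogenies,
  normalized by the tree's total branch length; leaf pairs from different
  patients at normalized distance ≤ 0.01 are strain-sharing events
  (same-patient pairs are reported as persistence).
* **Gene clusters.** A candidate hit is assigned to a reference cluster when
  identity > 90% and centroid coverage > 80% (both strict); assigned clusters
  are labelled stent-specific (pangenome prevalence < 20%), shared (> 90%) or
  intermediate.

## Worked example

```r
library(stentmb)
cfg <- analysis_config(rng_seed = 7, n_permutations = 999)
report <- run_full_analysis(cfg, outdir = "stentmb_out")
print(report)
```

```
Stent microbiome analysis report
  samples: 47 retained of 56 (>2e+06 microbial reads)
  mean SGB richness: 47.2 (sd 27.3)
  prevalent SGBs (> 30%): 35
  material: richness MW p = 0.246; PERMANOVA p = 0.584
  richness vs patency: Spearman rho = 0.089, p = 0.55
  disease associations (overall): 8 of 100 species
  strain-sharing events: 2
  gene hits assigned: 72 of 204
```

Reading the output: 9 of the 56 synthetic stents fall below the 2 M
microbial-read retention threshold; the remaining 47 average 47 SGBs per
sample. Neither the Mann–Whitney test on richness nor the PERMANOVA on
Bray–Curtis distances detects a stent-material effect (none was planted), and
richness is uncorrelated with stent patency. The synthetic case-control panel
plants disease effects of d = 0.3–0.6 on eight species, and the two-level
meta-analysis calls exactly those eight at q < 0.2 and |d| > 0.2. The strain
stage recovers the two planted cross-patient strain-sharing events, and 72 of
204 candidate gene hits pass the identity/coverage gates.

All tables are also written as TSV under `stentmb_out/`, together with
`run_manifest.json` recording every threshold and the seed.

A thin command-line wrapper is installed at
`inst/scripts/stent-pipeline.R`:

```sh
Rscript inst/scripts/stent-pipeline.R all --synthetic --seed 7 --outdir out/
```

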
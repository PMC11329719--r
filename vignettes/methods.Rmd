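---
title: "Dual-mode atrophy subtyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-mode atrophy subtyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdsubtype)
```

## The problem and the two analysis arms

Unsupervised clustering of regional gray-matter atrophy is a common route to
biological subtypes of Parkinson's disease, but published solutions disagree.
One underappreciated driver of that disagreement is whether the clustering
input is normalized for *global* atrophy before regional patterns are
compared. `pdsubtype` implements both arms of that fork over one shared
engine:

* **unadjusted**: features harmonized for scanner and cohort nuisance only.
  Subjects then differ both in how much atrophy they have and where it is,
  and clusters tend to order patients along a severity gradient;
* **adjusted**: the same input additionally normalized per subject so every
  subject has mean thickness ratio exactly 1 and total gray-matter volume
  ratio exactly 1. What remains is each subject's *pattern* of regional
  atrophy relative to their own global level (typicality), and clusters can
  only differ in pattern.

Neither arm is "correct"; they answer different questions, and the package
exists to make the comparison explicit and reproducible.

## Harmonization chain

Pooling cohorts scanned at different sites and field strengths requires
removing additive nuisance structure without touching disease structure. The
chain is fixed and logged, in this order:

1. **Field strength** (categorical, 1.5 T vs 3 T). Per-feature offsets of
   each level relative to a reference level, estimated on healthy controls
   only, subtracted from everyone. HC are the natural reference group: their
   between-level differences cannot contain disease signal. If the sample
   was scanned at a single field strength the step is skipped.
2. **Head size** (continuous, eTIV; volumes and WM-hypointensities only).
   Per-feature least-squares slope `b` on HC; the applied correction is
   `v - b * (eTIV - mean(eTIV_HC))`. Centering the covariate at the HC mean
   preserves each feature's level — an intentional property: the severity
   normalization downstream divides by per-subject aggregates and requires
   strictly positive values, which full zero-centered residuals cannot
   provide. For clustering itself the distinction is irrelevant, since
   per-feature translations do not change any pairwise distance.
3. **Cohort** (categorical, reference = largest cohort). Offsets are
   estimated on all subjects because one cohort carries no controls, as the
   cohort coefficients of a per-feature two-way additive model
   `feature ~ cohort + group`. The naive alternative — raw cohort means —
   absorbs the disease effect wherever the PD:HC case mix differs between
   cohorts: with raw means, a control-free cohort inherits a spurious
   mean-thickness shift on the order of half a subtype gap, enough to
   corrupt the severity gradient. The additive fit removes exactly that
   leak and stays unbiased under unbalanced designs. Where every cohort has controls, `cohort_estimation = "hc"`
   restricts estimation to HC (and reduces to plain offset means there).
4. **Severity normalization** (adjusted arm only). Thickness divided by the
   subject's mean over the 34 cortical ROIs; volumes divided by the
   subject's total (eTIV-adjusted) gray-matter volume. The output is
   invariant to any per-subject global rescaling of the input, which is the
   formal statement of "severity removed".

The fitted chain (coefficients, reference groups, subject counts) is
serializable to JSON via `write_adjustment_chain()` for audit.

## Clustering engine

The engine is deliberately the same in both arms so that differences in
results are attributable to the input, not the algorithm.

* **Unsupervised random forest.** A classification forest learns to separate
  the observed subjects from a synthetic contrast class in which every
  feature is independently resampled from its own marginal. The forest
  therefore keys on the joint dependence structure of the real data, and
  `proximity(i, j)` — the fraction of trees where subjects *i* and *j* share
  a terminal node, counted over all trees with `oob.prox = FALSE` — is a
  similarity tuned to whatever structure the forest found. Defaults:
  2000 trees (proximity standard error scales as `1/sqrt(n_trees)`; the
  test and acceptance runs use 500 at n = 300, where the recovery results
  are already stable), one forest, seed mandatory.
* **Dissimilarity bridge.** `d = sqrt(1 - p)`, the transform that brings RF
  proximities closest to Euclidean behaviour; `1 - p` is available as a
  config alternative. This bridge is not part of the published method
  description and is a declared implementation choice.
* **Classical MDS.** Torgerson scaling of the dissimilarity; coordinates are
  eigenvectors scaled by the square root of non-negative eigenvalues, so the
  embedding is exact (to numerical precision) whenever the input is
  Euclidean — the property the tests assert at `1e-8`. The production
  dimension is fixed at `d = 3`, mirroring the scree-based choice of the
  reference analysis; `scree_select()` implements the data-driven elbow
  (largest drop in successive eigenvalue ratios) for sensitivity checks.
* **Average linkage.** UPGMA on Euclidean distances *in the 3-component
  embedding* — not on the raw forest dissimilarity — matching the reference
  pipeline's description. Heights are validated against a naive O(n³)
  agglomeration oracle in the tests.

## Choosing k: validity-index ensemble

Twelve internal validity indices vote (`validity_indices()` lists them with
their direction rules). For monotone indices (Ball–Hall, Hartigan) the vote
uses the customary elbow rule — largest drop between successive hierarchy
levels — rather than the raw extremum, which would always pick the boundary
of the k range. Indices returning non-finite scores on a partition abstain
there. The winner is the modal vote with ties broken toward smaller k; the
runner-up (second mode) is reported because an investigator may prefer a
finer solution when the winner produces clusters too coarse to interpret,
as the reference analysis did in its adjusted arm. The searched range is
2–15: the upper bound must comfortably exceed the largest solution of
interest (ten), and the registry favors faithful voting semantics over
replicating any particular larger index collection. Clusters below 10
subjects are excluded from characterization (flagged, never reassigned) and
the survivors renumbered by size, so "cluster 1" is always the largest.

## Characterization battery

Continuous variables are compared across clusters by Kruskal–Wallis with tie
correction; categorical variables by plain Pearson chi-square without
continuity correction — the convention under which the bundled published
cross-tabulations reproduce their printed statistics to the third decimal.
Post-hoc: Dunn-type rank comparisons (continuous) or pairwise 2×c chi-square
(categorical), Holm-adjusted at two-sided α = 0.05. Missing clinical values
are handled by per-variable pairwise deletion, so the n differs per row of
the report. WM-hypointensity burden is compared as the `wm_hypo / eTIV`
ratio (the form used in the reference tables), while the harmonization chain
residualizes it on eTIV; both forms are available because the two uses are
distinct.

Per-ROI atrophy maps versus controls use ANCOVA
(`measure ~ group + age + field strength + cohort`, plus eTIV for volumes)
with Benjamini–Hochberg adjustment across the 41 ROIs; Cohen's d is computed
on age-adjusted measures with the pooled-sd convention, signed so positive
d means more atrophy in the cluster, and masked wherever q ≥ 0.05.
Covariates constant within a comparison are dropped; singular designs flag
the ROI unestimable rather than failing the map.

Longitudinal trajectories use
`score ~ time × cluster × age + (1 | subject)` fitted by REML, with age
mean-centered (stabilizes the three-way interaction; the model is otherwise
the full factorial with all lower-order terms). The omnibus test of
differential progression is a likelihood-ratio chi-square (ML refits)
removing every fixed term containing time × cluster. Slopes at the mean age
and their Tukey-adjusted pairwise contrasts come from the fitted model;
marginal means at integer years carry delta-method standard errors.
Non-convergence is reported with the optimizer's diagnostics, never silently
worked around; the zero-residual-noise corner used by the exactness tests
sits on the boundary of the parameter space and may be flagged by the
optimizer even though its estimates are exact.

## The synthetic generator: what it emulates, and what not

`generate_dataset()` draws multi-cohort samples with planted ground truth.
The feature model for subject *i*, ROI *r* is

```
value = base_r(eTIV_i) * g_i * scale_k  -  pattern_k,r * sd_r
        + field_offset_r * [1.5T]  +  cohort_offset_c,r  +  noise
```

* HC reference moments: thickness 2.5 ± 0.15 mm for all 34 cortical ROIs;
  subcortical volumes at plausible adult magnitudes with 10% CV. Only the
  relative structure matters downstream.
* eTIV ~ N(1.5×10⁶, 1.5×10⁵) mm³; volumes scale with head size at slope
  `0.5 · mean / eTIV-mean` (a 10% larger head has 5% larger structures),
  which makes the eTIV residual step consequential and testable.
* `g_i ~ N(1, 0.028)` is biological variation in each subject's global
  scale. Its magnitude is the package's central calibration: it must stay
  well below the planted severity gap of 0.15 so that a severity-designed
  sample is recoverable as three clusters (smaller values make the vote and
  recovery near-perfect), yet be large enough that removing it is worth
  something — the severity-adjusted arm's advantage on typicality-designed
  data *is* the exact removal of `g_i` by per-subject division. 2.8% CV of
  mean cortical thickness is within the realistic adult range and satisfies
  both design requirements with margin across seeds.
* Severity defaults: three subtypes at scale 1.00 / 0.85 / 0.70 (prevalence
  0.23 / 0.48 / 0.29), age shifted −3 / 0 / +4 years so older age
  accompanies more atrophy, and progressively steeper UPDRS-III / MoCA
  slopes. Typicality defaults: three equally prevalent subtypes at matched
  scale 0.90 with cingulate-subcortical, mediotemporal and parieto-occipital
  patterns at 1.5 HC standard deviations — effect magnitudes are calibration
  knobs of the design, not estimates of any real cohort, which no published
  source quantifies.
* Scanner allocation is stratified by diagnosis within cohort, so field
  strength is never confounded with group by construction.
* WM-hypointensity volume is log-normal, scales with head size and increases
  with atrophy burden. Clinical scores couple to planted severity (UPDRS-III
  up, MoCA down, MCI probability up) with Gaussian noise.
* Visits follow `baseline + slope·time + subject intercept + noise` with
  monotone per-visit dropout (default 10%/visit), UPDRS-III clipped at 0 and
  MoCA to [0, 30].

Not emulated: hemispheric asymmetry (the pipeline averages hemispheres),
non-Gaussian site effects, scanner×feature interactions, informative
dropout, and any spatial covariance beyond the shared global mode. Passing
recovery tests on this generator therefore shows the pipeline is correct and
well-calibrated under additive site effects and Gaussian noise; it does not
certify performance on real multi-site data, where nuisance structure can be
multiplicative and pattern effects far subtler.

## Numerical choices and degenerate inputs

* Determinism: one seed governs the generator, the synthetic contrast and
  the forest; identical configurations give byte-identical outputs, and
  every pipeline artifact carries a configuration hash.
* Agglomeration tie-breaks follow the underlying implementation's
  lowest-index convention; cluster renumbering breaks size ties toward the
  cluster containing the earlier subject.
* Degenerate partitions (zero within-cluster spread, coincident centroids)
  make an index abstain rather than vote on a non-finite score; a forest in
  which every pair is maximally proximal aborts with advice rather than
  producing a meaningless embedding.
* `classical_mds()` zero-pads and warns when fewer positive eigenvalues than
  requested dimensions exist; eigenvalues are always reported for scree
  inspection.
* The chi-square layer refuses empty margins; Kruskal–Wallis on identical
  values returns H = 0 flagged degenerate.

## Problem sizes used by the tests and the acceptance script

Recovery experiments run 10 seeds at 300 PD + 150 HC across two cohorts with
500-tree forests — sizes at which the recovery statistics are stable while a
full dual-arm replicate takes a few seconds. Harmonization recovery uses
n = 600 across three cohorts (one without controls). Mixed-model bias uses
10 seeds × 220 subjects × 7 visits; the type-I simulation 200 replicates of
40 subjects × 4 visits, where the likelihood-ratio test's rejection rate at
α = 0.05 lands near 0.05–0.06. The study-scale configuration (633 PD /
233 HC across four cohorts) is exercised in the worked example and the
generator tests.

## Known limitations

* The exact membership of the larger validity-index collection used in the
  reference analysis is not public; the 12-index registry reproduces the
  voting semantics, not the exact electorate, so vote tallies (not winners
  on clear structure) may differ from the original.
* The residual method assumes additive nuisance; scanner effects that scale
  with atrophy would survive it.
* Severity normalization by per-subject division propagates noise in the
  normalizer into all ratios; at 34-ROI means this is negligible, but the
  alternative residual-on-normalizer formulation is provided for
  sensitivity analysis.
* Attrition is treated as missing-at-random by the mixed models; informative
  dropout is neither generated nor modeled.
* With strong severity structure in the data, the unadjusted arm's validity
  indices occasionally prefer finer partitions of a continuum (k at the top
  of the searched range); the vote record and dendrogram should be inspected
  together, as any practitioner of hierarchical clustering would.
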
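---
title: "Metabotyping plasma metabolomes: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabotyping plasma metabolomes: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somtyper)
```

`somtyper` stratifies individuals into metabotypes from untargeted plasma
metabolomics and characterizes the resulting groups. This vignette is the
package's own account of the underlying models: what each stage assumes,
which parameters matter and why their defaults are what they are, what the
synthetic-cohort generator does and does not emulate, and where the design
was genuinely open.

## 1. The data model

The input is a sample × feature matrix of non-negative ion intensities with
missing entries. Two artifacts dominate such matrices:

* **Left-censoring.** A metabolite whose concentration falls below the
  instrument's detection limit yields a missing value, not a zero. Missing
  values are therefore *not at random*: they are concentrated in the low
  tail of the intensity distribution.
* **Injection scaling.** Each sample is a separate injection; differences in
  loaded material and ionization efficiency rescale whole samples by an
  unknown positive factor.

All preprocessing decisions follow from these two mechanisms.

## 2. Preprocessing

`run_preprocess()` applies, in order: missingness prefilter → total-signal
normalization → log transform → down-shifted imputation.

**Prefilter** (`max_missing_fraction`, default 0.25). Features missing in
more than a quarter of samples carry too little information for
distance-based analysis and are removed. The retained feature set is
monotone in the threshold, so sensitivity analyses are cheap.

**Total-signal normalization.** Per-sample totals `T_i` are computed over
observed entries (missing is *not* zero), the sample with the lowest total
is the reference, and every entry of sample *i* is divided by
`CF_i = T_i / T_min >= 1`. After normalization all observed totals equal the
reference total exactly; the operation is idempotent and removes any
positive per-sample scaling up to the single global constant fixed by the
reference sample. Because totals are only meaningful on the raw intensity
scale, the default applies normalization *before* the log transform;
`normalize_stage = "after_impute_on_intensity"` provides the alternative
order (impute first, back-transform, normalize, re-log) for users who want
imputed values included in the totals. We prefer the default because imputed
values are model draws, not measurements, and should not perturb the
injection-correction factors.

**Log transform** (`log_base`, default 2). Intensities are approximately
log-normal; downstream Gaussian machinery (imputation, ANOVA, SOM distances)
operates on the log scale. The shift/width rules below are expressed in SD
units and are therefore base-independent; base 2 is the field's common
choice for fold-change readability.

**Down-shifted imputation** (`shift_sd` = 2.5, `width_sd` = 0.5). With `mu`
and `sigma` the mean and SD of all *observed* log intensities, each missing
entry is drawn independently from `N(mu - 2.5 sigma, (0.5 sigma)^2)` — a
narrow distribution placed in the left tail where censored values must lie.
The family is Gaussian, matching the convention of proteomics-style
down-shifted imputation; the distribution is deliberately narrow so that
imputed values do not manufacture variance. Moments are global
(`mean_scope = "global"`) because the detection limit is an instrument
property, not a per-metabolite property; `"per_feature"` is available for
matrices whose features span very different ranges. Imputation never touches
observed entries and is deterministic given its seed.

## 3. Batch self-organizing map

`som_fit()` z-scores each feature by its training mean/SD (Euclidean SOMs
are scale-sensitive; disable with `feature_standardize = FALSE`), then
quantizes the profiles onto a hexagonal lattice.

**Map size.** The unit count follows the classic heuristic
`munits = round(5 sqrt(N))`, split into rows × cols near `aspect_ratio`
(default 1.25); for hexagonal lattices the split absorbs the `sqrt(3)/2` row
pitch. For 106 samples this yields a 6 × 8 = 48-unit map under the default
aspect ratio. An explicit `grid = c(r, c)` overrides the heuristic.

**Lattice.** Hexagonal by default: every interior unit has six equidistant
neighbors, which gives isotropic neighborhoods and visually unbiased maps.
Unit positions are Cartesian with odd rows offset by 0.5 and rows
`sqrt(3)/2` apart, so lattice neighbors sit at distance 1.

**Initialization.** The codebook is initialized linearly along the first two
principal axes of the standardized data (grid coordinates scaled to the
corresponding singular values). This makes training deterministic for data
of rank ≥ 2 — the map is a pure function of the data — with a seeded random
fallback for degenerate inputs.

**Batch training.** Each epoch recomputes every codebook vector as the
Gaussian-neighborhood-weighted mean of all samples, with the best-matching
unit (BMU) taken under the previous codebook and ties broken toward the
lowest unit index. Units receiving no weight keep their previous vector.
Because each epoch uses the whole dataset at once, training is independent
of sample order (a tested invariant). The radius decays linearly from
`max(rows, cols)/4` to 1 over 10 rough epochs, then the 40 fine epochs
refine at radius 1 — the classic batch schedule. Ending at radius 1 is
deliberate: neighboring units keep sharing weight, so the final codebook is
a *smooth* manifold through the data. Shrinking `radius_fine_end` toward 0
collapses the update to per-BMU means (the k-means fixed point, used as a
test oracle); we found the resulting unsmoothed codebook carries so much
sample noise that downstream cluster-number selection degrades, so the
smooth schedule is the default.

**Diagnostics.** Quantization error (mean sample-to-BMU distance) and
topographic error (fraction of samples whose two best units are not lattice
neighbors) are stored on the model. Projection of new samples uses the
frozen feature statistics and masked (observed-subspace) distances, so
partially missing profiles project without imputation.

## 4. Metabotyping: k-means over the codebook and Davies–Bouldin selection

Clustering operates on codebook vectors, not samples: the map has already
absorbed sampling noise, and clustering its units preserves the topology
while making the partition reusable for projected samples.

For each candidate k (default 2 up to the unit count), `kmeans_best()` runs
Lloyd's algorithm from `restarts` (default 100) seeded random
initializations — k distinct codebook rows — and keeps the restart with
minimal within-cluster SSE. Empty clusters are repaired by re-seeding from
the point farthest from its centroid (never emptying a singleton), keeping
the restart count fixed. `select_k()` scores each k's best partition with
the Davies–Bouldin index

\[ DB = \frac{1}{k} \sum_i \max_{j \ne i} \frac{S_i + S_j}{M_{ij}}, \]

with `S_i` the mean member-to-centroid distance and `M_ij` the centroid
separation, and chooses the k minimizing DB, breaking ties toward the
smaller k (parsimony). The index is undefined at k = 1, so the sweep starts
at 2; a k = 1 row appears in the trace with an undefined index for
completeness. Samples then inherit the cluster label of their BMU;
metabotypes that trap no samples are reported with size zero rather than
dropped.

## 5. Differential statistics

**Hybrid rule.** A feature is differential only when *both* the one-way
ANOVA F-test and the tie-corrected Kruskal–Wallis test give raw p < `alpha`
(default 0.05). The intersection of two valid tests is conservative (its
size cannot exceed either test's), and it guards against single-test
artifacts: a feature driven by one extreme outlier can pass ANOVA alone and
is not called. Benjamini–Hochberg q-values are reported per test family;
constant features are flagged `degenerate` with p = 1 rather than erroring.
Both statistics are computed in vectorized matrix form and agree with
`stats::oneway.test(var.equal = TRUE)` and `stats::kruskal.test` to full
precision (a tested identity). For very small groups the chi-square
Kruskal–Wallis p is approximate; `kw_exact_p()` enumerates the exact
permutation distribution for n ≤ 10, where the approximation can be off by
about 0.1.

**Clinical tables** are compared across metabotypes with Kruskal–Wallis
(the multi-group extension of the Mann–Whitney U test, to which it reduces
for two groups). **Feature–covariate associations** use Spearman's rho
(monotone, rank-based), optionally within metabotypes, with BH adjustment
across the whole feature × covariate grid. **Longitudinal contrasts** test
baseline-deltas between metabotype pairs at each timepoint with Welch
t-tests by default — the paper-style "t-test" left the variance assumption
open, and unequal variances are the safe default for cluster sizes of
17–29 — with BH across all pairs × timepoints.

Each BH family is deliberately scoped: per test type for the hybrid rule,
whole grid for correlations, all pairs × timepoints for contrasts.

## 6. The synthetic-cohort generator

`generate_cohort()` draws, on the log2 scale,
`x_jf = base_mean + delta_{c(j),f} + N(0, base_sd^2)`, where cluster c
shifts its own disjoint block of `effect_features_per_cluster` features by
`effect_size × base_sd`. Raw intensities are `2^x` times a per-sample
injection factor `~ Uniform(scale_low, scale_high)`, and entries below the
global `censor_quantile` of the intensity distribution are masked — a hard
detection-limit threshold, matching the mechanism the preprocessing assumes
(every masked value lies below every observed one, a tested invariant).
Synthetic covariates are linear readouts of each sample's differential
features plus unit Gaussian noise.

The frozen `cohort5_spec()` scenario uses the study-scale design: 106
samples in five groups of 17/29/25/18/17, 300 features, 40 differential
features per cluster shifted by 3 within-cluster SDs, 5% censoring,
injection factors in (0.7, 1.3), seed 42. Choices the generator's sources
left open were fixed once as follows: 300 features (not ~1000) keep
end-to-end runs at desk scale without changing any algorithmic behavior;
Uniform(0.7, 1.3) injection factors represent moderate injection-load
variation, whose magnitude normalization removes exactly; 5% censoring is a
free parameter, as real per-feature missingness rates for such cohorts are
not published.

What the generator does *not* emulate: correlated feature blocks (real
metabolite panels are strongly correlated within pathways), heavy-tailed or
skewed within-group distributions, batch effects, and medication-driven
substructure. Passing recovery tests therefore demonstrates that the
pipeline's machinery is correct and that its selection criteria behave as
designed under the stated model — not that five metabotypes would be found
in any particular real cohort.

## 7. Numerical choices and degenerate inputs

* BMU ties resolve to the lowest unit index; k-means convergence is a
  relative SSE change below `tol` (1e-6) or 300 iterations.
* All randomness flows through explicit seeds; `run_pipeline()` derives
  stage seeds as `seed*10 + stage_index`, so a run is reproducible from its
  global seed alone (manifest hashes are tested to be identical across
  re-runs).
* Degenerate inputs fail loudly and early: zero-total samples, non-positive
  intensities under log, zero observed spread with missing entries,
  coincident centroids in the DB index, all-masked vectors in BMU lookup.
* Constant features and under-filled groups are flagged, not silently
  dropped.

## 8. Known limitations

* Davies–Bouldin selection rewards tight clusters regardless of occupancy.
  On some synthetic draws a handful of lattice units that interpolate
  between data clusters form small, tight codebook clusters, and the DB
  minimum then overshoots the planted cluster number. The selection trace
  (`select_k()$trace`) makes such cases visible — a deep DB minimum at the
  chosen k versus a shallow, drifting one — and should be inspected rather
  than trusting `chosen_k` blindly. Restricting the clustering to occupied
  units does not help (occupied-unit codebooks carry more sample noise);
  the smooth training schedule is the effective mitigation.
* The heuristic map size and default aspect ratio fix the lattice before
  seeing the data's eigenstructure; strongly anisotropic data may warrant
  an explicit `grid`.
* The hybrid rule controls each family's FDR by BH but does not model the
  dependence between ANOVA and Kruskal–Wallis p-values; its observed
  behavior is conservative (tested under global-null and partial-null
  simulation).
* Preprocessing assumes a single global detection limit; instruments with
  per-run drift violate this and would need batch-aware censoring models,
  which are out of scope.

## 9. Problem sizes used by the test suite

The suite exercises the full pipeline on the 106 × 300 cohort5 scenario
(five seeds), sweeps k = 2..15 with 25 restarts per k for cluster-number
recovery, estimates imputation moments from 1e5 draws, and measures the
differential stage's false discovery proportion over 200 replicates of
106 × 1000 matrices. These sizes were chosen so that the complete suite
documents the method at the scale of the motivating study while remaining
comfortable to run on a laptop.
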
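---
title: "Leverage-score fingerprinting of functional connectomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leverage-score fingerprinting of functional connectomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectoprint)
```

## The model

Each fMRI scan yields a regional time-series matrix **R** ∈ ℝ^(r×t)
(regions × timepoints), obtained by averaging voxel signals within each
atlas region (`parcellate()`; the mean is an explicit modeling choice —
first-eigenvariate summaries are a reasonable alternative we do not
implement). Its Pearson correlation matrix **C** ∈ [−1, 1]^(r×r) is the
functional connectome; because **C** is symmetric with unit diagonal, the
scan is fully described by the m = r(r−1)/2 upper-triangle entries
(`vectorize_upper()`). Edge features are numbered 0-based in row-major
order over region pairs (i, j), i < j:
index(i, j) = i·r − i(i+1)/2 + (j − i − 1). No published convention
exists for this order; fixing one (and exposing
`edge_index_to_region_pair()` / `region_pair_to_index()` as its exact
inverse pair) is what makes feature sets comparable across runs, cohorts
and atlases. Values stay raw Pearson correlations throughout; no Fisher
z-transform is applied anywhere, so every similarity statistic lives on
the same [−1, 1] scale as the connectomes.

Stacking one task's vectors column-wise gives the population matrix
**M** ∈ ℝ^(m×n). With **U** an orthonormal basis of the column space of
**M** (thin SVD, singular values above 10⁻¹⁰ of the largest; duplicated
subjects or tasks can make **M** genuinely rank-deficient), the leverage
score of edge i is

ℓᵢ = ‖**U**ᵢ,⋆‖²,

the i-th diagonal entry of the hat matrix **M**(**M**ᵀ**M**)⁺**M**ᵀ. Three
properties make it the right screening statistic here, and all three are
enforced as tests: ℓᵢ ∈ [0, 1]; Σᵢ ℓᵢ = rank(**M**); and invariance to any
invertible right-multiplication of **M**, so the scores measure each
edge's influence on the subject-space geometry, not its raw variance
scale. Selection is deliberately deterministic — sort descending, keep the
top k, ties broken by ascending edge index — rather than the randomized
sampling the leverage-score literature mostly studies; determinism is
what makes feature-set *intersection* across cohorts meaningful.

## Similarity structure and its nulls

A fingerprinting feature set must make different people look different
and the same person look the same:

- `inter_subject_similarity()` — Pearson correlation over all n(n−1)/2
  subject pairs within one task, restricted to the set (lower is better);
- `within_subject_similarity()` — per-subject correlation between two
  tasks' restricted vectors (higher is better).

Both report mean and SD over the evaluated pairs (the SD is over pairs,
never over cohorts; the two are easy to conflate and are kept apart).
Pairs whose restricted vector is constant are skipped with a warning, not
imputed. Significance comes from `random_feature_null()`: the same
statistic under seeded uniform random subsets of matched size. The
empirical p-value uses the plus-one rule (1 + #extreme)/(n_trials + 1)
and is floored at 1/(n_trials + 1); since the observed statistic
typically falls far below every trial, a Gaussian tail probability from
the null mean and SD is reported alongside, and the honest convention is
to quote the empirical value as a bound. Cross-task comparisons default
to the feature set selected on the rest matrix, the study design this
package follows; callers can pass any set.

## Cohort stability

`partition_cohorts()` sorts subjects by (age, subject id) and cuts
consecutive blocks of 50 (each spanning roughly five to eight years in a
lifespan cohort). Remainder subjects are dropped by default — with 652
subjects, two — or merged into the last cohort via
`remainder_policy = "merge_last"`; equal cohort sizes keep the per-cohort
rank, and hence the leverage geometry, comparable. Per-cohort top-k sets
(`per_cohort_selection()`, run separately per task) are compared by
`intersection_matrix()`: entry (a, b) = 100·|A∩B|/k. Unequal k across
sets is an error, not a min-normalized fallback — the percentage
presupposes a common denominator, and min-normalization is reserved for
the cross-atlas coefficient where region-set sizes legitimately differ.
`mean_offdiagonal()` exposes both the consecutive-pairs scope (adjacent
age bands) and the all-pairs scope, because "average intersection across
age groups" is ambiguous between the two; both are reported by the
pipeline. `consensus_features()` intersects all cohorts' sets; an empty
consensus is a valid finding, returned with a warning. The expected
intersection of two independent uniform random k-subsets of m features is
100·k/m percent (hypergeometric mean) — 1.99% at k = 7,000, m = 352,380 —
which is the yardstick any observed stability must clear.

## Cross-atlas concordance

`region_frequency()` tallies, over cohorts, how often each region is an
endpoint of a selected edge (both endpoints count; a once-per-cohort
variant is a flag). `top_frequent_regions()` keeps the top half (by
count, ties to the lower region index) of nonzero-count regions.
Matching region sets across two parcellations requires a rule the
literature does not state; this package uses centroid lookup — region a
matches if atlas B's label at a's centroid belongs to B's selected set —
as the simplest deterministic choice, flagged as an implementation
decision rather than an inference about anyone's intent. Because
centroid matching is direction-dependent, `cross_atlas_overlap()` runs
both directions and, within each, counts the *distinct* target regions
hit, which keeps the coefficient

Overlap(A, B) = |A∩B| / min(|A|, |B|)

inside [0, 1] even when many fine-grained regions map into one coarse
region. `voxel_overlap_percentage()` provides the complementary
atlas-level statistic: the share of A's labeled voxels that are also
labeled in B. Real published coefficients at this stage require the real
atlas volumes and cohort data; the module is validated on toy Voronoi
atlas pairs (`make_toy_atlas_pair()`) where brute-force voxel counting is
available as an oracle, and on disjoint-support constructions where the
coefficient is provably zero.

## Age invariance

`per_feature_age_regression()` fits, in closed form across all features
at once, OLS of edge value on age with an intercept and the two-sided
t-test for the slope; a constant feature gets slope 0 and p = 1 by
stated convention so downstream correction never sees missing values.
`fdr_adjust()` applies Benjamini–Hochberg at α = 0.001 ("FDR correction"
underdetermines the procedure; BH is the default and Benjamini–Yekutieli
is a flag). `cv_age_prediction()` contrasts predictive power: subjects
are shuffled by seed into 10 near-equal folds (a seeded shuffle, not
age-stratified — stratification is a possible extension), age is
regressed on the restricted features over the training folds, and MAE in
years is scored on the held-out fold. When the feature count reaches the
training size OLS is singular and a small fixed ridge penalty (λ = 1,
documented, on centered predictors) takes over. MAE SDs are reported
separately over folds (`cv_age_prediction()`) and over random sets
(`random_set_mae_distribution()`, whose size defaults to the stable-set
size); the two spreads answer different questions and are never pooled.
The validation logic: a genuinely age-resilient signature should predict
age *poorly*, while size-matched random sets — which pick up age-drifting
edges — should do better.

## The synthetic study generator

`generate_study()` emulates the structure the analyses assume, with known
ground truth. For subject s (age aₛ), task τ, edge e:

value = tanh( μ(e) + δ(τ, e) + f(s, e)·1[e ∈ signature]
              + β·(aₛ − ā)·1[e ∈ drift] + ε )

with μ(e) ~ N(0, edge_mean_sd²) the shared group mean, δ ~ N(0,
task_effect_sd²) task shifts, f ~ N(0, fingerprint_sd²) the per-subject
fingerprint *constant across tasks*, β the per-year drift slope on a
disjoint planted edge set, and ε ~ N(0, noise_sd²) i.i.d. scan noise. The
tanh squash keeps values in (−1, 1) while preserving monotonicity;
regressing atanh-transformed values on age recovers β exactly, which the
parameter-recovery test exploits. Ages are drawn uniformly on [18, 87]
and assigned in sorted order over subject index, so cohort partitioning
is deterministic; sexes alternate M/F so both strata are always
populated without spending a random stream.

Defaults — 100 subjects, r = 60 (1,770 edges), 80 signature edges,
fingerprint_sd 0.5, noise_sd 0.1 — are the package's study conditions.
The remaining values, which no external source pins down, were fixed once
on plausibility grounds: 40 drift edges and β = 0.005/year give a
0.35-correlation-unit excursion over the 69-year span, a strong but not
caricatured aging effect; task_effect_sd = 0.2 and edge_mean_sd = 0.3
make the shared structure dominate raw similarity (all-features
inter-subject correlation ≈ 0.9), so the fingerprint contrast must be
*earned* by selection. Under these conditions the variance decomposition
is deliberately favorable: signature edges carry 0.5² of between-subject
variance against 0.1² of noise, so leverage selection recovers the
planted set essentially perfectly and cohort intersections sit near
100%, far above the real data's ≈40–50%. Passing tests therefore
demonstrate correctness of the machinery and the *directions* of every
contrast (selected < all for inter-subject similarity; within > between;
stable sets worse at age prediction; stability ≫ random null), not the
magnitudes real connectomes produce. What the generator does not emulate:
spatial autocorrelation between edges sharing a region, hemodynamics,
motion artifacts, non-uniform age distributions, and realistic
within-task variance structure — none of which could be calibrated without
access to the real lifespan fMRI data the generator stands in for.

`generate_timeseries_from_fc()` closes the loop to the time-series stage:
it repairs a target matrix to the nearest valid correlation matrix
(eigenvalues clipped at 10⁻⁸, then unit-diagonal rescaling — simple,
deterministic, adequate at toy scale), draws Gaussian timepoints through
the symmetric matrix square root, and hands the result to the same
`compute_fc()` path real data would take. `make_toy_atlas_pair()` builds
two complete Voronoi parcellations of one voxel grid from a single
seeded permutation (so equal region counts under one seed give identical
atlases), with centroids as affine-mapped mean voxel coordinates.

## Coverage exclusion

`exclude_low_coverage_rois()` implements the standard functional-mask
screen: a subject's mask is the voxels above 70% of that subject's mean
intensity (strict >), and a region is excluded if its within-mask voxel
fraction falls below 50% (strict <; exactly 50% is retained) for even one
subject. `drop_excluded_edges()` then removes all edges touching excluded
regions and re-indexes the survivors into a valid smaller feature space,
so analyses can be run before and after exclusion and compared.

## Numerical and degenerate-input conventions

- Zero-variance regions correlate 0 (warned), never NaN, so leverage
  computation downstream is total.
- Symmetry and unit-diagonal checks on `vectorize_upper()` use a 10⁻⁸
  tolerance; violations indicate upstream bugs and error out.
- All tie-breaks (top-k scores, frequent-region counts) resolve by
  ascending index, making every selection platform-reproducible.
- Every random quantity takes an explicit integer seed, evaluated under a
  save/restore wrapper so package calls never perturb the caller's RNG
  stream. `run_pipeline()` fans one master seed into fixed per-stage
  sub-seeds, so stages are independently reproducible and a manifest of
  seeds plus output digests makes whole runs byte-verifiable.

## Problem sizes used in validation

The shipped validation suite runs the full machinery at the default
synthetic scale (100 subjects × 3 tasks × 1,770 edges, 10–20 replicate
seeds for stochastic claims), uses 10,000-trial random-feature nulls, and
checks the combinatorial identities at the published parcellation sizes
(352,380 / 6,670 / 6,555 features). These sizes were chosen so the entire
suite completes in about a minute while leaving every statistical
contrast overwhelmingly clear; nothing in the method depends on them, and
all entry points accept the full-scale inputs.

## Known limitations

- The centroid matching rule is one of several defensible cross-atlas
  operationalizations (any-voxel intersection and MNI-coordinate lists
  being others); conclusions sensitive to the rule should be checked
  under an alternative.
- The per-feature age model is linear; curvilinear aging trajectories
  would be declared "significant drift" only insofar as their linear
  component is detectable.
- Leverage scores are computed by exact thin SVD; at m ≈ 3.5×10⁵ and
  n ≤ 652 this is comfortably tractable, but no approximate or streaming
  variant is provided.
- The generator's independence of edges given the planted structure
  understates the correlation among edges sharing a region in real FCs;
  random-feature nulls on real data are accordingly wider than the
  synthetic ones.
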
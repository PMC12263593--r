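# connectoprint

Individual-specific fingerprints in functional connectomes, selected by
deterministic leverage scores, and their stability across age and brain
parcellations.

## The problem

A functional connectome (FC) is the matrix of pairwise Pearson
correlations between regional fMRI time series; its upper triangle is a
vector of r(r−1)/2 edge features. A small subset of those edges carries a
stable, individual-specific signature: it separates people from each other
while staying consistent within a person across cognitive states. Finding
that subset — and asking whether it survives aging and a change of atlas —
matters for separating normal brain aging from pathological change: an
age-resilient signature is a usable baseline, an age-driven one is not.

`connectoprint` implements the full analysis as a tested R package:

- **Feature selection.** Stack vectorized FCs column-wise into a
  population matrix **M** (features × subjects). Let **U** be an
  orthonormal basis of the column space of **M**; the leverage score of
  edge *i* is ℓᵢ = ‖**U**ᵢ,⋆‖² — the *i*-th diagonal entry of the
  projector **M**(**M**ᵀ**M**)⁺**M**ᵀ. Scores lie in [0, 1] and sum to
  rank(**M**). Selection is deterministic: sort descending, keep the top
  *k* (ties to the lower edge index).
- **Similarity structure.** Inter-subject within-task and within-subject
  cross-task Pearson similarity on the selected edges, calibrated against
  all-feature and seeded random-subset baselines with empirical and
  Gaussian-tail p-values.
- **Cohort stability.** Subjects sorted by age, cut into cohorts of 50;
  per-cohort top-k sets compared by percentage intersection
  (100·|A∩B|/k), with consensus features (the intersection over all
  cohorts) as the candidate age-resilient signature. A sex-stratified
  variant runs through the same machinery.
- **Cross-atlas concordance.** Endpoint-frequency maps of selected edges,
  centroid matching between parcellations, and the min-normalized overlap
  coefficient Overlap(A, B) = |A∩B| / min(|A|, |B|), plus voxel-level
  atlas agreement.
- **Age invariance.** Per-edge OLS on age with Benjamini–Hochberg FDR at
  α = 0.001, and a 10-fold cross-validated linear age-prediction contrast:
  stable features should predict age *worse* than random feature sets.
- **Synthetic studies.** A seeded generator with planted fingerprint and
  age-drift edges, so every stage is validated against known ground truth
  without any imaging download.

## Worked example

```r
library(connectoprint)

study  <- generate_study(simulation_config(seed = 42))  # 100 subjects, 3 tasks, r = 60
M_rest <- study_population(study, "rest")

sig <- select_top_k(leverage_scores(M_rest), k = 80)
inter_subject_similarity(M_rest, sig)
#> <similarity_summary> inter_subject_within_task (rest): mean 0.3396 +/- 0.0955 over 4950 pairs
inter_subject_similarity(M_rest, feature_set(0:(M_rest$m - 1), m = M_rest$m))
#> <similarity_summary> inter_subject_within_task (rest): mean 0.8780 +/- 0.0088 over 4950 pairs
within_subject_similarity(M_rest, study_population(study, "smt"), sig)
#> <similarity_summary> within_subject_cross_task (rest-smt): mean 0.8512 +/- 0.0287 over 100 pairs
```

The selected edges cut between-subject similarity from 0.88 to 0.34 while
the same subject's scans stay at 0.85 across tasks — the fingerprint
contrast. Against 1,000 seeded random subsets of the same size the
observed inter-subject mean sits below every trial (empirical p at its
floor, 1/1001; Gaussian-tail p ≈ 5e−76):

```r
random_feature_null(M_rest, k = 80, n_trials = 1000, seed = 7,
                    observed = 0.3396, side = "lower")
#> <null_distribution> 1000 trials: null 0.8765 +/- 0.0292; observed 0.3396 (lower),
#>   empirical p = 0.000999, z_p = 4.88e-76
```

Cohort stability and age invariance on the same study:

```r
cohorts <- partition_cohorts(study$metadata, cohort_size = 50)
sets    <- per_cohort_selection(M_rest, cohorts, k = 80)
mean_offdiagonal(intersection_matrix(sets), "consecutive")
#> 100      # both age cohorts select the identical planted fingerprint set

cons <- consensus_features(sets)
length(intersect(cons$indices, study$truth$signature_edges)) / cons$k
#> 1        # consensus recovers the planted signature exactly

cv_age_prediction(M_rest, study$metadata$age, cons, folds = 10, seed = 1)$mean
#> 63.55    # years MAE: stable features carry almost no age signal
random_set_mae_distribution(M_rest, study$metadata$age, k = cons$k,
                            n_sets = 20, folds = 10, seed = 1)$mean
#> 37.73    # random sets pick up planted drift edges and predict age better
```

`run_pipeline(config, out_dir)` chains every stage (simulate → select →
similarity → stability → atlas-overlap → age-invariance) into one
reproducible run with a seed/digest manifest;
`inst/scripts/connectoprint.R` wraps it for the shell. The methods
vignette (`vignettes/connectome-fingerprinting.Rmd`) documents the model,
parameter choices, and limitations.

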
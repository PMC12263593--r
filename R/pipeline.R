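pipeline_config_defaults <- function() {
  list(
    seed = 1L,
    simulation = list(),        # overrides for simulation_config()
    k = 80L,                    # features retained per selection
    cohort_size = 50L,
    remainder_policy = "drop",
    stratum = "all",
    null_trials = 1000L,
    n_random_sets = 20L,
    folds = 10L,
    alpha = 0.001,
    atlas = list(grid_shape = c(8L, 8L, 8L), n_regions_b = 30L),
    fraction = 0.5
  )
}

#' Load and validate a pipeline configuration
#'
#' Accepts a named list or a YAML/JSON file with any subset of the known
#' keys; unknown keys are an error (listing the offenders), missing keys
#' take the defaults.
#'
#' @param config named list, or path to a YAML or JSON file.
#' @return validated configuration list.
#' @export
load_pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  defaults <- pipeline_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  sim_unknown <- setdiff(names(cfg$simulation),
                         names(formals(simulation_config)))
  if (length(sim_unknown)) {
    stopf("unknown simulation key(s): %s", paste(sim_unknown, collapse = ", "))
  }
  cfg
}

#' Run the full synthetic-study fingerprinting pipeline
#'
#' Executes every stage in order — simulate, select, similarity, cohort
#' stability, cross-atlas overlap, age invariance — against one synthetic
#' study, writing each stage's tables and JSON summaries to `out_dir` and
#' returning a run manifest (config snapshot, per-stage seeds, package
#' version, output-file digests). The master seed fans out to per-stage
#' sub-seeds by a fixed deterministic rule, so every stage is
#' independently reproducible and two runs with the same config produce
#' byte-identical numerical outputs.
#'
#' @param config named list or YAML/JSON path, see [load_pipeline_config].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return the run manifest (invisibly a list, also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = list(), out_dir, quiet = FALSE) {
  cfg <- load_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seeds <- list(
    simulate = derive_seed(cfg$seed, "simulate"),
    similarity = derive_seed(cfg$seed, "similarity"),
    atlas = derive_seed(cfg$seed, "atlas"),
    age = derive_seed(cfg$seed, "age")
  )
  outputs <- character(0)
  emit <- function(name) outputs <<- c(outputs, name)

  ## stage: simulate --------------------------------------------------
  say("stage simulate: generating synthetic study")
  sim_args <- utils::modifyList(list(seed = seeds$simulate), cfg$simulation)
  study <- tryCatch(generate_study(do.call(simulation_config, sim_args)),
                    error = function(e) stopf("stage simulate failed: %s",
                                              conditionMessage(e)))
  tasks <- study$config$tasks
  r <- study$config$n_regions
  m <- n_edges(r)
  write_metadata_tsv(study, file.path(out_dir, "metadata.tsv")); emit("metadata.tsv")
  for (tau in tasks) {
    f <- sprintf("population_%s.tsv", tau)
    write_population_tsv(study$connectomes[[tau]], file.path(out_dir, f)); emit(f)
  }
  jsonlite::write_json(study$truth, file.path(out_dir, "truth.json"),
                       digits = NA)
  emit("truth.json")

  ## stage: select ----------------------------------------------------
  say("stage select: leverage top-%d per task", cfg$k)
  selections <- tryCatch(lapply(tasks, function(tau) {
    lr <- leverage_scores(study$connectomes[[tau]])
    fs <- select_top_k(lr, cfg$k)
    f <- sprintf("features_%s.tsv", tau)
    write_feature_set_tsv(fs, file.path(out_dir, f), r = r, scores = lr$scores)
    emit(f)
    fs
  }), error = function(e) stopf("stage select failed: %s", conditionMessage(e)))
  names(selections) <- tasks

  ## stage: similarity ------------------------------------------------
  say("stage similarity: inter/within-subject + random-feature null")
  rest_task <- tasks[1]
  rest_features <- selections[[rest_task]]
  sim_report <- tryCatch({
    inter <- lapply(tasks, function(tau)
      inter_subject_similarity(study$connectomes[[tau]], rest_features))
    names(inter) <- tasks
    within <- if (length(tasks) >= 2) {
      w <- lapply(tasks[-1], function(tau)
        within_subject_similarity(study$connectomes[[rest_task]],
                                  study$connectomes[[tau]], rest_features))
      names(w) <- paste(rest_task, tasks[-1], sep = "-")
      w
    } else list()
    null <- random_feature_null(study$connectomes[[rest_task]],
                                k = rest_features$k,
                                n_trials = cfg$null_trials,
                                seed = seeds$similarity,
                                observed = inter[[rest_task]]$mean,
                                side = "lower")
    list(
      inter_subject = lapply(inter, function(s)
        list(task = s$label, mean = s$mean, sd = s$sd, n_pairs = s$n_pairs)),
      within_subject = lapply(within, function(s)
        list(task_pair = s$label, mean = s$mean, sd = s$sd, n_pairs = s$n_pairs)),
      null = list(n_trials = null$n_trials, mean = null$null_mean,
                  sd = null$null_sd, observed = null$observed,
                  empirical_p = null$empirical_p, z_p = null$z_p)
    )
  }, error = function(e) stopf("stage similarity failed: %s", conditionMessage(e)))
  jsonlite::write_json(sim_report, file.path(out_dir, "similarity.json"),
                       auto_unbox = TRUE, digits = NA)
  emit("similarity.json")

  ## stage: stability -------------------------------------------------
  say("stage stability: cohort feature-set intersections")
  stability <- tryCatch({
    cohorts <- partition_cohorts(study$metadata, cfg$cohort_size,
                                 cfg$remainder_policy, cfg$stratum)
    per_task <- lapply(tasks, function(tau) {
      sets <- per_cohort_selection(study$connectomes[[tau]], cohorts, cfg$k)
      im <- intersection_matrix(sets)
      f <- sprintf("intersection_%s.tsv", tau)
      write.table(data.frame(cohort = im$labels, im$values,
                             check.names = FALSE),
                  file.path(out_dir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      emit(f)
      list(sets = sets, im = im)
    })
    names(per_task) <- tasks
    cons <- consensus_features(per_task[[rest_task]]$sets)
    write_feature_set_tsv(cons, file.path(out_dir, "consensus_features.tsv"),
                          r = r)
    emit("consensus_features.tsv")
    summary <- lapply(per_task, function(pt)
      list(consecutive_mean = mean_offdiagonal(pt$im, "consecutive"),
           all_pairs_mean = mean_offdiagonal(pt$im, "all_pairs")))
    list(per_task = per_task, consensus = cons,
         summary = c(summary, list(consensus_size = cons$k,
                                   n_cohorts = length(cohorts))))
  }, error = function(e) stopf("stage stability failed: %s", conditionMessage(e)))
  jsonlite::write_json(stability$summary, file.path(out_dir, "stability.json"),
                       auto_unbox = TRUE, digits = NA)
  emit("stability.json")

  ## stage: atlas-overlap ---------------------------------------------
  say("stage atlas-overlap: toy atlas pair concordance")
  atlas_report <- tryCatch({
    pair <- make_toy_atlas_pair(cfg$atlas$grid_shape, r, cfg$atlas$n_regions_b,
                                seed = seeds$atlas)
    sets_a <- stability$per_task[[rest_task]]$sets
    freq_a <- region_frequency(sets_a, r, atlas_name = pair$a$name,
                               task = rest_task)
    top_a <- top_frequent_regions(freq_a, cfg$fraction)
    # project the same endpoint counts into atlas B id space via centroids
    counts_b <- setNames(integer(length(pair$b$region_ids)),
                         as.character(pair$b$region_ids))
    inv_b <- solve(pair$b$affine)
    for (rg in names(freq_a$counts)[freq_a$counts > 0]) {
      a_id <- as.character(as.integer(rg) + 1L)   # study region -> atlas A id
      mm <- pair$a$centroids[a_id, ]
      vox <- round(as.numeric(inv_b %*% c(mm, 1))[1:3])
      lab <- pair$b$labels[vox[1] + 1, vox[2] + 1, vox[3] + 1]
      counts_b[as.character(lab)] <- counts_b[as.character(lab)] +
        freq_a$counts[[rg]]
    }
    freq_b <- structure(list(counts = counts_b,
                             r = length(pair$b$region_ids),
                             atlas_name = pair$b$name, task = rest_task),
                        class = "region_frequency")
    top_b <- top_frequent_regions(freq_b, cfg$fraction)
    ov <- cross_atlas_overlap(as.character(as.integer(top_a) + 1L), pair$a,
                              top_b, pair$b)
    c(ov, list(voxel_overlap_pct = voxel_overlap_percentage(pair$a, pair$b)))
  }, error = function(e) stopf("stage atlas-overlap failed: %s",
                               conditionMessage(e)))
  jsonlite::write_json(atlas_report, file.path(out_dir, "atlas_overlap.json"),
                       auto_unbox = TRUE, digits = NA)
  emit("atlas_overlap.json")

  ## stage: age-invariance --------------------------------------------
  say("stage age-invariance: regression + CV MAE contrast")
  age_report <- tryCatch({
    cons <- stability$consensus
    stable_set <- if (cons$k >= 2) cons else selections[[rest_task]]
    inv <- age_invariance_summary(study$connectomes[[rest_task]],
                                  study$metadata$age, stable_set,
                                  alpha = cfg$alpha)
    stable_mae <- cv_age_prediction(study$connectomes[[rest_task]],
                                    study$metadata$age, stable_set,
                                    folds = cfg$folds, seed = seeds$age)
    random_mae <- random_set_mae_distribution(
      study$connectomes[[rest_task]], study$metadata$age, k = stable_set$k,
      n_sets = cfg$n_random_sets, folds = cfg$folds, seed = seeds$age)
    list(n_features = inv$n_features,
         n_nonsignificant = inv$n_nonsignificant,
         frac_nonsignificant = inv$frac_nonsignificant,
         stable_mae_mean = stable_mae$mean, stable_mae_sd = stable_mae$sd,
         random_mae_mean = random_mae$mean, random_mae_sd = random_mae$sd)
  }, error = function(e) stopf("stage age-invariance failed: %s",
                               conditionMessage(e)))
  jsonlite::write_json(age_report, file.path(out_dir, "age_invariance.json"),
                       auto_unbox = TRUE, digits = NA)
  emit("age_invariance.json")

  ## manifest ----------------------------------------------------------
  digests <- as.list(tools::md5sum(file.path(out_dir, outputs)))
  names(digests) <- outputs
  manifest <- list(
    config = cfg,
    seeds = seeds,
    package_version = as.character(packageVersion("connectoprint")),
    outputs = digests
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete: %d output files in %s", length(outputs) + 1, out_dir)
  invisible(manifest)
}
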
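#' Configuration for a synthetic connectome study
#'
#' Encodes the generative model the package's validation rests on: every
#' edge value is a task-level group mean plus, on a planted subset of
#' edges, a subject-specific fingerprint that is constant across tasks,
#' plus, on a second disjoint subset, a linear-in-age drift, plus i.i.d.
#' scan noise; the sum is squashed into (-1, 1) by tanh.
#'
#' Defaults emulate a multi-task aging study: 100 subjects aged 18-87
#' scanned at rest, during a sensorimotor task and during movie watching,
#' with 80 fingerprint edges out of 1,770.
#'
#' @param n_subjects number of subjects.
#' @param n_regions number of atlas regions r; the edge pool has r(r-1)/2
#'   features.
#' @param tasks character vector of task labels.
#' @param age_range numeric `c(min, max)` in years, min < max.
#' @param n_signature_edges number of planted fingerprint edges.
#' @param n_drift_edges number of planted age-drift edges (disjoint from
#'   the signature set).
#' @param fingerprint_sd between-subject SD of the fingerprint values
#'   (correlation units).
#' @param noise_sd per-scan i.i.d. noise SD.
#' @param drift_slope mean shift per year of age on drift edges.
#' @param task_effect_sd SD of the task-specific group mean shifts.
#' @param edge_mean_sd SD of the per-edge group means shared by everyone.
#' @param seed integer seed; identical seed + config reproduces the study
#'   bit-for-bit.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 100, n_regions = 60,
                              tasks = c("rest", "smt", "movie"),
                              age_range = c(18, 87),
                              n_signature_edges = 80, n_drift_edges = 40,
                              fingerprint_sd = 0.5, noise_sd = 0.1,
                              drift_slope = 0.005, task_effect_sd = 0.2,
                              edge_mean_sd = 0.3, seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_regions = as.integer(n_regions),
    tasks = as.character(tasks), age_range = as.numeric(age_range),
    n_signature_edges = as.integer(n_signature_edges),
    n_drift_edges = as.integer(n_drift_edges),
    fingerprint_sd = as.numeric(fingerprint_sd),
    noise_sd = as.numeric(noise_sd),
    drift_slope = as.numeric(drift_slope),
    task_effect_sd = as.numeric(task_effect_sd),
    edge_mean_sd = as.numeric(edge_mean_sd),
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  m <- n_edges(cfg$n_regions)
  if (cfg$n_subjects < 2) stopf("invalid config: n_subjects must be >= 2")
  if (length(cfg$tasks) < 1 || anyDuplicated(cfg$tasks)) {
    stopf("invalid config: tasks must be a non-empty set of distinct labels")
  }
  if (cfg$n_signature_edges < 0 || cfg$n_drift_edges < 0) {
    stopf("invalid config: planted edge counts must be >= 0")
  }
  if (cfg$n_signature_edges + cfg$n_drift_edges > m) {
    stopf("invalid config: n_signature_edges + n_drift_edges (%d) exceeds edge pool r(r-1)/2 = %d",
          cfg$n_signature_edges + cfg$n_drift_edges, m)
  }
  sds <- c(cfg$fingerprint_sd, cfg$noise_sd, cfg$task_effect_sd, cfg$edge_mean_sd)
  if (any(sds < 0)) stopf("invalid config: all SDs must be >= 0")
  if (length(cfg$age_range) != 2 || cfg$age_range[1] >= cfg$age_range[2]) {
    stopf("invalid config: age_range min must be < max")
  }
  invisible(cfg)
}

#' Generate a synthetic connectome study with planted ground truth
#'
#' Draws subject ages uniformly on the configured range (assigned in
#' ascending order over subject index, so age-cohort partitioning is
#' deterministic), assigns sexes alternately M/F, plants a signature edge
#' set and a disjoint age-drift edge set, and generates, for every
#' (subject, task) scan, the edge vector
#' `tanh(group_mean + task_effect + fingerprint + drift + noise)`.
#'
#' @param config a [simulation_config].
#' @return an object of class `synthetic_study` with `metadata` (data frame
#'   of subject_id, age, sex), `connectomes` (named list: one
#'   [population_matrix] per task, subjects in metadata order), `truth`
#'   (0-based `signature_edges` and `drift_edges`), and the `config`.
#' @export
generate_study <- function(config) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, as.list(config))
  }
  validate_simulation_config(config)
  n <- config$n_subjects
  r <- config$n_regions
  m <- n_edges(r)
  tasks <- config$tasks
  age_mid <- mean(config$age_range)

  with_seed(config$seed, {
    subject_id <- sprintf("sub%04d", seq_len(n))
    ages <- sort(runif(n, config$age_range[1], config$age_range[2]))
    sex <- rep_len(c("M", "F"), n)

    planted <- sample.int(m, config$n_signature_edges + config$n_drift_edges)
    signature <- sort(planted[seq_len(config$n_signature_edges)]) - 1L
    drift <- sort(planted[seq_len(config$n_drift_edges) + config$n_signature_edges]) - 1L

    group_mean <- rnorm(m, 0, config$edge_mean_sd)
    task_effect <- matrix(rnorm(m * length(tasks), 0, config$task_effect_sd),
                          m, length(tasks), dimnames = list(NULL, tasks))
    fingerprint <- matrix(0, m, n)
    if (length(signature)) {
      fingerprint[signature + 1L, ] <-
        rnorm(length(signature) * n, 0, config$fingerprint_sd)
    }
    drift_term <- matrix(0, m, n)
    if (length(drift)) {
      drift_term[drift + 1L, ] <-
        outer(rep(config$drift_slope, length(drift)), ages - age_mid)
    }

    connectomes <- lapply(tasks, function(tau) {
      noise <- matrix(rnorm(m * n, 0, config$noise_sd), m, n)
      values <- tanh(group_mean + task_effect[, tau] + fingerprint +
                       drift_term + noise)
      population_matrix(values, subjects = subject_id, task = tau, r = r)
    })
    names(connectomes) <- tasks

    structure(
      list(
        metadata = data.frame(subject_id = subject_id, age = ages, sex = sex,
                              stringsAsFactors = FALSE),
        connectomes = connectomes,
        truth = list(signature_edges = signature, drift_edges = drift),
        config = config
      ),
      class = "synthetic_study"
    )
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d subjects x %d tasks, r = %d (%d signature, %d drift edges)\n",
    nrow(x$metadata), length(x$connectomes), x$config$n_regions,
    length(x$truth$signature_edges), length(x$truth$drift_edges)))
  invisible(x)
}

#' Extract one task's population matrix from a study
#'
#' @param study a `synthetic_study`.
#' @param task task label.
#' @return the task's [population_matrix].
#' @export
study_population <- function(study, task) {
  if (!task %in% names(study$connectomes)) {
    stopf("unknown task '%s' (have: %s)", task,
          paste(names(study$connectomes), collapse = ", "))
  }
  study$connectomes[[task]]
}

#' Simulate regional time series with a target correlation structure
#'
#' Repairs `target_corr` to the nearest valid correlation matrix
#' (eigenvalues clipped at a small floor, then unit-diagonal rescaling) and
#' draws t independent Gaussian timepoints through its symmetric matrix
#' square root, so the population correlation of the output equals the
#' repaired target.
#'
#' @param target_corr symmetric matrix with unit diagonal.
#' @param t number of timepoints (>= 2).
#' @param seed integer seed.
#' @param eig_floor eigenvalue clipping floor for the repair (default 1e-8).
#' @param subject_id,task provenance labels.
#' @return a [regional_time_series] of dimension r x t.
#' @export
generate_timeseries_from_fc <- function(target_corr, t, seed,
                                        eig_floor = 1e-8,
                                        subject_id = NA_character_,
                                        task = NA_character_) {
  target_corr <- as.matrix(target_corr)
  if (nrow(target_corr) != ncol(target_corr) ||
      max(abs(target_corr - t(target_corr))) > 1e-8) {
    stopf("target correlation matrix must be symmetric")
  }
  if (t < 2) stopf("need t >= 2 timepoints")
  r <- nrow(target_corr)
  e <- eigen(target_corr, symmetric = TRUE)
  lam <- pmax(e$values, eig_floor)
  repaired <- e$vectors %*% (lam * t(e$vectors))
  d <- 1 / sqrt(diag(repaired))
  repaired <- repaired * tcrossprod(d)        # unit-diagonal renormalization
  e2 <- eigen(repaired, symmetric = TRUE)
  root <- e2$vectors %*% (sqrt(pmax(e2$values, 0)) * t(e2$vectors))
  x <- with_seed(seed, root %*% matrix(rnorm(r * t), r, t))
  regional_time_series(x, subject_id = subject_id, task = task)
}

#' Atlas definition on a voxel grid
#'
#' @param labels integer array over the voxel grid; value = region id,
#'   0 or NA = unlabeled background.
#' @param affine 4x4 voxel-to-mm transform applied to 0-based voxel
#'   coordinates.
#' @param centroids optional matrix (regions x 3) of region centroids in
#'   mm with rownames = region ids; computed from `labels` via `affine`
#'   when omitted.
#' @param name atlas name.
#' @return an object of class `atlas_definition`.
#' @export
atlas_definition <- function(labels, affine, centroids = NULL,
                             name = "atlas") {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3) stopf("labels must be a 3-D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4))) stopf("affine must be 4x4")
  ids <- sort(unique(labels[!is.na(labels) & labels != 0]))
  if (!length(ids)) stopf("atlas has no labeled voxels")
  if (is.null(centroids)) {
    coords <- which(!is.na(labels) & labels != 0, arr.ind = TRUE) - 1L
    vals <- labels[!is.na(labels) & labels != 0]
    centroids <- t(vapply(ids, function(id) {
      vox <- colMeans(coords[vals == id, , drop = FALSE])
      as.numeric(affine %*% c(vox, 1))[1:3]
    }, numeric(3)))
    rownames(centroids) <- as.character(ids)
  } else {
    centroids <- as.matrix(centroids)
    if (!setequal(rownames(centroids), as.character(ids))) {
      stopf("centroid region ids must match labeled region ids")
    }
  }
  colnames(centroids) <- c("x_mm", "y_mm", "z_mm")
  structure(
    list(labels = labels, affine = affine,
         centroids = centroids[as.character(ids), , drop = FALSE],
         region_ids = ids, name = name),
    class = "atlas_definition"
  )
}

#' @export
print.atlas_definition <- function(x, ...) {
  cat(sprintf("<atlas_definition> '%s': %d regions on a %s grid\n",
              x$name, length(x$region_ids),
              paste(dim(x$labels), collapse = "x")))
  invisible(x)
}

#' Build a pair of toy Voronoi parcellations of one voxel grid
#'
#' Draws one seeded permutation of the grid's voxels and uses its first
#' `n_regions_a` (resp. `n_regions_b`) entries as region centers, then
#' labels every voxel with its nearest center (ties to the lower region
#' id). Because both atlases take centers from the same permutation, equal
#' region counts under one seed give identical atlases. Centroids are the
#' affine-transformed mean voxel coordinates.
#'
#' @param grid_shape integer triple of voxel counts per axis.
#' @param n_regions_a,n_regions_b region counts (each <= number of voxels).
#' @param seed integer seed.
#' @param affine 4x4 voxel-to-mm transform (default 2 mm isotropic voxels
#'   with a -10 mm origin shift).
#' @return list of two complete [atlas_definition]s, `a` and `b`.
#' @export
make_toy_atlas_pair <- function(grid_shape, n_regions_a, n_regions_b, seed,
                                affine = rbind(c(2, 0, 0, -10),
                                               c(0, 2, 0, -10),
                                               c(0, 0, 2, -10),
                                               c(0, 0, 0, 1))) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  nvox <- prod(grid_shape)
  if (n_regions_a > nvox || n_regions_b > nvox) {
    stopf("region count exceeds voxel count (%d)", nvox)
  }
  coords <- as.matrix(expand.grid(x = seq_len(grid_shape[1]) - 1L,
                                  y = seq_len(grid_shape[2]) - 1L,
                                  z = seq_len(grid_shape[3]) - 1L))
  perm <- with_seed(seed, sample.int(nvox))
  build <- function(n_regions, name) {
    centers <- coords[perm[seq_len(n_regions)], , drop = FALSE]
    # squared distance voxel -> each center; nearest wins, ties -> lower id
    d2 <- outer(rowSums(coords^2), rowSums(centers^2), "+") -
      2 * coords %*% t(centers)
    lab <- max.col(-d2, ties.method = "first")
    labels <- array(as.integer(lab), dim = grid_shape)
    atlas_definition(labels, affine, name = name)
  }
  list(a = build(n_regions_a, "toy_a"), b = build(n_regions_b, "toy_b"))
}
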
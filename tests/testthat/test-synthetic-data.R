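test_that("invalid configurations are rejected with the violated invariant named", {
  expect_error(simulation_config(n_signature_edges = 1000, n_drift_edges = 1000,
                                 n_regions = 10),
               "exceeds edge pool")
  expect_error(simulation_config(noise_sd = -0.1), "SDs must be >= 0")
  expect_error(simulation_config(age_range = c(50, 30)), "age_range")
  expect_error(simulation_config(tasks = character(0)), "tasks")
})

test_that("degenerate variance collapses all subjects onto the task mean", {
  st <- generate_study(simulation_config(
    n_subjects = 10, n_regions = 12, n_signature_edges = 10, n_drift_edges = 5,
    fingerprint_sd = 0, noise_sd = 0, drift_slope = 0, seed = 3))
  for (tau in names(st$connectomes)) {
    vals <- st$connectomes[[tau]]$values
    expect_equal(vals, vals[, 1] %*% t(rep(1, ncol(vals))),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("same config and seed reproduce the study bit-for-bit", {
  cfg <- simulation_config(n_subjects = 12, n_regions = 15,
                           n_signature_edges = 10, n_drift_edges = 5, seed = 99)
  expect_identical(generate_study(cfg), generate_study(cfg))
})

test_that("study satisfies its structural invariants", {
  st <- default_study(1)
  cfg <- st$config
  m <- n_edges(cfg$n_regions)
  expect_setequal(names(st$connectomes), cfg$tasks)
  for (tau in cfg$tasks) {
    M <- st$connectomes[[tau]]
    expect_identical(M$subjects, st$metadata$subject_id)  # each pair once
    expect_true(all(abs(M$values) < 1))                    # tanh range
    expect_equal(nrow(M$values), m)
  }
  expect_true(all(diff(st$metadata$age) >= 0))             # sorted ages
  expect_setequal(unique(st$metadata$sex), c("M", "F"))
  expect_length(intersect(st$truth$signature_edges, st$truth$drift_edges), 0)
})

test_that("planted fingerprints make subjects more similar to themselves across tasks than to others", {
  wins <- vapply(1:20, function(s) {
    st <- default_study(s)
    sig <- feature_set(st$truth$signature_edges, m = st$connectomes$rest$m)
    w <- within_subject_similarity(st$connectomes$rest, st$connectomes$smt, sig)$mean
    b <- inter_subject_similarity(st$connectomes$rest, sig)$mean
    w > b
  }, logical(1))
  expect_true(all(wins))
})

test_that("OLS on the unsquashed scale recovers the planted drift slope within 3 SE", {
  st <- generate_study(simulation_config(seed = 11, noise_sd = 0.05))
  slope <- st$config$drift_slope
  ok <- vapply(st$truth$drift_edges[1:5], function(e) {
    y <- atanh(st$connectomes$rest$values[e + 1, ])  # inverts the stated squash
    fit <- summary(lm(y ~ st$metadata$age))$coefficients
    abs(fit[2, 1] - slope) < 3 * fit[2, 2]
  }, logical(1))
  expect_true(all(ok))
})

test_that("without planted fingerprints, within- and between-subject cross-task similarity are indistinguishable", {
  rejections <- vapply(1:20, function(s) {
    st <- generate_study(simulation_config(n_subjects = 30,
                                           n_signature_edges = 0, seed = s))
    C <- connectoprint:::cross_task_similarity_matrix(
      st$connectomes$rest, st$connectomes$smt,
      full_feature_set(st$connectomes$rest))
    t.test(diag(C), C[row(C) != col(C)])$p.value < 0.01
  }, logical(1))
  expect_lte(sum(rejections), 3)
})

test_that("simulated time series reproduce a target correlation structure", {
  # independence limit
  ts <- generate_timeseries_from_fc(diag(6), t = 10000, seed = 4)
  emp <- cor(t(ts$values))
  expect_lt(max(abs(emp[upper.tri(emp)])), 0.05)
  # 2x2 target, sampling-error tolerance ~ (1 - rho^2)/sqrt(t)
  tgt <- matrix(c(1, 0.8, 0.8, 1), 2)
  ts2 <- generate_timeseries_from_fc(tgt, t = 10000, seed = 5)
  expect_lt(abs(cor(ts2$values[1, ], ts2$values[2, ]) - 0.8), 0.03)
  # shape contract and input validation
  expect_identical(dim(generate_timeseries_from_fc(random_corr(7), 40, 1)$values),
                   c(7L, 40L))
  expect_error(generate_timeseries_from_fc(matrix(c(1, 0.5, 0, 1), 2), 10, 1),
               "symmetric")
  expect_error(generate_timeseries_from_fc(diag(3), t = 1, seed = 1), "t >= 2")
})

test_that("indefinite targets are repaired to a valid correlation matrix", {
  bad <- matrix(0.9, 3, 3); diag(bad) <- 1; bad[1, 2] <- bad[2, 1] <- -0.9
  ts <- generate_timeseries_from_fc(bad, t = 50000, seed = 6)
  emp <- cor(t(ts$values))
  ev <- eigen(emp, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
  expect_equal(diag(emp), rep(1, 3), tolerance = 1e-12)
})

test_that("toy atlas pairs are complete partitions and identical under equal settings", {
  pair <- make_toy_atlas_pair(c(6, 5, 4), 7, 3, seed = 2)
  for (at in pair) {
    expect_identical(dim(at$labels), c(6L, 5L, 4L))
    expect_true(all(at$labels %in% at$region_ids))  # every voxel labeled once
  }
  expect_length(pair$a$region_ids, 7)
  expect_length(pair$b$region_ids, 3)
  same <- make_toy_atlas_pair(c(6, 5, 4), 5, 5, seed = 2)
  expect_identical(same$a$labels, same$b$labels)
  expect_equal(same$a$centroids, same$b$centroids)
  expect_error(make_toy_atlas_pair(c(2, 2, 2), 9, 2, seed = 1),
               "exceeds voxel count")
})

test_that("atlas centroids are the affine image of mean voxel coordinates", {
  pair <- make_toy_atlas_pair(c(5, 5, 5), 4, 2, seed = 8)
  at <- pair$a
  for (rg in at$region_ids) {
    vox <- which(at$labels == rg, arr.ind = TRUE) - 1
    expected <- as.numeric(at$affine %*% c(colMeans(vox), 1))[1:3]
    expect_equal(unname(at$centroids[as.character(rg), ]), expected,
                 tolerance = 1e-12)
  }
})
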
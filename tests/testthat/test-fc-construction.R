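test_that("parcellation averages voxel rows within regions, ordered by region id", {
  # identity partition: single-voxel regions come back reordered by id
  vox <- matrix(rnorm(12), 3, 4)
  out <- parcellate(vox, labels = c("r3", "r1", "r2"))
  expect_equal(out$values, vox[c(2, 3, 1), ], ignore_attr = TRUE)
  # two constant voxels average to their midpoint
  two <- rbind(rep(1, 5), rep(3, 5), rep(7, 5))
  expect_equal(parcellate(two, labels = c("a", "a", "b"))$values[1, ], rep(2, 5))
  # seeded random instance vs direct loop oracle
  set.seed(21)
  vox <- matrix(rnorm(20 * 7), 20, 7)
  labels <- sample(sprintf("g%d", 1:5), 20, replace = TRUE)
  got <- parcellate(vox, labels)
  for (i in seq_along(got$region_ids)) {
    rows <- which(labels == got$region_ids[i])
    manual <- colSums(vox[rows, , drop = FALSE]) / length(rows)
    expect_equal(got$values[i, ], manual, tolerance = 1e-12)
  }
  expect_error(parcellate(vox, labels, regions = c("g1", "g9")), "g9")
})

test_that("functional connectivity matches the textbook Pearson formula", {
  set.seed(5)
  x <- matrix(rnorm(4 * 50), 4, 50)
  x[2, ] <- 2 * x[1, ] + 1          # affine copy
  x[3, ] <- -x[1, ]                 # anti-correlated
  fc <- compute_fc(regional_time_series(x))
  expect_equal(fc[1, 2], 1)
  expect_equal(fc[1, 3], -1)
  expect_equal(fc, t(fc))
  expect_equal(diag(fc), rep(1, 4))
  # elementwise covariance / sd-product oracle
  for (i in 1:3) for (j in (i + 1):4) {
    manual <- mean((x[i, ] - mean(x[i, ])) * (x[j, ] - mean(x[j, ]))) /
      (sqrt(mean((x[i, ] - mean(x[i, ]))^2)) * sqrt(mean((x[j, ] - mean(x[j, ]))^2)))
    expect_equal(fc[i, j], manual, tolerance = 1e-12)
  }
})

test_that("zero-variance regions get correlation 0 with a warning, not NaN", {
  x <- rbind(rnorm(10), rnorm(10), rep(2, 10))
  expect_warning(fc <- compute_fc(x), "zero-variance")
  expect_equal(fc[3, 1:2], c(0, 0))
  expect_equal(diag(fc), rep(1, 3))
  expect_false(anyNA(fc))
})

test_that("correlation matrices of long series are positive semidefinite", {
  for (s in 1:5) {
    ts <- generate_timeseries_from_fc(random_corr(8, seed = s), t = 30, seed = s)
    ev <- eigen(compute_fc(ts), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
})

test_that("upper-triangle vectorization has the exact combinatorial length", {
  for (r in c(2, 5, 115, 116, 840)) {
    expect_identical(n_edges(r), as.integer(r * (r - 1) / 2))
  }
  expect_identical(length(vectorize_upper(random_corr(30))$values), 435L)
  # smallest case: single off-diagonal survives
  m2 <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(vectorize_upper(m2)$values, 0.3)
  # asymmetry and non-unit diagonal rejected
  bad <- random_corr(5); bad[1, 2] <- bad[1, 2] + 1e-4
  expect_error(vectorize_upper(bad), "asymmetric")
  bad2 <- random_corr(5); diag(bad2)[2] <- 0.9
  expect_error(vectorize_upper(bad2), "diagonal")
})

test_that("vectorization uses canonical row-major order and loses no information", {
  C <- random_corr(6, seed = 9)
  v <- vectorize_upper(C)
  pairs <- edge_index_to_region_pair(seq_along(v$values) - 1L, 6)
  expect_equal(v$values, C[cbind(pairs[, 1] + 1, pairs[, 2] + 1)])
  # reconstruct and re-vectorize: identity
  rec <- diag(6)
  rec[cbind(pairs[, 1] + 1, pairs[, 2] + 1)] <- v$values
  rec[cbind(pairs[, 2] + 1, pairs[, 1] + 1)] <- v$values
  expect_identical(vectorize_upper(rec)$values, v$values)
})

test_that("edge index <-> region pair mapping matches exhaustive enumeration", {
  for (r in c(3, 12)) {
    pairs <- edge_index_to_region_pair(0:(n_edges(r) - 1), r)
    expect_equal(unname(pairs), unname(enumerate_pairs(r)))
    # bijection roundtrip
    k <- region_pair_to_index(pairs[, 1], pairs[, 2], r)
    expect_identical(k, 0:(n_edges(r) - 1))
  }
  expect_equal(unname(edge_index_to_region_pair(0:2, 3)),
               cbind(c(0L, 0L, 1L), c(1L, 2L, 2L)))
  # last Craddock-scale edge, against the enumeration oracle
  oracle <- enumerate_pairs(840)
  expect_equal(unname(edge_index_to_region_pair(352379, 840)),
               unname(oracle[352380, , drop = FALSE]))
  expect_error(edge_index_to_region_pair(3, 3), "out of range")
  expect_error(region_pair_to_index(2, 2, 5), "i < j")
})

test_that("population assembly preserves vectors and honours subject order", {
  set.seed(31)
  vecs <- lapply(1:5, function(s) {
    connectome_vector(runif(n_edges(8), -1, 1), r = 8,
                      subject_id = sprintf("s%d", s), task = "rest")
  })
  M <- assemble_population(vecs)
  expect_identical(M$m, n_edges(8))
  for (j in 1:5) expect_identical(M$values[, j], vecs[[j]]$values)
  # permuting the requested order permutes columns identically
  M2 <- assemble_population(vecs, subjects = c("s3", "s1", "s5", "s2", "s4"))
  expect_identical(M2$values[, 1], vecs[[3]]$values)
  expect_identical(M2$values[, 5], vecs[[4]]$values)
  # contract violations
  other <- vecs; other[[2]]$task <- "movie"
  expect_error(assemble_population(other), "mix tasks")
  dup <- vecs; dup[[2]]$subject_id <- "s1"
  expect_error(assemble_population(dup), "duplicate subject")
})

test_that("coverage exclusion reproduces hand-computed masks", {
  # uniform intensities: every voxel in every mask, nothing excluded
  flat <- matrix(5, 3, 20)
  res <- exclude_low_coverage_rois(flat, labels = rep(1:4, each = 5))
  expect_length(res$excluded, 0)
  expect_setequal(res$retained, as.character(1:4))
  # one region all-zero for one subject: zero coverage, excluded
  img <- matrix(10, 2, 20)
  img[2, 1:5] <- 0
  res <- exclude_low_coverage_rois(img, labels = rep(1:4, each = 5))
  expect_identical(res$excluded, "1")
  # constructed instance with hand-computed exclusion set:
  # subject mean 1 -> mask threshold 0.7; region coverage per subject below
  labels <- rep(1:10, each = 10)
  img <- matrix(1, 2, 100)
  img[1, labels == 3] <- c(rep(0.5, 6), rep(1.5, 4) * 0.875) # cov 0.4 -> excluded
  img[2, labels == 7] <- c(rep(0.5, 5), rep(1.5, 5))          # cov 0.5 -> retained
  img[1, labels == 9] <- c(rep(0.5, 4), rep(1.3, 6))          # adjust below
  # renormalize rows so each subject's mean intensity is exactly 1
  img <- img / rowMeans(img)
  res <- exclude_low_coverage_rois(img, labels)
  cov_check <- function(s, rg) mean(img[s, labels == rg] > 0.7 * mean(img[s, ]))
  manual_excluded <- sort(unique(unlist(lapply(1:10, function(rg)
    if (any(sapply(1:2, cov_check, rg = rg) < 0.5)) rg))))
  expect_identical(res$excluded, as.character(manual_excluded))
  expect_setequal(c(res$retained, res$excluded), as.character(1:10))
})

test_that("dropping excluded regions re-indexes edges consistently", {
  st <- generate_study(simulation_config(n_subjects = 8, n_regions = 10,
                                         n_signature_edges = 10,
                                         n_drift_edges = 5, seed = 2))
  M <- st$connectomes$rest
  red <- drop_excluded_edges(M, retained = c(0, 2, 3, 7, 9))
  expect_identical(red$M$r, 5L)
  expect_identical(red$M$m, n_edges(5))
  # every kept edge's values survive untouched under the new indexing
  old_pairs <- edge_index_to_region_pair(red$old_edges, 10)
  new_pairs <- edge_index_to_region_pair(0:(red$M$m - 1), 5)
  expect_identical(unname(red$region_map[as.character(old_pairs[, 1])]),
                   new_pairs[, 1])
  expect_identical(red$M$values, M$values[red$old_edges + 1L, ])
})
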
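fake_metadata <- function(n, seed = 1) {
  connectoprint:::with_seed(seed, data.frame(
    subject_id = sprintf("p%04d", seq_len(n)),
    age = runif(n, 18, 88),
    sex = rep_len(c("M", "F"), n)
  ))
}

test_that("cohort partitioning sorts by age and cuts exact blocks", {
  md <- fake_metadata(100)
  co <- partition_cohorts(md, 50)
  expect_length(co, 2)
  expect_true(all(vapply(co, function(x) length(x$subject_ids), integer(1)) == 50))
  expect_lte(co[[1]]$age_range[2], co[[2]]$age_range[1])
  # full-cohort-study size: 652 subjects, cohorts of 50
  md652 <- fake_metadata(652)
  expect_length(partition_cohorts(md652, 50), 13)
  assigned <- unlist(lapply(partition_cohorts(md652, 50),
                            function(x) x$subject_ids))
  expect_length(assigned, 650)  # 2 remainder subjects dropped
  merged <- partition_cohorts(md652, 50, remainder_policy = "merge_last")
  expect_length(merged[[13]]$subject_ids, 52)
  expect_error(partition_cohorts(fake_metadata(10), 50), "cohort_size 50")
})

test_that("sex-stratified partitioning reuses the same machinery", {
  md <- fake_metadata(100)
  males <- partition_cohorts(md, 25, stratum = "M")
  expect_length(males, 2)
  expect_true(all(md$sex[match(unlist(lapply(males, `[[`, "subject_ids")),
                               md$subject_id)] == "M"))
})

test_that("per-cohort selection is deterministic and column-faithful", {
  st <- default_study(4)
  M <- st$connectomes$rest
  co <- partition_cohorts(st$metadata, 50)
  sets <- per_cohort_selection(M, co, 80)
  expect_length(sets, 2)
  # one cohort holding every subject equals global selection
  all_co <- list(list(label = "ALL", subject_ids = st$metadata$subject_id,
                      age_range = range(st$metadata$age), stratum = "all"))
  expect_identical(per_cohort_selection(M, all_co, 80)[[1]]$indices,
                   select_top_k(leverage_scores(M), 80)$indices)
  # duplicated cohort gives identical sets
  dup <- per_cohort_selection(M, co[c(1, 1)], 80)
  expect_identical(dup[[1]]$indices, dup[[2]]$indices)
})

test_that("intersection matrices compute percentage overlap with fixed diagonal", {
  fs <- function(idx) feature_set(idx, m = 100)
  same <- intersection_matrix(list(fs(0:9), fs(0:9)))
  expect_equal(unname(same$values), matrix(100, 2, 2))
  disj <- intersection_matrix(list(fs(0:9), fs(10:19)))
  expect_equal(disj$values[1, 2], 0)
  half <- intersection_matrix(list(fs(1:10), fs(6:15)))
  expect_equal(half$values[1, 2], 50)   # 5 shared of k = 10
  expect_equal(diag(half$values), c(100, 100), ignore_attr = TRUE)
  expect_true(isSymmetric(half$values))
  expect_error(intersection_matrix(list(fs(0:9), fs(0:4))), "unequal k")
})

test_that("off-diagonal means cover consecutive and all-pairs scopes", {
  fs <- function(idx) feature_set(idx, m = 1000)
  # three sets with known superdiagonal overlaps 50% and 30%
  im <- intersection_matrix(list(fs(0:9), fs(5:14), fs(c(12:14, 20:26))))
  expect_equal(im$values[1, 2], 50)
  expect_equal(im$values[2, 3], 30)
  expect_equal(mean_offdiagonal(im, "consecutive"), 40)
  expect_equal(mean_offdiagonal(im, "all_pairs"),
               mean(c(50, 30, im$values[1, 3])))
  expect_equal(mean_offdiagonal(same_matrix <- intersection_matrix(
    list(fs(0:9), fs(0:9))), "all_pairs"), 100)  # idempotence
})

test_that("random feature sets overlap at the analytic k/m rate", {
  m <- 352380; k <- 7000
  sets <- lapply(1:40, function(i) sample_random_features(m, k, seed = i))
  im <- intersection_matrix(sets)
  got <- mean_offdiagonal(im, "all_pairs")
  expect_lt(abs(got - 100 * k / m), 0.15)   # expectation 1.9865%
})

test_that("consensus features intersect all cohorts and recover planted truth", {
  fs <- function(idx) feature_set(idx, m = 100)
  expect_identical(consensus_features(list(fs(0:9), fs(0:9)))$indices, 0:9)
  expect_warning(empty <- consensus_features(list(fs(0:9), fs(50:59))),
                 "empty")
  expect_identical(empty$k, 0L)
  expect_error(consensus_features(list(fs(0:9))), ">= 2")
  prec <- vapply(1:5, function(s) {
    st <- default_study(s)
    co <- partition_cohorts(st$metadata, 20)   # 5 cohorts of 20
    cons <- consensus_features(per_cohort_selection(st$connectomes$rest, co,
                                                    st$config$n_signature_edges))
    length(intersect(cons$indices, st$truth$signature_edges)) / max(cons$k, 1)
  }, numeric(1))
  expect_gte(mean(prec), 0.8)
})

test_that("stable feature sets overlap far above the random-null rate", {
  st <- default_study(6)
  co <- partition_cohorts(st$metadata, 20)
  sets <- per_cohort_selection(st$connectomes$rest, co,
                               st$config$n_signature_edges)
  got <- mean_offdiagonal(intersection_matrix(sets), "all_pairs")
  null_rate <- 100 * st$config$n_signature_edges / st$connectomes$rest$m
  expect_gte(got, null_rate + 10)
})

test_that("consensus regions tally edge endpoints exactly", {
  expect_equal(consensus_regions(feature_set(0L, m = 10), r = 5),
               c(`0` = 1L, `1` = 1L))
  # edges (0,1) and (0,2) at r = 5: indices 0 and 1
  expect_equal(consensus_regions(c(0L, 1L), r = 5),
               c(`0` = 2L, `1` = 1L, `2` = 1L))
  # random consensus vs brute-force endpoint tally at r = 20
  idx <- sample_random_features(n_edges(20), 30, seed = 5)$indices
  got <- consensus_regions(idx, 20)
  manual <- integer(20)
  for (k in idx) {
    pr <- enumerate_pairs(20)[k + 1, ]
    manual[pr[1] + 1] <- manual[pr[1] + 1] + 1L
    manual[pr[2] + 1] <- manual[pr[2] + 1] + 1L
  }
  expect_equal(unname(got), manual[manual > 0])
  expect_identical(as.integer(names(got)), which(manual > 0) - 1L)
})
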
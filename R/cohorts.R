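#' Partition subjects into age-ordered cohorts
#'
#' Sorts subjects by (age, subject_id) and cuts consecutive blocks of
#' `cohort_size`, so each cohort spans a contiguous age band. Remainder
#' subjects that do not fill a block are dropped by default or merged into
#' the last cohort.
#'
#' @param metadata data frame with columns `subject_id` and `age` (years);
#'   an optional `sex` column enables `stratum` filtering.
#' @param cohort_size subjects per cohort (default 50).
#' @param remainder_policy "drop" (default) or "merge_last".
#' @param stratum "all" (default), "M" or "F": restrict to one sex before
#'   partitioning (the sex-stratified analysis reuses this same machinery).
#' @return list of cohorts; each has `label`, `subject_ids` (age order),
#'   `age_range`, `stratum`.
#' @export
partition_cohorts <- function(metadata, cohort_size = 50,
                              remainder_policy = c("drop", "merge_last"),
                              stratum = c("all", "M", "F")) {
  remainder_policy <- match.arg(remainder_policy)
  stratum <- match.arg(stratum)
  if (!all(c("subject_id", "age") %in% names(metadata))) {
    stopf("metadata needs subject_id and age columns")
  }
  if (anyNA(metadata$age)) stopf("every subject needs an age")
  if (cohort_size < 2) stopf("cohort_size must be >= 2")
  if (stratum != "all") {
    if (!"sex" %in% names(metadata)) stopf("stratum filtering needs a sex column")
    metadata <- metadata[metadata$sex == stratum, , drop = FALSE]
  }
  md <- metadata[order(metadata$age, metadata$subject_id), , drop = FALSE]
  n <- nrow(md)
  n_cohorts <- n %/% cohort_size
  if (n_cohorts < 1) {
    stopf("only %d subject(s) for cohort_size %d", n, cohort_size)
  }
  sizes <- rep(cohort_size, n_cohorts)
  if (remainder_policy == "merge_last") sizes[n_cohorts] <- sizes[n_cohorts] + n %% cohort_size
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  lapply(seq_len(n_cohorts), function(i) {
    block <- md[starts[i]:ends[i], , drop = FALSE]
    list(label = sprintf("C%02d", i),
         subject_ids = block$subject_id,
         age_range = range(block$age),
         stratum = stratum)
  })
}

#' Leverage-based top-k selection within each cohort
#'
#' Extracts each cohort's columns from the full population matrix, computes
#' leverage scores on the cohort matrix, and retains the top k features.
#'
#' @param M_full a [population_matrix] containing every cohort subject.
#' @param cohorts output of [partition_cohorts].
#' @param k features to retain per cohort.
#' @param rank_tolerance passed to [leverage_scores].
#' @return list of [feature_set]s, one per cohort, in cohort order.
#' @export
per_cohort_selection <- function(M_full, cohorts, k, rank_tolerance = 1e-10) {
  lapply(cohorts, function(co) {
    pos <- match(co$subject_ids, M_full$subjects)
    if (anyNA(pos)) {
      stopf("cohort %s subject(s) missing from population matrix: %s",
            co$label, paste(co$subject_ids[is.na(pos)], collapse = ", "))
    }
    if (length(pos) < 2) stopf("cohort %s has fewer than 2 subjects", co$label)
    sub <- population_matrix(M_full$values[, pos, drop = FALSE],
                             subjects = co$subject_ids,
                             task = M_full$task, r = M_full$r)
    lr <- leverage_scores(sub, rank_tolerance)
    lr$cohort <- co$label
    fs <- select_top_k(lr, k)
    fs$params$cohort <- co$label
    fs
  })
}

#' Pairwise percentage intersection of cohort feature sets
#'
#' Entry (a, b) is 100 * |A intersect B| / k; the diagonal is 100 by
#' construction. All sets must share the same k, since the percentage
#' presupposes a common denominator.
#'
#' @param feature_sets list of [feature_set]s with equal k, typically from
#'   [per_cohort_selection].
#' @param labels optional cohort labels for dimnames.
#' @return an object of class `intersection_matrix` wrapping the c x c
#'   percentage matrix.
#' @export
intersection_matrix <- function(feature_sets, labels = NULL) {
  ks <- vapply(feature_sets, function(f) f$k, integer(1))
  if (length(unique(ks)) != 1L) {
    stopf("feature sets have unequal k: %s", paste(unique(ks), collapse = ", "))
  }
  k <- ks[1]
  if (k < 1) stopf("feature sets are empty")
  c_ <- length(feature_sets)
  if (is.null(labels)) {
    labels <- vapply(seq_len(c_), function(i) {
      lbl <- feature_sets[[i]]$params$cohort
      if (is.null(lbl) || is.na(lbl)) sprintf("S%02d", i) else lbl
    }, character(1))
  }
  vals <- diag(100, c_)
  if (c_ >= 2) {
    for (a in seq_len(c_ - 1)) {
      for (b in (a + 1):c_) {
        pct <- 100 * length(intersect(feature_sets[[a]]$indices,
                                      feature_sets[[b]]$indices)) / k
        vals[a, b] <- vals[b, a] <- pct
      }
    }
  }
  dimnames(vals) <- list(labels, labels)
  structure(list(values = vals, labels = labels, k = k), class = "intersection_matrix")
}

#' @export
print.intersection_matrix <- function(x, ...) {
  cat(sprintf("<intersection_matrix> %d sets, k = %d\n", length(x$labels), x$k))
  print(round(x$values, 1))
  invisible(x)
}

#' Mean off-diagonal intersection percentage
#'
#' Summarizes an [intersection_matrix] either over consecutive cohort pairs
#' (the superdiagonal: adjacent age bands) or over all unordered pairs
#' (the strict upper triangle).
#'
#' @param x an `intersection_matrix` with at least 2 sets.
#' @param scope "consecutive" or "all_pairs".
#' @return the mean percentage, a single number.
#' @export
mean_offdiagonal <- function(x, scope = c("consecutive", "all_pairs")) {
  scope <- match.arg(scope)
  v <- x$values
  if (nrow(v) < 2) stopf("need >= 2 feature sets")
  if (scope == "consecutive") {
    mean(v[cbind(seq_len(nrow(v) - 1), seq_len(nrow(v) - 1) + 1)])
  } else {
    mean(v[upper.tri(v)])
  }
}

#' Consensus features across cohorts
#'
#' The intersection of all cohorts' feature sets: features selected in
#' every age band, the candidate age-resilient signature. An empty
#' intersection is a valid outcome and is returned (with a warning) as an
#' empty set.
#'
#' @param feature_sets list of at least 2 [feature_set]s.
#' @return a [feature_set] with provenance "consensus".
#' @export
consensus_features <- function(feature_sets) {
  if (length(feature_sets) < 2) stopf("need >= 2 feature sets")
  idx <- Reduce(intersect, lapply(feature_sets, function(f) f$indices))
  if (!length(idx)) {
    warning("consensus is empty: no feature common to all cohorts", call. = FALSE)
  }
  m <- feature_sets[[1]]$m
  feature_set(idx, m = m, provenance = "consensus",
              params = list(n_sets = length(feature_sets)))
}

#' Region endpoint counts of a feature set
#'
#' Each edge feature touches two regions; this tallies how often each
#' region appears as an endpoint of the given features.
#'
#' @param features a [feature_set] (or 0-based edge index vector).
#' @param r region count.
#' @return named integer vector: names are 0-based region indices (only
#'   regions with nonzero count), values are endpoint counts.
#' @export
consensus_regions <- function(features, r) {
  idx <- if (inherits(features, "feature_set")) features$indices else as.integer(features)
  if (!length(idx)) return(setNames(integer(0), character(0)))
  pairs <- edge_index_to_region_pair(idx, r)
  tab <- table(factor(c(pairs[, 1], pairs[, 2]), levels = 0:(r - 1)))
  tab <- tab[tab > 0]
  setNames(as.integer(tab), names(tab))
}
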
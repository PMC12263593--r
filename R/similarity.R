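restrict_rows <- function(M, features) {
  stopifnot(inherits(M, "population_matrix"))
  idx <- if (inherits(features, "feature_set")) features$indices else as.integer(features)
  if (length(idx) && (min(idx) < 0 || max(idx) >= M$m)) {
    stopf("feature indices outside [0, %d)", M$m)
  }
  M$values[idx + 1L, , drop = FALSE]
}

feature_provenance <- function(features) {
  if (inherits(features, "feature_set")) features$provenance else "custom"
}

similarity_summary <- function(vals, mode, label, features, n_skipped = 0L) {
  structure(
    list(mean = mean(vals), sd = if (length(vals) > 1) sd(vals) else 0,
         n_pairs = length(vals),
         n_skipped = n_skipped, mode = mode, label = label,
         provenance = feature_provenance(features),
         k = if (inherits(features, "feature_set")) features$k else length(features)),
    class = "similarity_summary"
  )
}

#' @export
print.similarity_summary <- function(x, ...) {
  cat(sprintf("<similarity_summary> %s (%s): mean %.4f +/- %.4f over %d pairs (k = %d, %s features)\n",
              x$mode, x$label, x$mean, x$sd, x$n_pairs, x$k, x$provenance))
  invisible(x)
}

#' Inter-subject similarity within one task
#'
#' Pearson correlation between every unordered pair of subjects' connectome
#' vectors, restricted to a feature set. Low values mean the features
#' separate individuals. Pairs involving a zero-variance restricted vector
#' are skipped with a warning.
#'
#' @param M a [population_matrix] with n >= 2 subjects.
#' @param features a [feature_set] (or 0-based index vector) of size >= 3.
#' @return a `similarity_summary` with the mean, SD over the n(n-1)/2
#'   evaluated pairs, and the pair count.
#' @export
inter_subject_similarity <- function(M, features) {
  X <- restrict_rows(M, features)
  if (nrow(X) < 3) stopf("need >= 3 features to correlate subject pairs")
  if (ncol(X) < 2) stopf("need >= 2 subjects")
  C <- suppressWarnings(cor(X))
  vals <- C[upper.tri(C)]
  n_skipped <- sum(is.na(vals))
  if (n_skipped > 0) {
    warning(sprintf("%d pair(s) skipped (zero-variance restricted vector)",
                    n_skipped), call. = FALSE)
    vals <- vals[!is.na(vals)]
  }
  if (!length(vals)) stopf("all subject pairs degenerate; nothing to summarize")
  similarity_summary(vals, "inter_subject_within_task", M$task, features,
                     n_skipped)
}

#' Within-subject similarity across two tasks
#'
#' Per-subject Pearson correlation between the same subject's
#' feature-restricted vectors from two task matrices. High values mean the
#' features are stable within an individual across cognitive states.
#'
#' @param M_a,M_b [population_matrix] objects with identical subject order.
#' @param features a [feature_set] (or 0-based index vector) of size >= 3.
#' @return a `similarity_summary` with n_pairs = n subjects.
#' @export
within_subject_similarity <- function(M_a, M_b, features) {
  if (!identical(M_a$subjects, M_b$subjects)) {
    stopf("subject order differs between the two task matrices")
  }
  Xa <- restrict_rows(M_a, features)
  Xb <- restrict_rows(M_b, features)
  if (nrow(Xa) < 3) stopf("need >= 3 features to correlate task pairs")
  vals <- suppressWarnings(
    vapply(seq_len(ncol(Xa)), function(j) cor(Xa[, j], Xb[, j]), numeric(1)))
  n_skipped <- sum(is.na(vals))
  if (n_skipped > 0) {
    warning(sprintf("%d subject(s) skipped (zero-variance restricted vector)",
                    n_skipped), call. = FALSE)
    vals <- vals[!is.na(vals)]
  }
  if (!length(vals)) stopf("all subjects degenerate; nothing to summarize")
  similarity_summary(vals, "within_subject_cross_task",
                     paste(M_a$task, M_b$task, sep = "-"), features, n_skipped)
}

#' Cross-subject cross-task similarity matrix (internal helper)
#'
#' Full n x n matrix of correlations between task-a vectors and task-b
#' vectors; the diagonal holds within-subject values, the off-diagonal
#' between-subject cross-task values. Used by calibration checks.
#' @keywords internal
cross_task_similarity_matrix <- function(M_a, M_b, features) {
  if (!identical(M_a$subjects, M_b$subjects)) {
    stopf("subject order differs between the two task matrices")
  }
  suppressWarnings(cor(restrict_rows(M_a, features), restrict_rows(M_b, features)))
}

#' Random-feature null distribution for a similarity statistic
#'
#' Repeats a similarity computation on seeded uniform random feature
#' subsets of the same size and locates the observed statistic in that
#' null. The empirical p-value uses the plus-one rule,
#' (1 + #{trials at least as extreme}) / (n_trials + 1), and is therefore
#' floored at 1/(n_trials + 1); a Gaussian tail probability from the null
#' mean and SD (`z_p`) is reported alongside for observed values far
#' beyond the floor.
#'
#' @param M a [population_matrix]; give `M_b` too for the within-subject
#'   cross-task statistic.
#' @param k random subset size.
#' @param n_trials number of null draws (>= 100).
#' @param seed integer seed.
#' @param observed the observed mean similarity to locate in the null.
#' @param side "lower" if small observed values are extreme, "higher"
#'   otherwise.
#' @param M_b optional second task matrix.
#' @return an object of class `null_distribution`: per-trial means,
#'   `null_mean`, `null_sd`, `observed`, `empirical_p`, `z_p`.
#' @export
random_feature_null <- function(M, k, n_trials, seed, observed,
                                side = c("lower", "higher"), M_b = NULL) {
  side <- match.arg(side)
  if (n_trials < 100) stopf("need n_trials >= 100")
  if (k > M$m) stopf("k (%d) exceeds feature pool (%d)", k, M$m)
  trials <- with_seed(seed, {
    vapply(seq_len(n_trials), function(i) {
      idx <- sample.int(M$m, k)
      if (is.null(M_b)) {
        X <- M$values[idx, , drop = FALSE]
        C <- suppressWarnings(cor(X))
        mean(C[upper.tri(C)], na.rm = TRUE)
      } else {
        Xa <- M$values[idx, , drop = FALSE]
        Xb <- M_b$values[idx, , drop = FALSE]
        mean(vapply(seq_len(ncol(Xa)), function(j) cor(Xa[, j], Xb[, j]),
                    numeric(1)), na.rm = TRUE)
      }
    }, numeric(1))
  })
  n_extreme <- if (side == "lower") sum(trials <= observed) else sum(trials >= observed)
  empirical_p <- (1 + n_extreme) / (n_trials + 1)
  mu <- mean(trials); s <- sd(trials)
  z_p <- if (side == "lower") pnorm(observed, mu, s) else pnorm(observed, mu, s, lower.tail = FALSE)
  structure(
    list(trials = trials, n_trials = n_trials, seed = seed,
         observed = observed, side = side, null_mean = mu, null_sd = s,
         empirical_p = empirical_p, z_p = z_p),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d trials: null %.4f +/- %.4f; observed %.4f (%s), empirical p = %.3g, z_p = %.3g\n",
              x$n_trials, x$null_mean, x$null_sd, x$observed, x$side,
              x$empirical_p, x$z_p))
  invisible(x)
}
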
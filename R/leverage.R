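#' Row leverage scores of a population matrix
#'
#' For a tall features x subjects matrix M, let U be an orthonormal basis
#' of the column space of M (the left singular vectors with singular value
#' above `rank_tolerance` times the largest). The leverage score of row i
#' is the squared Euclidean norm of row i of U — equivalently the i-th
#' diagonal entry of the orthogonal projector M (M'M)^+ M'. Scores lie in
#' [0, 1], sum to the numerical rank, and are invariant to any invertible
#' right-multiplication of M (change of subject basis).
#'
#' @param M a [population_matrix], or a plain numeric matrix with at least
#'   as many rows as columns.
#' @param rank_tolerance relative singular-value cutoff (default 1e-10);
#'   duplicated subjects or tasks can make M rank-deficient.
#' @return an object of class `leverage_result`: `scores` (length m),
#'   `rank`, plus `task`/`cohort` provenance.
#' @export
leverage_scores <- function(M, rank_tolerance = 1e-10) {
  if (inherits(M, "population_matrix")) {
    values <- M$values; task <- M$task
  } else {
    values <- as.matrix(M); task <- NA_character_
  }
  m <- nrow(values); n <- ncol(values)
  if (m < n || n < 1) stopf("need m >= n >= 1 (got %d x %d)", m, n)
  if (all(values == 0)) stopf("all-zero matrix has no column space")
  s <- svd(values, nu = n, nv = 0)
  keep <- s$d > rank_tolerance * s$d[1]
  U <- s$u[, keep, drop = FALSE]
  scores <- rowSums(U^2)
  scores <- pmin(pmax(scores, 0), 1)  # clamp roundoff at the boundary
  structure(
    list(scores = scores, rank = sum(keep), task = task,
         cohort = NA_character_),
    class = "leverage_result"
  )
}

#' @export
print.leverage_result <- function(x, ...) {
  cat(sprintf("<leverage_result> %d features, rank %d, score sum %.4f\n",
              length(x$scores), x$rank, sum(x$scores)))
  invisible(x)
}

#' Feature set container
#'
#' A set of 0-based edge indices with its provenance (how it was produced
#' and with what parameters), the unit of all stability and similarity
#' comparisons.
#'
#' @param indices 0-based edge indices; stored sorted and unique.
#' @param m size of the feature pool the indices refer to (optional but
#'   recommended; enables range checks downstream).
#' @param provenance one of "leverage", "random", "consensus".
#' @param params named list of generating parameters (task, cohort, seed, ...).
#' @return an object of class `feature_set`.
#' @export
feature_set <- function(indices, m = NA_integer_,
                        provenance = c("leverage", "random", "consensus"),
                        params = list()) {
  provenance <- match.arg(provenance)
  indices <- as.integer(indices)
  if (anyNA(indices) || any(indices < 0)) stopf("edge indices must be >= 0")
  if (anyDuplicated(indices)) stopf("edge indices must be unique")
  if (!is.na(m) && length(indices) && max(indices) >= m) {
    stopf("edge index %d outside feature pool of size %d", max(indices), m)
  }
  structure(
    list(indices = sort(indices), k = length(indices), m = as.integer(m),
         provenance = provenance, params = params),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> k = %d (%s)\n", x$k, x$provenance))
  invisible(x)
}

#' Deterministically retain the top-k leverage features
#'
#' Sorts scores in descending order and keeps the k largest; ties are
#' broken by ascending edge index, so the selection is reproducible across
#' platforms.
#'
#' @param result a [leverage_result] (or a plain numeric score vector).
#' @param k number of features to retain, in [1, m].
#' @return a [feature_set] with provenance "leverage".
#' @export
select_top_k <- function(result, k) {
  scores <- if (inherits(result, "leverage_result")) result$scores else as.numeric(result)
  m <- length(scores)
  if (k < 1 || k > m) stopf("k must lie in [1, %d], got %s", m, format(k))
  ord <- order(scores, decreasing = TRUE)  # stable: ties stay in index order
  idx <- sort(ord[seq_len(k)]) - 1L
  params <- if (inherits(result, "leverage_result")) {
    list(task = result$task, cohort = result$cohort)
  } else list()
  feature_set(idx, m = m, provenance = "leverage", params = params)
}

#' Uniform random feature subsets (selection baseline)
#'
#' Draws k of m edge indices uniformly without replacement under `seed`,
#' matching the size of a leverage selection for null comparisons.
#'
#' @param m feature pool size.
#' @param k subset size (<= m).
#' @param seed integer seed.
#' @return a [feature_set] with provenance "random".
#' @export
sample_random_features <- function(m, k, seed) {
  if (k > m) stopf("k (%s) exceeds pool size m (%s)", format(k), format(m))
  idx <- with_seed(seed, sample.int(m, k)) - 1L
  feature_set(idx, m = m, provenance = "random", params = list(seed = seed))
}
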
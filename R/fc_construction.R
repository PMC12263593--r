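#' Number of connectome edge features for r regions
#'
#' The upper triangle of an r x r correlation matrix holds r(r-1)/2
#' distinct region-pair features.
#'
#' @param r region count (>= 2).
#' @return integer edge count.
#' @examples
#' n_edges(116) # 6670
#' @export
n_edges <- function(r) {
  stopifnot(r >= 2)
  as.integer(round(r * (r - 1) / 2))
}

#' Regional time-series container
#'
#' Holds one scan's regions x timepoints signal matrix together with the
#' region identifiers and scan provenance.
#'
#' @param values numeric matrix, one row per region, one column per timepoint.
#' @param region_ids identifiers for the rows; defaults to the rownames or
#'   `0:(r-1)`.
#' @param subject_id,task scan provenance labels.
#' @return an object of class `regional_time_series`.
#' @export
regional_time_series <- function(values, region_ids = NULL,
                                 subject_id = NA_character_,
                                 task = NA_character_) {
  values <- as.matrix(values)
  if (nrow(values) < 2 || ncol(values) < 2) {
    stopf("a regional time series needs >= 2 regions and >= 2 timepoints")
  }
  if (anyNA(values)) stopf("time series contains missing values")
  if (is.null(region_ids)) {
    region_ids <- if (!is.null(rownames(values))) rownames(values)
                  else as.character(seq_len(nrow(values)) - 1L)
  }
  if (length(region_ids) != nrow(values)) {
    stopf("region_ids length (%d) != region count (%d)",
          length(region_ids), nrow(values))
  }
  structure(
    list(values = unname(values), region_ids = as.character(region_ids),
         subject_id = subject_id, task = task),
    class = "regional_time_series"
  )
}

#' @export
print.regional_time_series <- function(x, ...) {
  cat(sprintf("<regional_time_series> %d regions x %d timepoints (subject %s, task %s)\n",
              nrow(x$values), ncol(x$values), x$subject_id, x$task))
  invisible(x)
}

#' Vectorized connectome container
#'
#' The upper triangle of one scan's correlation matrix, stored in the
#' canonical row-major edge order (see [edge_index_to_region_pair]).
#'
#' @param values numeric vector of length r(r-1)/2 with entries in [-1, 1].
#' @param r region count the vector was derived from.
#' @param subject_id,task scan provenance labels.
#' @return an object of class `connectome_vector`.
#' @export
connectome_vector <- function(values, r, subject_id = NA_character_,
                              task = NA_character_) {
  values <- as.numeric(values)
  m <- n_edges(r)
  if (length(values) != m) {
    stopf("connectome vector for r = %d must have length %d, got %d",
          r, m, length(values))
  }
  if (anyNA(values)) stopf("connectome vector contains missing values")
  if (any(values < -1 - 1e-8) || any(values > 1 + 1e-8)) {
    stopf("connectome values must lie in [-1, 1]")
  }
  structure(
    list(values = values, r = as.integer(r),
         subject_id = subject_id, task = task),
    class = "connectome_vector"
  )
}

#' Population matrix of stacked connectome vectors
#'
#' Features x subjects matrix for one task: column j is subject j's
#' vectorized connectome.
#'
#' @param values numeric matrix, m = r(r-1)/2 rows, one column per subject.
#' @param subjects subject identifiers, one per column.
#' @param task task label shared by all columns.
#' @param r region count.
#' @return an object of class `population_matrix`.
#' @export
population_matrix <- function(values, subjects, task, r) {
  values <- as.matrix(values)
  m <- n_edges(r)
  if (nrow(values) != m) {
    stopf("population matrix for r = %d must have %d rows, got %d",
          r, m, nrow(values))
  }
  subjects <- as.character(subjects)
  if (length(subjects) != ncol(values)) {
    stopf("one subject id per column required (%d ids, %d columns)",
          length(subjects), ncol(values))
  }
  if (anyDuplicated(subjects)) stopf("duplicate subject ids in population matrix")
  structure(
    list(values = unname(values), subjects = subjects,
         task = task, r = as.integer(r), m = m),
    class = "population_matrix"
  )
}

#' @export
print.population_matrix <- function(x, ...) {
  cat(sprintf("<population_matrix> %d features x %d subjects (task %s, r = %d)\n",
              x$m, length(x$subjects), x$task, x$r))
  invisible(x)
}

#' Parcellate voxel time series into regional time series
#'
#' Averages voxel rows within each region, per timepoint. Regions are
#' ordered by ascending region id in the output.
#'
#' @param voxel_ts numeric matrix, voxels x timepoints.
#' @param labels region id for each voxel row (length `nrow(voxel_ts)`).
#' @param regions optional vector of region ids that must all be present;
#'   a listed region with zero voxels is an error naming the region.
#' @param subject_id,task scan provenance labels, passed through.
#' @return a [regional_time_series] with one row per region.
#' @export
parcellate <- function(voxel_ts, labels, regions = NULL,
                       subject_id = NA_character_, task = NA_character_) {
  voxel_ts <- as.matrix(voxel_ts)
  if (length(labels) != nrow(voxel_ts)) {
    stopf("labels length (%d) != voxel count (%d)",
          length(labels), nrow(voxel_ts))
  }
  if (anyNA(labels)) stopf("every voxel must carry a region label")
  labels <- as.character(labels)
  if (!is.null(regions)) {
    missing <- setdiff(as.character(regions), labels)
    if (length(missing)) {
      stopf("region(s) with zero voxels: %s", paste(missing, collapse = ", "))
    }
  }
  ids <- sort(unique(labels))
  out <- t(vapply(ids, function(id) {
    colMeans(voxel_ts[labels == id, , drop = FALSE])
  }, numeric(ncol(voxel_ts))))
  regional_time_series(out, region_ids = ids,
                       subject_id = subject_id, task = task)
}

#' Pearson functional-connectivity matrix of a regional time series
#'
#' Computes the r x r matrix of pairwise Pearson correlations between
#' regional signals. A zero-variance region gets correlation 0 with every
#' other region (with a warning) rather than NA, so downstream leverage
#' computation never sees missing values.
#'
#' @param ts a [regional_time_series] (or plain regions x timepoints matrix)
#'   with at least 3 timepoints.
#' @return symmetric numeric matrix with unit diagonal.
#' @export
compute_fc <- function(ts) {
  values <- if (inherits(ts, "regional_time_series")) ts$values else as.matrix(ts)
  if (ncol(values) < 3) stopf("need >= 3 timepoints to correlate")
  sds <- apply(values, 1, sd)
  fc <- suppressWarnings(cor(t(values)))
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance region(s); their correlations set to 0",
                    sum(sds == 0)), call. = FALSE)
    fc[sds == 0, ] <- 0
    fc[, sds == 0] <- 0
  }
  diag(fc) <- 1
  fc
}

#' Vectorize the upper triangle of a correlation matrix
#'
#' Extracts the r(r-1)/2 above-diagonal entries in the canonical row-major
#' order (0,1), (0,2), ..., (0,r-1), (1,2), ... and returns them as a
#' [connectome_vector]. The matrix must be symmetric with unit diagonal
#' (within `tol`); correlation matrices always are, so a violation signals
#' an upstream bug.
#'
#' @param corr square numeric matrix.
#' @param subject_id,task provenance labels.
#' @param tol symmetry / unit-diagonal tolerance.
#' @return a [connectome_vector] of length r(r-1)/2.
#' @export
vectorize_upper <- function(corr, subject_id = NA_character_,
                            task = NA_character_, tol = 1e-8) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr)) stopf("matrix must be square")
  if (max(abs(corr - t(corr))) > tol) {
    stopf("matrix asymmetric beyond tolerance %g", tol)
  }
  if (max(abs(diag(corr) - 1)) > tol) {
    stopf("diagonal differs from 1 beyond tolerance %g", tol)
  }
  r <- nrow(corr)
  # row-major upper triangle == column-major lower triangle of the transpose
  tm <- t(corr)
  connectome_vector(tm[lower.tri(tm)], r = r,
                    subject_id = subject_id, task = task)
}

#' Map a canonical edge index to its region pair (and back)
#'
#' Edges are numbered 0-based in row-major order over region pairs
#' (i, j) with i < j and 0-based regions: index(i, j) =
#' i*r - i(i+1)/2 + (j - i - 1). `edge_index_to_region_pair` inverts this;
#' `region_pair_to_index` is its exact inverse. Both are vectorized.
#'
#' @param k 0-based edge index (vectorized), in [0, r(r-1)/2).
#' @param r region count.
#' @return for `edge_index_to_region_pair`, a two-column integer matrix of
#'   0-based (i, j) pairs with i < j; for `region_pair_to_index`, an
#'   integer vector of edge indices.
#' @examples
#' edge_index_to_region_pair(0:2, r = 3)
#' region_pair_to_index(838, 839, r = 840) # 352379
#' @export
edge_index_to_region_pair <- function(k, r) {
  m <- n_edges(r)
  k <- as.numeric(k)
  if (any(is.na(k)) || any(k < 0) || any(k >= m) || any(k != floor(k))) {
    stopf("edge index out of range [0, %d)", m)
  }
  # row i occupies indices [offset[i], offset[i] + (r - 1 - i))
  offsets <- c(0, cumsum(seq(r - 1, 1)))
  i <- findInterval(k, offsets, rightmost.closed = FALSE) - 1L
  j <- as.integer(k - offsets[i + 1L] + i + 1L)
  cbind(i = as.integer(i), j = j)
}

#' @rdname edge_index_to_region_pair
#' @param i,j 0-based region indices with i < j (vectorized).
#' @export
region_pair_to_index <- function(i, j, r) {
  i <- as.numeric(i); j <- as.numeric(j)
  if (any(i < 0) || any(j >= r) || any(i >= j)) {
    stopf("need 0 <= i < j < r")
  }
  as.integer(i * r - i * (i + 1) / 2 + (j - i - 1))
}

#' Stack connectome vectors into a population matrix
#'
#' @param vectors list of [connectome_vector]s sharing `r` and `task`.
#' @param subjects subject order for the columns; defaults to the vectors'
#'   own subject ids. One vector per listed subject.
#' @return a [population_matrix] whose column j is the listed subject j's
#'   vector.
#' @export
assemble_population <- function(vectors, subjects = NULL) {
  stopifnot(length(vectors) >= 1)
  rs <- vapply(vectors, function(v) v$r, integer(1))
  tasks <- vapply(vectors, function(v) as.character(v$task), character(1))
  if (length(unique(rs)) != 1L) stopf("vectors mix region counts: %s",
                                      paste(unique(rs), collapse = ", "))
  if (length(unique(tasks)) != 1L) stopf("vectors mix tasks: %s",
                                         paste(unique(tasks), collapse = ", "))
  ids <- vapply(vectors, function(v) as.character(v$subject_id), character(1))
  if (anyDuplicated(ids)) stopf("duplicate subject in input vectors")
  if (is.null(subjects)) subjects <- ids
  pos <- match(as.character(subjects), ids)
  if (anyNA(pos)) {
    stopf("subject(s) without a vector: %s",
          paste(subjects[is.na(pos)], collapse = ", "))
  }
  values <- vapply(vectors[pos], function(v) v$values,
                   numeric(length(vectors[[1]]$values)))
  population_matrix(values, subjects = subjects, task = tasks[1], r = rs[1])
}

#' Exclude regions with insufficient functional coverage
#'
#' Builds a per-subject functional mask (voxels whose intensity exceeds
#' `mask_fraction` times that subject's mean intensity over all voxels) and
#' excludes any region whose within-mask voxel fraction falls below
#' `coverage_min` for at least one subject. Boundary coverage exactly equal
#' to `coverage_min` is retained.
#'
#' @param mean_images subjects x voxels matrix of nonnegative mean signal
#'   intensities.
#' @param labels region id per voxel column.
#' @param mask_fraction mask threshold as a fraction of the subject mean
#'   intensity (default 0.7).
#' @param coverage_min minimum within-mask fraction of a region's voxels
#'   (default 0.5).
#' @return list with sorted character vectors `retained` and `excluded`;
#'   their union is all regions.
#' @export
exclude_low_coverage_rois <- function(mean_images, labels,
                                      mask_fraction = 0.7,
                                      coverage_min = 0.5) {
  mean_images <- as.matrix(mean_images)
  if (length(labels) != ncol(mean_images)) {
    stopf("labels length (%d) != voxel count (%d)",
          length(labels), ncol(mean_images))
  }
  if (anyNA(labels)) stopf("every voxel must carry a region label")
  if (any(mean_images < 0)) stopf("intensities must be nonnegative")
  labels <- as.character(labels)
  regions <- sort(unique(labels))
  masks <- mean_images > mask_fraction * rowMeans(mean_images)
  excluded <- vapply(regions, function(rg) {
    cols <- labels == rg
    if (!any(cols)) stopf("region %s has no voxels", rg)
    coverage <- rowMeans(masks[, cols, drop = FALSE])
    any(coverage < coverage_min)
  }, logical(1))
  list(retained = regions[!excluded], excluded = regions[excluded])
}

#' Drop edges touching excluded regions from a population matrix
#'
#' Re-indexes the feature space to the retained regions: keeps only edges
#' whose both endpoints are retained and renumbers regions 0..r'-1 in the
#' order given by `retained` (ascending original index), so the result is a
#' valid [population_matrix] over the reduced parcellation.
#'
#' @param M a [population_matrix].
#' @param retained 0-based original region indices to keep (>= 2).
#' @return list with the reduced population matrix `M`, the kept 0-based
#'   original edge indices `old_edges` (in new-edge order), and the
#'   old-to-new region map `region_map` (named integer vector).
#' @export
drop_excluded_edges <- function(M, retained) {
  stopifnot(inherits(M, "population_matrix"))
  retained <- sort(unique(as.integer(retained)))
  if (any(retained < 0) || any(retained >= M$r)) {
    stopf("retained region indices must lie in [0, %d)", M$r)
  }
  if (length(retained) < 2) stopf("need >= 2 retained regions")
  new_r <- length(retained)
  region_map <- setNames(seq_along(retained) - 1L, retained)
  pairs <- edge_index_to_region_pair(seq_len(M$m) - 1L, M$r)
  keep <- pairs[, 1] %in% retained & pairs[, 2] %in% retained
  old_edges <- which(keep) - 1L
  new_idx <- region_pair_to_index(region_map[as.character(pairs[keep, 1])],
                                  region_map[as.character(pairs[keep, 2])],
                                  new_r)
  ord <- order(new_idx)
  reduced <- population_matrix(M$values[old_edges[ord] + 1L, , drop = FALSE],
                               subjects = M$subjects, task = M$task, r = new_r)
  list(M = reduced, old_edges = old_edges[ord], region_map = region_map)
}
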
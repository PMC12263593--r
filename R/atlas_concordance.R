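#' Region selection frequency across cohorts
#'
#' Accumulates, over a list of per-cohort feature sets, how often each
#' region appears as an endpoint of a selected edge. By default both
#' endpoints of every selected edge in every cohort count; with
#' `unique_per_cohort` a region counts at most once per cohort.
#'
#' @param feature_sets list of [feature_set]s (one per cohort).
#' @param r region count of the parcellation the edges index.
#' @param atlas_name,task provenance labels.
#' @param unique_per_cohort count each region at most once per cohort.
#' @return an object of class `region_frequency`: `counts` (named integer
#'   vector over 0-based region indices, zero-count regions included),
#'   `atlas_name`, `task`.
#' @export
region_frequency <- function(feature_sets, r, atlas_name = NA_character_,
                             task = NA_character_, unique_per_cohort = FALSE) {
  counts <- setNames(integer(r), as.character(0:(r - 1)))
  for (fs in feature_sets) {
    idx <- if (inherits(fs, "feature_set")) fs$indices else as.integer(fs)
    if (!length(idx)) next
    pairs <- edge_index_to_region_pair(idx, r)
    ends <- c(pairs[, 1], pairs[, 2])
    if (unique_per_cohort) ends <- unique(ends)
    tab <- table(factor(ends, levels = 0:(r - 1)))
    counts <- counts + as.integer(tab)
  }
  structure(list(counts = counts, r = as.integer(r),
                 atlas_name = atlas_name, task = task),
            class = "region_frequency")
}

#' @export
print.region_frequency <- function(x, ...) {
  cat(sprintf("<region_frequency> %s/%s: %d of %d regions with nonzero count\n",
              x$atlas_name, x$task, sum(x$counts > 0), x$r))
  invisible(x)
}

#' Most frequently selected regions
#'
#' Regions with nonzero count, sorted by (count descending, region index
#' ascending), truncated to `ceiling(fraction * number of nonzero-count
#' regions)`. The ascending-index tie-break makes the set deterministic.
#'
#' @param freq a [region_frequency].
#' @param fraction fraction of nonzero-count regions to keep, in (0, 1].
#' @return character vector of 0-based region indices (in rank order).
#' @export
top_frequent_regions <- function(freq, fraction = 0.5) {
  if (fraction <= 0 || fraction > 1) stopf("fraction must lie in (0, 1]")
  nz <- freq$counts[freq$counts > 0]
  if (!length(nz)) stopf("no region has nonzero frequency")
  ord <- order(-nz, as.integer(names(nz)))
  names(nz)[ord][seq_len(ceiling(fraction * length(nz)))]
}

#' Match selected regions of one atlas into another by centroid lookup
#'
#' A region of atlas A matches if atlas B's label at A's region centroid
#' (mm coordinate mapped through B's inverse affine to the nearest voxel)
#' belongs to the selected region set of B. The centroid rule is one
#' deliberate, deterministic operationalization of coordinate
#' intersection; it is direction-dependent, so concordance reports should
#' run both directions (see [overlap_coefficient]).
#'
#' @param regions_a region ids of atlas A to match (atlas A id space).
#' @param atlas_a,atlas_b [atlas_definition]s sharing an mm space.
#' @param regions_b selected region ids of atlas B.
#' @return the subset of `regions_a` that matched. Regions whose centroid
#'   falls outside atlas B's grid are unmatched (with a message).
#' @export
match_regions_across_atlases <- function(regions_a, atlas_a, regions_b, atlas_b) {
  regions_a <- as.character(regions_a)
  regions_b <- as.character(regions_b)
  missing <- setdiff(regions_a, rownames(atlas_a$centroids))
  if (length(missing)) stopf("unknown atlas A region(s): %s",
                             paste(missing, collapse = ", "))
  inv <- solve(atlas_b$affine)
  dims <- dim(atlas_b$labels)
  matched <- vapply(regions_a, function(rg) {
    mm <- atlas_a$centroids[rg, ]
    vox <- round(as.numeric(inv %*% c(mm, 1))[1:3])
    if (any(vox < 0) || any(vox >= dims)) {
      message(sprintf("region %s centroid outside atlas '%s' grid; unmatched",
                      rg, atlas_b$name))
      return(FALSE)
    }
    lab <- atlas_b$labels[vox[1] + 1, vox[2] + 1, vox[3] + 1]
    !is.na(lab) && lab != 0 && as.character(lab) %in% regions_b
  }, logical(1))
  regions_a[matched]
}

#' Min-normalized overlap coefficient of two region sets
#'
#' Overlap(A, B) = |A intersect B| / min(|A|, |B|), with the intersection
#' size supplied as the matched subset from cross-atlas matching. The min
#' normalization (rather than the Dice denominator) keeps the coefficient
#' comparable when region sizes differ strongly between fine- and
#' coarse-grained atlases.
#'
#' @param set_a,set_b the two region sets (nonempty).
#' @param matches the matched subset standing in for A intersect B.
#' @return a number in [0, 1].
#' @export
overlap_coefficient <- function(set_a, set_b, matches) {
  if (!length(set_a) || !length(set_b)) stopf("region sets must be nonempty")
  if (length(matches) > min(length(set_a), length(set_b))) {
    stopf("more matches (%d) than the smaller set (%d)",
          length(matches), min(length(set_a), length(set_b)))
  }
  length(matches) / min(length(set_a), length(set_b))
}

# distinct selected target regions hit by the source set's centroids; a
# genuine subset of regions_b, so its size never exceeds min(|A|, |B|)
matched_target_regions <- function(regions_a, atlas_a, regions_b, atlas_b) {
  regions_a <- as.character(regions_a)
  regions_b <- as.character(regions_b)
  inv <- solve(atlas_b$affine)
  dims <- dim(atlas_b$labels)
  hits <- vapply(regions_a, function(rg) {
    mm <- atlas_a$centroids[rg, ]
    vox <- round(as.numeric(inv %*% c(mm, 1))[1:3])
    if (any(vox < 0) || any(vox >= dims)) return(NA_character_)
    as.character(atlas_b$labels[vox[1] + 1, vox[2] + 1, vox[3] + 1])
  }, character(1))
  intersect(regions_b, hits)
}

#' Symmetric cross-atlas concordance report
#'
#' Runs centroid matching in both directions between the top frequent
#' regions of two atlases. For each direction the intersection is the set
#' of distinct selected target regions hit by the source regions'
#' centroids (so it is a true subset of the target set), divided by the
#' smaller set size.
#'
#' @param regions_a,regions_b selected region id sets.
#' @param atlas_a,atlas_b the two [atlas_definition]s.
#' @return list with `overlap_ab`, `overlap_ba`, `n_a`, `n_b`,
#'   `n_matched_ab`, `n_matched_ba`.
#' @export
cross_atlas_overlap <- function(regions_a, atlas_a, regions_b, atlas_b) {
  m_ab <- matched_target_regions(regions_a, atlas_a, regions_b, atlas_b)
  m_ba <- matched_target_regions(regions_b, atlas_b, regions_a, atlas_a)
  list(
    overlap_ab = overlap_coefficient(regions_a, regions_b, m_ab),
    overlap_ba = overlap_coefficient(regions_b, regions_a, m_ba),
    n_a = length(regions_a), n_b = length(regions_b),
    n_matched_ab = length(m_ab), n_matched_ba = length(m_ba)
  )
}

#' Percentage of atlas A's labeled voxels also labeled in atlas B
#'
#' Both atlases must live on the same voxel grid with the same affine;
#' a voxel counts as labeled when its label is neither 0 nor NA.
#'
#' @param atlas_a,atlas_b [atlas_definition]s on a common grid.
#' @return percentage in [0, 100].
#' @export
voxel_overlap_percentage <- function(atlas_a, atlas_b) {
  if (!identical(dim(atlas_a$labels), dim(atlas_b$labels)) ||
      max(abs(atlas_a$affine - atlas_b$affine)) > 1e-8) {
    stopf("atlases are on different grids; resample before comparing")
  }
  lab_a <- !is.na(atlas_a$labels) & atlas_a$labels != 0
  lab_b <- !is.na(atlas_b$labels) & atlas_b$labels != 0
  if (!any(lab_a)) stopf("atlas A has no labeled voxels")
  100 * sum(lab_a & lab_b) / sum(lab_a)
}
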
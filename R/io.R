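#' Read and write the package's plain-text interchange formats
#'
#' Tab-separated formats shared by all stages: subject metadata
#' (subject_id, age, sex), regional time series (first column region_id,
#' remaining columns timepoints), connectome vectors (edge_index,
#' region_i, region_j, value), population matrices (edge_index then one
#' column per subject), feature sets (edge_index, region_i, region_j,
#' optional score), and atlases (voxel table plus a JSON affine sidecar).
#'
#' @param x object to write.
#' @param path file path (for atlases, the voxel TSV; the affine goes to
#'   `<path>.affine.json`).
#' @name connectoprint_io
NULL

#' @rdname connectoprint_io
#' @export
write_metadata_tsv <- function(x, path) {
  md <- if (inherits(x, "synthetic_study")) x$metadata else x
  write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname connectoprint_io
#' @export
read_metadata_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = c(subject_id = "character"))
}

#' @rdname connectoprint_io
#' @export
write_regional_ts_tsv <- function(x, path) {
  stopifnot(inherits(x, "regional_time_series"))
  df <- data.frame(region_id = x$region_ids, x$values, check.names = FALSE)
  colnames(df) <- c("region_id", sprintf("t%d", seq_len(ncol(x$values))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname connectoprint_io
#' @param subject_id,task provenance for readers.
#' @export
read_regional_ts_tsv <- function(path, subject_id = NA_character_,
                                 task = NA_character_) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  regional_time_series(as.matrix(df[, -1, drop = FALSE]),
                       region_ids = as.character(df[[1]]),
                       subject_id = subject_id, task = task)
}

#' @rdname connectoprint_io
#' @export
write_connectome_tsv <- function(x, path) {
  stopifnot(inherits(x, "connectome_vector"))
  pairs <- edge_index_to_region_pair(seq_along(x$values) - 1L, x$r)
  df <- data.frame(edge_index = seq_along(x$values) - 1L,
                   region_i = pairs[, 1], region_j = pairs[, 2],
                   value = x$values)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname connectoprint_io
#' @param r region count for readers that need it.
#' @export
read_connectome_tsv <- function(path, r, subject_id = NA_character_,
                                task = NA_character_) {
  df <- read.table(path, sep = "\t", header = TRUE)
  df <- df[order(df$edge_index), ]
  connectome_vector(df$value, r = r, subject_id = subject_id, task = task)
}

#' @rdname connectoprint_io
#' @export
write_population_tsv <- function(x, path) {
  stopifnot(inherits(x, "population_matrix"))
  df <- data.frame(edge_index = seq_len(x$m) - 1L, x$values,
                   check.names = FALSE)
  colnames(df) <- c("edge_index", x$subjects)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname connectoprint_io
#' @export
read_population_tsv <- function(path, r, task = NA_character_) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  df <- df[order(df$edge_index), , drop = FALSE]
  population_matrix(as.matrix(df[, -1, drop = FALSE]),
                    subjects = colnames(df)[-1], task = task, r = r)
}

#' @rdname connectoprint_io
#' @param scores optional per-feature scores to store alongside a feature set.
#' @export
write_feature_set_tsv <- function(x, path, r = NULL, scores = NULL) {
  stopifnot(inherits(x, "feature_set"))
  df <- data.frame(edge_index = x$indices)
  if (!is.null(r)) {
    pairs <- edge_index_to_region_pair(x$indices, r)
    df$region_i <- pairs[, 1]; df$region_j <- pairs[, 2]
  }
  if (!is.null(scores)) df$score <- scores[x$indices + 1L]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname connectoprint_io
#' @param m feature pool size for feature-set readers.
#' @param provenance provenance label to attach on read.
#' @export
read_feature_set_tsv <- function(path, m = NA_integer_,
                                 provenance = "leverage") {
  df <- read.table(path, sep = "\t", header = TRUE)
  feature_set(df$edge_index, m = m, provenance = provenance)
}

#' @rdname connectoprint_io
#' @export
write_atlas_tsv <- function(x, path) {
  stopifnot(inherits(x, "atlas_definition"))
  keep <- !is.na(x$labels) & x$labels != 0
  coords <- which(keep, arr.ind = TRUE) - 1L
  df <- data.frame(x_voxel = coords[, 1], y_voxel = coords[, 2],
                   z_voxel = coords[, 3], region_id = x$labels[keep])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(affine = x$affine, dim = dim(x$labels),
                            name = x$name),
                       paste0(path, ".affine.json"), digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname connectoprint_io
#' @export
read_atlas_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".affine.json"),
                              simplifyVector = TRUE)
  labels <- array(0L, dim = meta$dim)
  labels[cbind(df$x_voxel, df$y_voxel, df$z_voxel) + 1L] <- df$region_id
  aff <- meta$affine
  if (!is.matrix(aff)) aff <- matrix(unlist(aff), 4, 4, byrow = TRUE)
  atlas_definition(labels, affine = aff,
                   name = if (is.null(meta$name)) "atlas" else meta$name)
}

#' @rdname connectoprint_io
#' @export
write_centroids_tsv <- function(x, path) {
  stopifnot(inherits(x, "atlas_definition"))
  df <- data.frame(region_id = rownames(x$centroids), x$centroids)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
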
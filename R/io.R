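# Plain-text serialisation of the pipeline's intermediate objects:
# square CSV for distance matrices, CSV for coordinates, JSON for records.

#' Write a distance matrix as a square CSV
#'
#' @param d a `dist` or symmetric matrix with item names.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(d, path) {
  m <- as.matrix(d)
  utils::write.csv(m, path)
  invisible(path)
}

#' Read a distance matrix written by [write_distance_csv()]
#'
#' @param path CSV file with id header row and column.
#' @return a `dist` object.
#' @export
read_distance_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1L, check.names = FALSE))
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop("not a square labelled distance matrix: ", path)
  }
  if (max(abs(m - t(m))) > 1e-12) stop("matrix is not symmetric: ", path)
  stats::as.dist(m)
}

#' Write ordination coordinates as CSV
#'
#' @param ord an `nmds_fit` or a coordinate matrix with row names.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_coordinates_csv <- function(ord, path) {
  pts <- if (inherits(ord, "nmds_fit")) ord$points else as.matrix(ord)
  utils::write.csv(pts, path)
  invisible(path)
}
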
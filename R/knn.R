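#' Pairwise Euclidean distance matrix
#'
#' Exact dense distances, computed in compiled code via the Gram-matrix
#' identity. Used as the substrate of every neighborhood metric.
#'
#' @param x Numeric matrix (points in rows) or any object accepted by the
#'   package's coordinate coercion (`expression_matrix`, `embedding2d`).
#' @return An n x n numeric matrix.
#' @keywords internal
#' @export
pairwise_dist <- function(x) {
  m <- as_coords(x)
  check_finite(m, "points")
  cpp_pairwise_dist(m)
}

#' Exact k-nearest-neighbour graph
#'
#' Brute-force Euclidean k nearest neighbours. Self-neighbours are excluded;
#' exact distance ties are broken by ascending point index, so the graph is
#' fully deterministic. Duplicate points (distance 0) are valid neighbours.
#'
#' @param points Numeric matrix or coordinate-bearing object.
#' @param k Number of neighbours, `1 <= k < n`.
#' @param space_tag Optional tag (`"HD"` or `"2D"`) recorded on the graph.
#' @return An object of class `knn_graph`: list with `k`, `indices`
#'   (n x k integer matrix, rows ordered by non-decreasing distance),
#'   `dists`, and `space_tag`.
#' @examples
#' g <- knn_graph(cbind(c(0, 1, 3), 0), k = 1)
#' g$indices
#' @export
knn_graph <- function(points, k, space_tag = NA_character_) {
  m <- as_coords(points)
  check_finite(m, "points")
  k <- as.integer(k)
  n <- nrow(m)
  if (k < 1) abort("k must be >= 1")
  if (n <= k) abort(sprintf("need n > k (n = %d, k = %d)", n, k))
  res <- cpp_knn_from_dist(cpp_pairwise_dist(m), k)
  structure(list(k = k, indices = res$indices, dists = res$dists,
                 space_tag = space_tag),
            class = "knn_graph")
}

#' @export
print.knn_graph <- function(x, ...) {
  cat(sprintf("<knn_graph> n=%d k=%d%s\n", nrow(x$indices), x$k,
              if (is.na(x$space_tag)) "" else paste0(" (", x$space_tag, ")")))
  invisible(x)
}
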
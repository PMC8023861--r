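#' Number of unique edges for a given node count
#'
#' An edge is an unordered pair of distinct nodes, so an atlas with `n_nodes`
#' nodes has `n_nodes * (n_nodes - 1) / 2` edges (e.g. 35778 for a 268-node
#' atlas).
#'
#' @param n_nodes Number of nodes (positive integer, >= 2).
#' @return Integer edge count.
#' @export
#' @examples
#' edge_count(268)  # 35778
edge_count <- function(n_nodes) {
  stopifnot(length(n_nodes) == 1L, n_nodes >= 2, n_nodes == round(n_nodes))
  as.integer(n_nodes * (n_nodes - 1) / 2)
}

#' Node pairs for each edge index
#'
#' Returns the node pair (i, j), i < j, corresponding to every position of the
#' canonical edge vector. The ordering is the strict upper triangle traversed
#' row by row: (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n).
#'
#' @param n_nodes Number of nodes.
#' @return Integer matrix with columns `node_a`, `node_b` and one row per edge.
#' @export
edge_nodes <- function(n_nodes) {
  n_nodes <- as.integer(n_nodes)
  idx <- which(lower.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  # lower-triangle positions of the transpose, column-major == row-major upper
  out <- cbind(node_a = idx[, 2L], node_b = idx[, 1L])
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

#' Vectorize a symmetric connectivity matrix
#'
#' Extracts the strict upper triangle of a symmetric matrix in row-major order
#' (the package's fixed edge-vector convention); the diagonal is discarded.
#'
#' @param m Square numeric matrix, symmetric within `tol`.
#' @param tol Maximum permitted absolute asymmetry (default `1e-8`).
#' @return Numeric vector of length `n * (n - 1) / 2`.
#' @seealso [restore_matrix()] for the inverse.
#' @export
#' @examples
#' m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
#' vectorize_edges(m)  # 1 2 3
vectorize_edges <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || nrow(m) < 2L)
    stop("`m` must be a square matrix with at least 2 nodes")
  asym <- max(abs(m - t(m)))
  if (asym > tol)
    stop(sprintf("matrix is not symmetric: max |m - t(m)| = %.3g exceeds tol %.3g",
                 asym, tol))
  tm <- t(m)
  tm[lower.tri(tm)]
}

#' Restore a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_edges()] up to the discarded diagonal, which is set
#' to zero.
#'
#' @param edges Numeric edge vector in the canonical ordering.
#' @param n_nodes Number of nodes the vector corresponds to.
#' @return Symmetric `n_nodes` x `n_nodes` matrix with zero diagonal.
#' @export
restore_matrix <- function(edges, n_nodes) {
  n_nodes <- as.integer(n_nodes)
  expected <- edge_count(n_nodes)
  if (length(edges) != expected)
    stop(sprintf("edge vector of length %d does not match n_nodes = %d (expected %d)",
                 length(edges), n_nodes, expected))
  lower <- matrix(0, n_nodes, n_nodes)
  lower[lower.tri(lower)] <- edges
  t(lower) + lower
}
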
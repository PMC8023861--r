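# Node, task, and network contributions of a fitted predictive model;
# comparison with MMA maps; hypergeometric network-overlap testing.

#' Node contribution of a predictive model
#'
#' For node n, sums `B(k, m) * beta_m^k * std(E_k(:, m))` over its incident
#' edges k and tasks m: the ridge weight of each selected feature scaled
#' back by the training standard deviation of that edge, credited to both
#' endpoint nodes. Contributions are signed by default (positive and
#' negative predictive edges can cancel); set `magnitude = TRUE` to sum
#' absolute contributions for display.
#'
#' @param model A fitted [rcpm()] model.
#' @param magnitude Sum `|beta| * std` instead of the signed product.
#' @return Numeric vector of length `n_nodes`.
#' @export
node_contribution <- function(model, magnitude = FALSE) {
  stopifnot(inherits(model, "rcpm"))
  w <- rep(0, model$n_nodes)
  if (model$empty || !nrow(model$features)) return(w)
  contrib <- model$features$beta * model$features$scale
  if (magnitude) contrib <- abs(contrib)
  pairs <- edge_nodes(model$n_nodes)[model$features$edge, , drop = FALSE]
  for (i in seq_along(contrib)) {
    w[pairs[i, 1L]] <- w[pairs[i, 1L]] + contrib[i]
    w[pairs[i, 2L]] <- w[pairs[i, 2L]] + contrib[i]
  }
  w
}

#' Task contribution proportions of a predictive model
#'
#' Sums each task's selected-feature weights scaled by the training feature
#' standard deviations, then normalizes the task totals to sum to one so
#' each value is the task's contribution proportion in the whole model.
#' Magnitudes `|beta| * std` are used by default so proportions are
#' non-negative; `signed = TRUE` gives the raw signed totals (normalized by
#' their sum) instead.
#'
#' @param model A fitted [rcpm()] model with at least one selected edge.
#' @param signed Use signed contributions instead of magnitudes.
#' @return Named numeric vector over tasks summing to 1.
#' @export
task_contribution <- function(model, signed = FALSE) {
  stopifnot(inherits(model, "rcpm"))
  if (model$empty || !nrow(model$features))
    stop("empty model: no selected edges")
  contrib <- model$features$beta * model$features$scale
  if (!signed) contrib <- abs(contrib)
  w <- vapply(seq_along(model$task_names), function(t)
    sum(contrib[model$features$task == t]), numeric(1))
  names(w) <- model$task_names
  w / sum(w)
}

#' Average node contribution per canonical network
#'
#' @param w_n Numeric node-contribution vector (e.g. [node_contribution()]
#'   or an MMA node score).
#' @param netmap A [network_map()] of the same length.
#' @return Named numeric vector: arithmetic mean of `w_n` over the member
#'   nodes of each network.
#' @export
network_average <- function(w_n, netmap) {
  stopifnot(inherits(netmap, "network_map"))
  if (length(w_n) != length(netmap))
    stop("w_n length does not match network map")
  counts <- table(netmap)
  empty <- levels(netmap)[counts == 0]
  if (length(empty))
    stop("empty network(s): ", paste(empty, collapse = ", "))
  vapply(levels(netmap), function(l) mean(w_n[netmap == l]), numeric(1))
}

#' Pearson similarity of two contribution profiles
#'
#' Compares node- or network-level contribution vectors (e.g. a predictive
#' model's node weights against an MMA F map) by Pearson correlation with a
#' two-sided p-value.
#'
#' @param a,b Numeric vectors of equal length >= 3, neither constant.
#' @return List with `r` and `p`.
#' @export
profile_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 3) stop("at least 3 values are required")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("constant vector")
  ct <- stats::cor.test(a, b)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Hypergeometric edge-overlap test
#'
#' Probability of observing more than `x` shared edges between an edge set
#' of size `n` and one of size `K` drawn from a population of `M` edges:
#' `p = P(X > x)` with `X ~ Hypergeometric(M, K, n)` (the upper tail of the
#' hypergeometric cdf, evaluated stably on the log-gamma scale).
#'
#' @param x Observed overlapping edge count.
#' @param n Edges in the first set.
#' @param K Edges in the second set.
#' @param M Population edge count (35778 for a 268-node atlas).
#' @return Upper-tail probability.
#' @export
hypergeometric_overlap <- function(x, n, K, M = 35778) {
  if (any(c(x, n, K, M) < 0)) stop("counts must be non-negative")
  if (n > M || K > M) stop("set sizes exceed the population")
  if (x > min(n, K))
    stop(sprintf("overlap x = %d exceeds min(n, K) = %d", x, min(n, K)))
  stats::phyper(x, K, M - K, n, lower.tail = FALSE)
}

#' Network-pair enrichment profile of an edge set
#'
#' Classifies every population edge by the network pair of its endpoints
#' (10 within-network and 45 between-network cells for the canonical
#' 10-network partition) and tests, per cell, whether the given edge set
#' overlaps that cell more than chance via [hypergeometric_overlap()]. The
#' `likelihood` column (1 - p) is a reporting convenience for stacked
#' profiles, not an inferential quantity.
#'
#' @param mask Logical edge mask over the canonical edge vector.
#' @param netmap A [network_map()] with one label per node.
#' @return Data frame with one row per network pair: `network_a`,
#'   `network_b`, cell size `K`, set size `n`, overlap `x`, population `M`,
#'   `p`, and `likelihood`.
#' @export
edge_set_network_profile <- function(mask, netmap) {
  stopifnot(inherits(netmap, "network_map"))
  n_nodes <- length(netmap)
  n_edges <- edge_count(n_nodes)
  if (length(mask) != n_edges)
    stop("mask length does not match the network map's edge count")
  pairs <- edge_nodes(n_nodes)
  a <- pmin(as.integer(netmap[pairs[, 1L]]), as.integer(netmap[pairs[, 2L]]))
  b <- pmax(as.integer(netmap[pairs[, 1L]]), as.integer(netmap[pairs[, 2L]]))
  cell <- (a - 1L) * nlevels(netmap) + b
  n_set <- sum(mask)
  nets <- levels(netmap)
  rows <- list()
  for (i in seq_along(nets)) {
    for (j in i:length(nets)) {
      id <- (i - 1L) * nlevels(netmap) + j
      in_cell <- cell == id
      K <- sum(in_cell)
      x <- sum(mask & in_cell)
      rows[[length(rows) + 1L]] <- data.frame(
        network_a = nets[i], network_b = nets[j], K = K, n = n_set, x = x,
        M = n_edges,
        p = if (K > 0 || x == 0) hypergeometric_overlap(x, n_set, K, n_edges)
            else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  out$likelihood <- 1 - out$p
  out
}
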
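# Edgewise mass-multivariate analysis of diagnostic group: per edge, the
# vector of connectivity values across task connectomes is the multivariate
# response and diagnostic group the factor. Implemented directly from the
# SSCP decomposition (looping stats::manova over ~35k edges would be far too
# slow); stats::manova is the independent oracle in the test suite.

# Wilks' Lambda -> Rao's F approximation
wilks_to_f <- function(lambda_stat, p, q, n, g) {
  ve <- n - g
  t_exp <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  w <- ve + q - (p + q + 1) / 2
  df1 <- p * q
  df2 <- w * t_exp - (p * q - 2) / 2
  lam_t <- lambda_stat^(1 / t_exp)
  f <- (1 - lam_t) / lam_t * df2 / df1
  list(f = f, df1 = df1, df2 = df2)
}

# Pillai trace -> F approximation
pillai_to_f <- function(v, p, q, n, g) {
  s <- min(p, q)
  m <- (abs(p - q) - 1) / 2
  nn <- (n - g - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  f <- (df2 / df1) * v / (s - v)
  list(f = f, df1 = df1, df2 = df2)
}

#' Edgewise MANOVA of diagnostic group
#'
#' For each edge, tests the group factor against the multivariate response
#' formed by that edge's connectivity strength in every task connectome.
#' The omnibus statistic is Wilks' Lambda with Rao's F approximation by
#' default (Pillai's trace available).
#'
#' @param connectomes A [task_connectome_set()].
#' @param groups Group label per subject (factor/character, >= 2 levels);
#'   each group needs at least `n_tasks + 2` subjects and the total
#'   `n >= n_groups + n_tasks + 2`.
#' @param statistic `"wilks"` (default) or `"pillai"`.
#' @return An object of class `mma_result`: per-edge `F`, `p`, approximation
#'   dfs, the statistic name, and a logical `flagged` marking edges with a
#'   singular total covariance (reported with `p = 1`).
#' @seealso [fdr_correct()], [pairwise_contrast()], [mma_summaries()]
#' @export
edgewise_manova <- function(connectomes, groups,
                            statistic = c("wilks", "pillai")) {
  stopifnot(inherits(connectomes, "task_connectome_set"))
  statistic <- match.arg(statistic)
  groups <- droplevels(as.factor(groups))
  n <- length(connectomes$subject_ids)
  if (length(groups) != n) stop("groups length does not match subjects")
  g <- nlevels(groups)
  m <- length(connectomes$task_names)
  if (g < 2) stop("at least 2 groups are required")
  sizes <- tabulate(groups)
  if (n < g + m + 2) stop("too few subjects for the multivariate test")
  if (any(sizes < m + 2))
    stop("each group needs at least n_tasks + 2 subjects")
  n_edges <- dim(connectomes$edges)[3L]
  gidx <- split(seq_len(n), groups)

  fvals <- pvals <- rep(NA_real_, n_edges)
  flagged <- rep(FALSE, n_edges)
  q <- g - 1
  for (k in seq_len(n_edges)) {
    Y <- connectomes$edges[, , k]          # n x m response
    if (!is.matrix(Y)) Y <- matrix(Y, ncol = m)
    Yc <- sweep(Y, 2L, colMeans(Y))
    Tm <- crossprod(Yc)
    W <- matrix(0, m, m)
    for (gi in gidx) {
      Yg <- Y[gi, , drop = FALSE]
      Ygc <- sweep(Yg, 2L, colMeans(Yg))
      W <- W + crossprod(Ygc)
    }
    dT <- det(Tm)
    dW <- det(W)
    if (!is.finite(dT) || dT <= 0 || !is.finite(dW) || dW <= 0) {
      flagged[k] <- TRUE
      pvals[k] <- 1
      next
    }
    if (statistic == "wilks") {
      lam <- dW / dT
      ap <- wilks_to_f(min(max(lam, .Machine$double.xmin), 1), m, q, n, g)
    } else {
      B <- Tm - W
      v <- sum(diag(B %*% solve(Tm)))
      ap <- pillai_to_f(min(v, min(m, q) - 1e-12), m, q, n, g)
    }
    fvals[k] <- ap$f
    pvals[k] <- stats::pf(ap$f, ap$df1, ap$df2, lower.tail = FALSE)
  }
  ap0 <- if (statistic == "wilks") wilks_to_f(0.5, m, q, n, g) else
    pillai_to_f(0.5, m, q, n, g)
  structure(
    list(F = fvals, p = pvals, flagged = flagged, statistic = statistic,
         df1 = ap0$df1, df2 = ap0$df2, n = n, groups = levels(groups),
         n_tasks = m, n_nodes = connectomes$n_nodes),
    class = "mma_result")
}

#' @export
print.mma_result <- function(x, ...) {
  cat(sprintf("mma_result (%s): %d edges, %d groups, %d tasks; %d flagged\n",
              x$statistic, length(x$F), length(x$groups), x$n_tasks,
              sum(x$flagged)))
  invisible(x)
}

#' Benjamini-Hochberg FDR significance mask
#'
#' Step-up false-discovery-rate control over all tested edges.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Logical mask of rejections (empty input gives an empty mask).
#' @export
fdr_correct <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(logical(0))
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Pairwise group contrast by Hotelling's T-squared
#'
#' Two-sample Hotelling T-squared per edge on the task-vector response, with
#' the exact F transform for p-values.
#'
#' @param connectomes A [task_connectome_set()].
#' @param groups Group label per subject.
#' @param pair Character vector of the two group levels to contrast; both
#'   need at least `n_tasks + 2` subjects.
#' @return List of class `hotelling_contrast` with per-edge `T2`, `F`, `p`,
#'   `flagged`, and the contrasted pair.
#' @export
pairwise_contrast <- function(connectomes, groups, pair) {
  stopifnot(inherits(connectomes, "task_connectome_set"), length(pair) == 2)
  groups <- as.factor(groups)
  if (!all(pair %in% levels(groups))) stop("unknown group in pair")
  i1 <- which(groups == pair[1L])
  i2 <- which(groups == pair[2L])
  m <- length(connectomes$task_names)
  n1 <- length(i1); n2 <- length(i2)
  if (min(n1, n2) < m + 2)
    stop("both groups need at least n_tasks + 2 subjects")
  n_edges <- dim(connectomes$edges)[3L]
  t2 <- fvals <- pvals <- rep(NA_real_, n_edges)
  flagged <- rep(FALSE, n_edges)
  fscale <- (n1 + n2 - m - 1) / (m * (n1 + n2 - 2))
  for (k in seq_len(n_edges)) {
    Y1 <- connectomes$edges[i1, , k, drop = FALSE][, , 1L]
    Y2 <- connectomes$edges[i2, , k, drop = FALSE][, , 1L]
    if (m == 1L) { Y1 <- matrix(Y1, ncol = 1L); Y2 <- matrix(Y2, ncol = 1L) }
    d <- colMeans(Y1) - colMeans(Y2)
    S <- (crossprod(sweep(Y1, 2L, colMeans(Y1))) +
            crossprod(sweep(Y2, 2L, colMeans(Y2)))) / (n1 + n2 - 2)
    Sd <- tryCatch(solve(S, d), error = function(e) NULL)
    if (is.null(Sd)) {
      flagged[k] <- TRUE
      pvals[k] <- 1
      next
    }
    t2[k] <- (n1 * n2 / (n1 + n2)) * sum(d * Sd)
    fvals[k] <- fscale * t2[k]
    pvals[k] <- stats::pf(fvals[k], m, n1 + n2 - m - 1, lower.tail = FALSE)
  }
  structure(list(T2 = t2, F = fvals, p = pvals, flagged = flagged,
                 pair = pair, n = c(n1, n2), n_tasks = m,
                 n_nodes = connectomes$n_nodes),
            class = "hotelling_contrast")
}

#' Node and network summaries of significant edges
#'
#' Node score: sum of the omnibus F statistic over each node's significant
#' incident edges. Network scores: sums over significant edges grouped by
#' the network pair of their endpoints, with within-network (diagonal) and
#' between-network cells reported separately.
#'
#' @param result An `mma_result` from [edgewise_manova()].
#' @param mask Logical significance mask over edges (e.g. from
#'   [fdr_correct()] on `result$p`).
#' @param netmap A [network_map()] with one label per node.
#' @return List with `node_scores` (per node) and `network_scores`
#'   (symmetric network x network matrix of summed F).
#' @export
mma_summaries <- function(result, mask, netmap) {
  stopifnot(inherits(result, "mma_result"), inherits(netmap, "network_map"))
  n_nodes <- result$n_nodes
  if (length(netmap) != n_nodes)
    stop("network map length does not match node count")
  if (length(mask) != length(result$F)) stop("mask length mismatch")
  pairs <- edge_nodes(n_nodes)
  sig <- which(mask & !is.na(result$F))
  node_scores <- rep(0, n_nodes)
  nets <- levels(netmap)
  network_scores <- matrix(0, length(nets), length(nets),
                           dimnames = list(nets, nets))
  for (k in sig) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    node_scores[i] <- node_scores[i] + result$F[k]
    node_scores[j] <- node_scores[j] + result$F[k]
    a <- as.integer(netmap[i]); b <- as.integer(netmap[j])
    network_scores[a, b] <- network_scores[a, b] + result$F[k]
    if (a != b) network_scores[b, a] <- network_scores[b, a] + result$F[k]
  }
  list(node_scores = node_scores, network_scores = network_scores)
}
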
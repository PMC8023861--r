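# Predictive core: correlation-based edge selection (optionally partial
# correlation controlling for motion), then one ridge regression pooling the
# selected edges from all tasks. Selection and fitting only ever see training
# subjects; test subjects are scored through predict() with the stored
# training statistics.

# correlation of each column of E with y, plus two-sided p from the t
# transform t = r sqrt(df / (1 - r^2)). When motion is supplied, the partial
# correlation given motion is computed (identical to correlating the
# motion-residualized edge and phenotype) and df = n - 3.
edge_phenotype_cor <- function(E, y, motion = NULL) {
  n <- length(y)
  # column sds via sufficient statistics; one GEMM for all cross-products
  cs <- colSums(E)
  se <- sqrt(pmax(colSums(E * E) - cs^2 / n, 0))
  if (!is.null(motion) && stats::sd(motion) > 0) {
    yc <- y - mean(y); mc <- motion - mean(motion)
    cross <- crossprod(E, cbind(yc, mc))
    r_ey <- cross[, 1L] / (se * sqrt(sum(yc^2)))
    r_em <- pmin(pmax(cross[, 2L] / (se * sqrt(sum(mc^2))), -1), 1)
    r_ym <- stats::cor(y, motion)
    r <- (r_ey - r_em * r_ym) / sqrt((1 - r_em^2) * (1 - r_ym^2))
    df <- n - 3L
  } else {
    yc <- y - mean(y)
    r <- as.vector(crossprod(E, yc)) / (se * sqrt(sum(yc^2)))
    df <- n - 2L
  }
  r[!is.finite(r)] <- 0  # zero-variance or motion-degenerate edges: never selected
  r <- pmin(pmax(r, -1), 1)
  tt <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(tt, df = df, lower.tail = FALSE)
  p[abs(r) == 1] <- 0
  list(r = r, p = p)
}

#' Select edges correlated with a phenotype
#'
#' For each task and edge, computes the Pearson correlation between edge
#' strength and the phenotype across training subjects (partial correlation
#' given motion when `motion` is supplied, correlating the residuals after
#' regressing each side on motion, with df = n - 3). Edges with two-sided
#' p < `alpha` are selected; positively and negatively correlated edges are
#' pooled into one mask.
#'
#' @param connectomes A [task_connectome_set()] restricted to training
#'   subjects (>= 10).
#' @param phenotype Numeric phenotype score per training subject.
#' @param motion Optional motion summary (mm) per training subject.
#' @param alpha Two-sided selection threshold (default 0.01).
#' @return An object of class `edge_selection`: logical `mask` (edge x task),
#'   plus matching `r` and `p` matrices, `alpha`, and `n_train`.
#' @export
select_edges <- function(connectomes, phenotype, motion = NULL, alpha = 0.01) {
  stopifnot(inherits(connectomes, "task_connectome_set"))
  n <- length(connectomes$subject_ids)
  if (length(phenotype) != n) stop("phenotype length does not match subjects")
  if (n < 10) stop("at least 10 training subjects are required")
  if (!all(is.finite(phenotype))) stop("phenotype must be finite")
  if (!is.null(motion) && length(motion) != n)
    stop("motion length does not match subjects")
  n_tasks <- length(connectomes$task_names)
  n_edges <- dim(connectomes$edges)[3L]
  mask <- matrix(FALSE, n_edges, n_tasks,
                 dimnames = list(NULL, connectomes$task_names))
  rmat <- pmat <- matrix(NA_real_, n_edges, n_tasks,
                         dimnames = list(NULL, connectomes$task_names))
  for (t in seq_len(n_tasks)) {
    res <- edge_phenotype_cor(task_edges(connectomes, t), phenotype, motion)
    rmat[, t] <- res$r
    pmat[, t] <- res$p
    mask[, t] <- res$p < alpha
  }
  structure(list(mask = mask, r = rmat, p = pmat, alpha = alpha, n_train = n),
            class = "edge_selection")
}

#' @export
print.edge_selection <- function(x, ...) {
  cat(sprintf("edge_selection: alpha = %g, n_train = %d\n", x$alpha, x$n_train))
  print(colSums(x$mask))
  invisible(x)
}

# ridge solve on standardized features: min ||yc - X b||^2 + lambda ||b||^2.
# Uses the kernel form when p > n.
ridge_solve <- function(X, yc, lambda) {
  n <- nrow(X); p <- ncol(X)
  if (p <= n) {
    as.vector(solve(crossprod(X) + diag(lambda, p), crossprod(X, yc)))
  } else {
    a <- solve(tcrossprod(X) + diag(lambda, n), yc)
    as.vector(crossprod(X, a))
  }
}

# inner k-fold CV over a lambda grid, minimizing mean squared error
choose_lambda <- function(X, yc, lambda_grid, n_folds = 5L) {
  n <- nrow(X)
  n_folds <- min(n_folds, n)
  folds <- sample(rep_len(seq_len(n_folds), n))
  mse <- matrix(NA_real_, n_folds, length(lambda_grid))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    Xt <- X[tr, , drop = FALSE]; yt <- yc[tr]
    Xv <- X[!tr, , drop = FALSE]; yv <- yc[!tr]
    # eigendecompose the kernel once, sweep the grid cheaply
    G <- tcrossprod(Xt)
    eg <- eigen(G, symmetric = TRUE)
    Kv <- Xv %*% t(Xt)
    uy <- crossprod(eg$vectors, yt)
    Ku <- Kv %*% eg$vectors
    for (l in seq_along(lambda_grid)) {
      pred <- Ku %*% (uy / (eg$values + lambda_grid[l]))
      mse[f, l] <- mean((yv - pred)^2)
    }
  }
  lambda_grid[which.min(colMeans(mse))]
}

#' Fit a ridge connectome-based predictive model
#'
#' The central fitting function. Selects edges per task by (partial)
#' correlation with the phenotype (unless a precomputed `selection` is
#' given), z-scores the selected features by their training statistics, and
#' fits a single ridge regression over the pooled feature set from all
#' tasks, with an unpenalized intercept. The penalty is chosen by inner
#' k-fold cross-validation over a log-spaced grid unless `lambda` is fixed.
#'
#' @param connectomes A [task_connectome_set()] of training subjects.
#' @param phenotype Numeric phenotype per training subject.
#' @param motion Optional motion summary per training subject, used for
#'   partial-correlation edge selection.
#' @param alpha Selection threshold (two-sided p; default 0.01).
#' @param selection Optional precomputed [select_edges()] result.
#' @param lambda Fixed ridge penalty; `NULL` (default) selects it by inner
#'   cross-validation.
#' @param lambda_grid Penalty grid for the inner CV (default 13 log-spaced
#'   points over 1e-3..1e3).
#' @param n_inner_folds Inner CV fold count (default 5).
#' @return An object of class `rcpm`: feature table (task, edge, training
#'   mean/sd, ridge weight), selection mask, penalty, intercept, and
#'   training metadata. If no edge is selected the model is returned empty
#'   (`empty = TRUE`) with a warning and predicts the training mean.
#' @seealso [predict.rcpm()], [coef.rcpm()], [node_contribution()],
#'   [task_contribution()]
#' @export
rcpm <- function(connectomes, phenotype, motion = NULL, alpha = 0.01,
                 selection = NULL,
                 lambda = NULL, lambda_grid = 10^seq(-3, 3, length.out = 13),
                 n_inner_folds = 5L) {
  stopifnot(inherits(connectomes, "task_connectome_set"))
  n <- length(connectomes$subject_ids)
  if (length(phenotype) != n) stop("phenotype length does not match subjects")
  if (is.null(selection))
    selection <- select_edges(connectomes, phenotype, motion, alpha)
  mask <- selection$mask
  n_tasks <- length(connectomes$task_names)
  n_edges <- dim(connectomes$edges)[3L]
  stopifnot(nrow(mask) == n_edges, ncol(mask) == n_tasks)

  feat_task <- rep(seq_len(n_tasks), times = colSums(mask))
  feat_edge <- unlist(lapply(seq_len(n_tasks), function(t) which(mask[, t])),
                      use.names = FALSE)
  if (!length(feat_edge)) {
    warning("no edges selected; returning an empty model that predicts the training mean")
    return(structure(
      list(empty = TRUE, mask = mask, selection = selection,
           features = data.frame(task = integer(0), edge = integer(0),
                                 center = numeric(0), scale = numeric(0),
                                 beta = numeric(0)),
           lambda = NA_real_, intercept = mean(phenotype), alpha = selection$alpha,
           n_train = n, task_names = connectomes$task_names,
           n_nodes = connectomes$n_nodes, n_edges = n_edges),
      class = "rcpm"))
  }

  X <- matrix(NA_real_, n, length(feat_edge))
  for (t in unique(feat_task)) {
    cols <- which(feat_task == t)
    X[, cols] <- connectomes$edges[, t, feat_edge[cols]]
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1  # cannot occur for selected edges; guard anyway
  X <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  yc <- phenotype - mean(phenotype)
  if (is.null(lambda))
    lambda <- choose_lambda(X, yc, lambda_grid, n_inner_folds)
  beta <- ridge_solve(X, yc, lambda)

  structure(
    list(empty = FALSE, mask = mask, selection = selection,
         features = data.frame(task = feat_task, edge = feat_edge,
                               center = ctr, scale = scl, beta = beta),
         lambda = lambda, intercept = mean(phenotype), alpha = selection$alpha,
         n_train = n, task_names = connectomes$task_names,
         n_nodes = connectomes$n_nodes, n_edges = n_edges),
    class = "rcpm")
}

#' Predict phenotype scores for new subjects
#'
#' Applies the training feature scalings and ridge weights to held-out
#' connectomes. The test phenotype is never touched.
#'
#' @param object A fitted [rcpm()] model.
#' @param newdata A [task_connectome_set()] with the same tasks and edge
#'   dimension as the training set.
#' @param ... Ignored.
#' @return Numeric predicted score per subject.
#' @export
predict.rcpm <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "task_connectome_set"))
  if (!identical(newdata$task_names, object$task_names))
    stop("task mismatch between model and new data")
  if (dim(newdata$edges)[3L] != object$n_edges)
    stop("edge-dimension mismatch between model and new data")
  n <- length(newdata$subject_ids)
  if (object$empty) return(rep(object$intercept, n))
  ft <- object$features
  X <- matrix(NA_real_, n, nrow(ft))
  for (t in unique(ft$task)) {
    cols <- which(ft$task == t)
    X[, cols] <- newdata$edges[, t, ft$edge[cols]]
  }
  X <- sweep(sweep(X, 2L, ft$center), 2L, ft$scale, "/")
  drop(X %*% ft$beta) + object$intercept
}

#' @export
coef.rcpm <- function(object, ...) {
  stats::setNames(object$features$beta,
                  sprintf("%s:e%d", object$task_names[object$features$task],
                          object$features$edge))
}

#' @export
print.rcpm <- function(x, ...) {
  if (x$empty) {
    cat("rcpm model (empty: no edges selected); predicts training mean",
        format(x$intercept), "\n")
    return(invisible(x))
  }
  cat(sprintf("rcpm model: %d selected features over %d tasks, lambda = %g, n_train = %d\n",
              nrow(x$features), length(x$task_names), x$lambda, x$n_train))
  invisible(x)
}

#' @export
summary.rcpm <- function(object, ...) {
  per_task <- table(factor(object$task_names[object$features$task],
                           levels = object$task_names))
  out <- list(n_features = nrow(object$features), per_task = per_task,
              lambda = object$lambda, alpha = object$alpha,
              n_train = object$n_train, intercept = object$intercept,
              empty = object$empty)
  class(out) <- "summary.rcpm"
  out
}

#' @export
print.summary.rcpm <- function(x, ...) {
  cat(sprintf("rcpm model: %d features (alpha = %g, lambda = %s, n_train = %d)\n",
              x$n_features, x$alpha, format(x$lambda), x$n_train))
  print(x$per_task)
  invisible(x)
}
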
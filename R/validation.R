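# Cross-validation harnesses, performance metrics, permutation nulls, and
# selection-consistency summaries.

# one-tailed permutation p: (#{null > observed} + 1) / (n_perm + 1)
perm_pvalue <- function(null, observed) {
  (sum(null > observed) + 1) / (length(null) + 1)
}

#' Cross-validated R-squared
#'
#' `q^2 = 1 - sum((y_i - yhat_i)^2) / sum((y_i - ybar)^2)` over pooled
#' out-of-fold predictions, with `ybar` the mean of the actual values. Less
#' biased than the Pearson correlation between actual and predicted under
#' cross-validation, and can be negative when out-of-sample residuals exceed
#' the outcome variance. The square root is reported when `q^2 >= 0` and
#' flagged undefined (`NA`) otherwise rather than clamped.
#'
#' @param actual Numeric vector of observed values (length >= 3,
#'   non-constant).
#' @param predicted Numeric vector of predictions, same length.
#' @return List with `q2` and `root` (`sqrt(q2)` or `NA` when `q2 < 0`).
#' @export
r2_cv <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  if (length(actual) < 3) stop("at least 3 observations are required")
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) stop("actual values are constant (zero denominator)")
  q2 <- 1 - sum((actual - predicted)^2) / ss_tot
  list(q2 = q2, root = if (q2 >= 0) sqrt(q2) else NA_real_)
}

# One train/test fold of the full pipeline: train-fold PCA of the measures,
# (partial-)correlation edge selection, pooled ridge fit, test-fold scoring.
# Operates on a per-task list of edge matrices for speed; equivalence with
# the public fit_latent / select_edges / rcpm / predict path is asserted in
# the test suite.
rcpm_fold <- function(Elist, measures, motion, train, test, alpha,
                      lambda, lambda_grid, n_inner_folds) {
  lat <- fit_latent(measures[train, , drop = FALSE])
  y_tr <- apply_latent(lat, measures[train, , drop = FALSE])
  y_te <- apply_latent(lat, measures[test, , drop = FALSE])
  n_tasks <- length(Elist)
  n_edges <- ncol(Elist[[1L]])
  mo <- if (!is.null(motion)) motion[train]
  mask <- matrix(FALSE, n_edges, n_tasks)
  Etr <- lapply(Elist, function(E) E[train, , drop = FALSE])
  for (t in seq_len(n_tasks))
    mask[, t] <- edge_phenotype_cor(Etr[[t]], y_tr, mo)$p < alpha
  y_te <- unname(y_te)
  if (!any(mask))
    return(list(actual = y_te, pred = rep(mean(y_tr), length(y_te)),
                mask = mask, failed = TRUE))
  Xtr <- do.call(cbind, lapply(seq_len(n_tasks), function(t)
    Etr[[t]][, mask[, t], drop = FALSE]))
  Xte <- do.call(cbind, lapply(seq_len(n_tasks), function(t)
    Elist[[t]][test, mask[, t], drop = FALSE]))
  n_tr <- nrow(Xtr)
  ctr <- colMeans(Xtr)
  scl <- sqrt(pmax(colMeans(Xtr^2) - ctr^2, 0) * n_tr / (n_tr - 1))
  scl[scl == 0] <- 1
  Xtr <- sweep(sweep(Xtr, 2L, ctr), 2L, scl, "/")
  Xte <- sweep(sweep(Xte, 2L, ctr), 2L, scl, "/")
  yc <- y_tr - mean(y_tr)
  if (is.null(lambda))
    lambda <- choose_lambda(Xtr, yc, lambda_grid, n_inner_folds)
  beta <- ridge_solve(Xtr, yc, lambda)
  list(actual = y_te, pred = unname(drop(Xte %*% beta)) + mean(y_tr),
       mask = mask, failed = FALSE, lambda = lambda)
}

# extract per-task edge matrices once
edge_matrix_list <- function(connectomes) {
  lapply(seq_along(connectomes$task_names), function(t)
    task_edges(connectomes, t))
}

resolve_motion <- function(phenotypes, use_motion) {
  if (use_motion && !is.null(phenotypes$motion_grand_mean))
    phenotypes$motion_grand_mean
  else NULL
}

resolve_measures <- function(phenotypes, measures) {
  if (is.null(phenotypes$measures)) stop("phenotype table has no measures")
  if (is.null(measures)) return(phenotypes$measures)
  miss <- setdiff(measures, colnames(phenotypes$measures))
  if (length(miss)) stop("unknown measures: ", paste(miss, collapse = ", "))
  phenotypes$measures[, measures, drop = FALSE]
}

#' K-fold cross-validated rCPM
#'
#' For each of `iterations` random divisions of the whole sample
#' (irrespective of diagnostic group) into `k` approximately equal folds,
#' trains the full pipeline on k-1 folds (train-restricted PCA of the
#' chosen measures, edge selection with optional partial-correlation motion
#' control, pooled ridge fit) and scores the held-out fold. Predictions are
#' pooled across folds to give one `q^2` per iteration; the median over
#' iterations is the headline statistic.
#'
#' @param connectomes A [task_connectome_set()].
#' @param phenotypes A [phenotype_table()] aligned with `connectomes`.
#' @param measures Character vector of measure columns defining the
#'   construct (default: all measures).
#' @param k Fold count (default 10); requires `n >= 2k`.
#' @param iterations Number of random divisions (study default 1000;
#'   desk-scale analyses use 50).
#' @param alpha Edge-selection threshold.
#' @param use_motion Control for grand-mean motion via partial correlation
#'   during selection (default TRUE when motion is available).
#' @param lambda Fixed ridge penalty, or `NULL` for inner-CV choice.
#' @param lambda_grid,n_inner_folds Inner cross-validation settings.
#' @param seed Integer seed; fixes folds and all downstream randomness.
#' @return An object of class `cv_rcpm`: per-iteration `q2` and `root`,
#'   their medians, pooled actual/predicted matrices (subject x iteration),
#'   per-iteration edge-selection union `masks` (iteration x edge, any
#'   task), fold assignments, and a failed-fold report.
#' @export
kfold_cv <- function(connectomes, phenotypes, measures = NULL, k = 10L,
                     iterations = 100L, alpha = 0.01, use_motion = TRUE,
                     lambda = NULL, lambda_grid = 10^seq(-3, 3, length.out = 13),
                     n_inner_folds = 5L, seed = NULL) {
  stopifnot(inherits(connectomes, "task_connectome_set"))
  check_paired(connectomes, phenotypes)
  n <- length(connectomes$subject_ids)
  if (k > n) stop("k exceeds the number of subjects")
  if (n < 2 * k) stop("need at least 2k subjects")
  if (!is.null(seed)) set.seed(seed)
  meas <- resolve_measures(phenotypes, measures)
  motion <- resolve_motion(phenotypes, use_motion)
  Elist <- edge_matrix_list(connectomes)
  n_edges <- ncol(Elist[[1L]])

  q2 <- root <- numeric(iterations)
  actual <- predicted <- matrix(NA_real_, n, iterations,
                                dimnames = list(connectomes$subject_ids, NULL))
  masks <- matrix(FALSE, iterations, n_edges)
  fold_assign <- matrix(NA_integer_, n, iterations)
  failed <- list()
  for (it in seq_len(iterations)) {
    folds <- sample(rep_len(seq_len(k), n))
    fold_assign[, it] <- folds
    union_mask <- rep(FALSE, n_edges)
    for (f in seq_len(k)) {
      test <- which(folds == f)
      train <- which(folds != f)
      res <- rcpm_fold(Elist, meas, motion, train, test, alpha,
                       lambda, lambda_grid, n_inner_folds)
      actual[test, it] <- res$actual
      predicted[test, it] <- res$pred
      union_mask <- union_mask | rowSums(res$mask) > 0
      if (res$failed)
        failed[[length(failed) + 1L]] <- data.frame(iteration = it, fold = f)
    }
    masks[it, ] <- union_mask
    perf <- r2_cv(actual[, it], predicted[, it])
    q2[it] <- perf$q2
    root[it] <- perf$root
  }
  structure(
    list(q2 = q2, root = root,
         median_q2 = stats::median(q2),
         median_root = if (stats::median(q2) >= 0) sqrt(stats::median(q2)) else NA_real_,
         actual = actual, predicted = predicted, masks = masks,
         fold_assignments = fold_assign,
         failed_folds = if (length(failed)) do.call(rbind, failed) else NULL,
         k = k, iterations = iterations, alpha = alpha, seed = seed,
         n_nodes = connectomes$n_nodes),
    class = "cv_rcpm")
}

#' @export
print.cv_rcpm <- function(x, ...) {
  cat(sprintf("cv_rcpm: %d-fold x %d iterations, median q^2 = %.4f (median root = %s)\n",
              x$k, x$iterations, x$median_q2,
              ifelse(is.na(x$median_root), "undefined", sprintf("%.4f", x$median_root))))
  if (!is.null(x$failed_folds))
    cat(sprintf("  %d fold(s) had no selected edges (predicted train mean)\n",
                nrow(x$failed_folds)))
  invisible(x)
}

#' Behavior-shuffle permutation test for prediction performance
#'
#' Randomly shuffles the correspondence between behavioral measures and
#' connectivity matrices `n_perm` times, reruns the cross-validated rCPM
#' analysis on each shuffle, and compares the observed statistic (median
#' per-iteration `q^2`) with the null distribution. The one-tailed p-value
#' is `(#\{null > observed\} + 1) / (n_perm + 1)`.
#'
#' Motion stays with the connectomes (it is an imaging-derived quantity);
#' only the behavioral measures are shuffled.
#'
#' @inheritParams kfold_cv
#' @param n_perm Number of permutations (study default 1000).
#' @param iterations Random k-fold divisions for the observed statistic.
#' @param perm_iterations Divisions per permutation (default 1 for
#'   tractability).
#' @param observed Optional precomputed `cv_rcpm` for the observed run.
#' @return An object of class `permutation_result`: observed statistic,
#'   null vector, `p`, and scheme tag `"behavior"`.
#' @export
permutation_test_behavior <- function(connectomes, phenotypes, measures = NULL,
                                      n_perm = 1000L, iterations = 10L,
                                      perm_iterations = 1L, k = 10L,
                                      alpha = 0.01, use_motion = TRUE,
                                      lambda = NULL,
                                      lambda_grid = 10^seq(-3, 3, length.out = 13),
                                      n_inner_folds = 5L, seed = NULL,
                                      observed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(observed))
    observed <- kfold_cv(connectomes, phenotypes, measures, k, iterations,
                         alpha, use_motion, lambda, lambda_grid, n_inner_folds)
  rho_obs <- stats::median(observed$q2)
  n <- length(connectomes$subject_ids)
  null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    ph <- phenotypes
    ph$measures <- ph$measures[perm, , drop = FALSE]
    rownames(ph$measures) <- phenotypes$subject_ids
    cv <- kfold_cv(connectomes, ph, measures, k, perm_iterations, alpha,
                   use_motion, lambda, lambda_grid, n_inner_folds)
    null[b] <- stats::median(cv$q2)
  }
  p <- perm_pvalue(null, rho_obs)
  structure(list(observed = rho_obs, null = null, p = p,
                 scheme = "behavior", n_perm = n_perm),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result (%s): observed = %.4f, p = %.4g (%d permutations)\n",
              x$scheme, x$observed, x$p, x$n_perm))
  invisible(x)
}

#' Leave-one-group-out validation
#'
#' For each diagnostic group, trains the full pipeline on all other groups
#' and tests on the left-out group. One split per group, no iteration (the
#' possibilities are exhausted). Performance is the Pearson correlation
#' between actual and predicted phenotype in the left-out group.
#'
#' @inheritParams kfold_cv
#' @return An object of class `logo_result`: data frame of `group`, `n`,
#'   `r`, plus per-group actual/predicted vectors.
#' @export
leave_group_out <- function(connectomes, phenotypes, measures = NULL,
                            alpha = 0.01, use_motion = TRUE, lambda = NULL,
                            lambda_grid = 10^seq(-3, 3, length.out = 13),
                            n_inner_folds = 5L, seed = NULL) {
  stopifnot(inherits(connectomes, "task_connectome_set"))
  check_paired(connectomes, phenotypes)
  groups <- phenotypes$group
  lev <- levels(droplevels(groups))
  if (length(lev) < 2) stop("at least 2 groups are required")
  sizes <- table(factor(groups, levels = lev))
  if (any(sizes < 3))
    stop("each group needs at least 3 subjects (",
         paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), ")")
  if (!is.null(seed)) set.seed(seed)
  meas <- resolve_measures(phenotypes, measures)
  motion <- resolve_motion(phenotypes, use_motion)
  Elist <- edge_matrix_list(connectomes)
  out <- data.frame(group = lev, n = as.integer(sizes), r = NA_real_)
  details <- list()
  for (gi in seq_along(lev)) {
    test <- which(groups == lev[gi])
    train <- which(groups != lev[gi])
    res <- rcpm_fold(Elist, meas, motion, train, test, alpha,
                     lambda, lambda_grid, n_inner_folds)
    r <- suppressWarnings(stats::cor(res$actual, res$pred))
    # a constant prediction (e.g. empty model) carries zero association
    out$r[gi] <- if (is.finite(r)) r else 0
    details[[lev[gi]]] <- list(actual = res$actual, pred = res$pred)
  }
  structure(list(performance = out, details = details),
            class = "logo_result")
}

#' @export
print.logo_result <- function(x, ...) {
  cat("leave-one-group-out validation:\n")
  print(x$performance, row.names = FALSE)
  invisible(x)
}

#' Group-membership permutation test for leave-one-group-out models
#'
#' Permutes diagnostic-group membership `n_perm` times, keeping the
#' behavior-connectome correspondence and the group sizes intact, and reruns
#' the leave-one-group-out analysis on each permutation. The observed
#' per-group performance is compared with the 2.5/97.5 percentiles of its
#' null: above the 97.5th percentile means group membership was detracting
#' information, below the 2.5th that it was contributing; otherwise the
#' group label is uninformative. An empirical two-sided permutation p-value
#' per group is corrected across groups by FDR (default q = 0.001), and a
#' group is only classified away from "uninformative" when FDR-significant.
#'
#' @inheritParams leave_group_out
#' @param n_perm Number of group-label permutations (study default 200;
#'   a warning is issued below 40, where the percentiles are unstable).
#' @param fdr_q FDR level for the multiple-group correction.
#' @return An object of class `group_permutation_result`: per-group observed
#'   `r`, null percentile band, permutation p, FDR-adjusted p, and
#'   classification in `{contributes, detracts, uninformative}`.
#' @export
group_permutation_test <- function(connectomes, phenotypes, measures = NULL,
                                   n_perm = 200L, fdr_q = 0.001,
                                   alpha = 0.01, use_motion = TRUE,
                                   lambda = NULL,
                                   lambda_grid = 10^seq(-3, 3, length.out = 13),
                                   n_inner_folds = 5L, seed = NULL) {
  if (n_perm < 40) warning("n_perm < 40: percentile band is unstable")
  if (!is.null(seed)) set.seed(seed)
  observed <- leave_group_out(connectomes, phenotypes, measures, alpha,
                              use_motion, lambda, lambda_grid, n_inner_folds)
  lev <- observed$performance$group
  null <- matrix(NA_real_, n_perm, length(lev), dimnames = list(NULL, lev))
  for (b in seq_len(n_perm)) {
    ph <- phenotypes
    ph$group <- sample(phenotypes$group)  # sizes preserved by relabeling
    res <- leave_group_out(connectomes, ph, measures, alpha, use_motion,
                           lambda, lambda_grid, n_inner_folds)
    null[b, ] <- res$performance$r[match(lev, res$performance$group)]
  }
  lo <- apply(null, 2L, stats::quantile, probs = 0.025)
  hi <- apply(null, 2L, stats::quantile, probs = 0.975)
  obs <- observed$performance$r
  p_up <- (colSums(null >= rep(obs, each = n_perm)) + 1) / (n_perm + 1)
  p_dn <- (colSums(null <= rep(obs, each = n_perm)) + 1) / (n_perm + 1)
  p <- pmin(2 * pmin(p_up, p_dn), 1)
  p_adj <- stats::p.adjust(p, method = "BH")
  classification <- rep("uninformative", length(lev))
  classification[obs > hi & p_adj <= fdr_q] <- "detracts"
  classification[obs < lo & p_adj <= fdr_q] <- "contributes"
  structure(
    list(table = data.frame(group = lev, n = observed$performance$n,
                            r = obs, lower = lo, upper = hi, p = p,
                            p_adj = p_adj,
                            classification = classification),
         null = null, observed = observed, n_perm = n_perm, fdr_q = fdr_q),
    class = "group_permutation_result")
}

#' @export
print.group_permutation_result <- function(x, ...) {
  cat(sprintf("group-membership permutation test (%d permutations):\n", x$n_perm))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Consistently selected edges and their node degree
#'
#' An edge is consistent when it was selected (in any task) in at least
#' `threshold` of the recorded iterations. The per-node degree counts the
#' consistent edges incident to each node, so degrees sum to twice the
#' number of consistent edges.
#'
#' @param masks Logical matrix, iterations x edges (e.g. `$masks` from
#'   [kfold_cv()]); >= 2 iterations.
#' @param n_nodes Number of atlas nodes matching the edge dimension.
#' @param threshold Required selection fraction in (0, 1] (default 0.95).
#' @return List with `consistent` (logical per edge), `degree` (integer per
#'   node), and `n_consistent`.
#' @export
consistency_degree <- function(masks, n_nodes, threshold = 0.95) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  masks <- as.matrix(masks)
  if (nrow(masks) < 2) stop("at least 2 iterations of masks are required")
  if (ncol(masks) != edge_count(n_nodes))
    stop("mask edge dimension does not match n_nodes")
  consistent <- colMeans(masks) >= threshold
  pairs <- edge_nodes(n_nodes)[consistent, , drop = FALSE]
  degree <- tabulate(as.vector(pairs), nbins = n_nodes)
  list(consistent = consistent, degree = degree,
       n_consistent = sum(consistent))
}

#' Cross-dataset external validation
#'
#' Fits a latent "general memory" construct per dataset independently (PCA
#' over all of that dataset's memory measures, all subjects), trains an
#' rCPM on every subject of the training dataset, applies it to the test
#' dataset, and reports the Pearson correlation between actual and
#' predicted scores. Intended for single general-connectivity connectomes
#' (see [general_fc()]) but works for any matching task sets.
#'
#' @param train_connectomes,test_connectomes [task_connectome_set()]s with
#'   identical node counts and task names.
#' @param train_measures,test_measures Numeric measure matrices (subject x
#'   measure) for each dataset; the measure sets may differ.
#' @param alpha,use_motion,lambda,lambda_grid,n_inner_folds,seed As in
#'   [kfold_cv()].
#' @param train_motion,test_motion Optional motion summaries per subject.
#' @return List of class `external_validation`: `r`, `p`, `df`, the fitted
#'   model, and actual/predicted scores for the test dataset.
#' @export
external_validate <- function(train_connectomes, train_measures,
                              test_connectomes, test_measures,
                              train_motion = NULL, test_motion = NULL,
                              alpha = 0.01, lambda = NULL,
                              lambda_grid = 10^seq(-3, 3, length.out = 13),
                              n_inner_folds = 5L, seed = NULL) {
  stopifnot(inherits(train_connectomes, "task_connectome_set"),
            inherits(test_connectomes, "task_connectome_set"))
  if (train_connectomes$n_nodes != test_connectomes$n_nodes)
    stop("node-count mismatch between datasets")
  if (!is.null(seed)) set.seed(seed)
  lat_train <- fit_latent(as.matrix(train_measures))
  lat_test <- fit_latent(as.matrix(test_measures))
  y_train <- apply_latent(lat_train, as.matrix(train_measures))
  y_test <- apply_latent(lat_test, as.matrix(test_measures))
  model <- rcpm(train_connectomes, y_train, motion = train_motion,
                alpha = alpha, lambda = lambda, lambda_grid = lambda_grid,
                n_inner_folds = n_inner_folds)
  pred <- predict(model, test_connectomes)
  ct <- stats::cor.test(y_test, pred)
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 df = unname(ct$parameter), model = model,
                 actual = y_test, predicted = pred,
                 latent_train = lat_train, latent_test = lat_test),
            class = "external_validation")
}

#' @export
print.external_validation <- function(x, ...) {
  cat(sprintf("external validation: r = %.3f (p = %.3g, df = %d)\n",
              x$r, x$p, x$df))
  invisible(x)
}
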
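set_from_tasks <- function(task_list, n_nodes) {
  # task_list: list of subject x edge matrices
  n <- nrow(task_list[[1]])
  edges <- array(NA_real_, c(n, length(task_list), ncol(task_list[[1]])))
  for (t in seq_along(task_list)) edges[, t, ] <- task_list[[t]]
  task_connectome_set(edges, sprintf("s%03d", seq_len(n)),
                      paste0("task", seq_along(task_list)), n_nodes)
}

test_that("an edge identical to the phenotype is always selected", {
  set.seed(61)
  n <- 50
  y <- rnorm(n)
  E <- matrix(rnorm(n * 10), n, 10)
  E[, 4] <- y
  sel <- select_edges(set_from_tasks(list(E), 5), y)
  expect_true(sel$mask[4, 1])
  expect_equal(unname(sel$p[4, 1]), 0)
})

test_that("partial correlation removes a motion-driven association", {
  set.seed(62)
  n <- 200
  motion <- abs(rnorm(n, 0.1, 0.03))
  y <- motion + rnorm(n, 0, 0.01)        # phenotype is almost pure motion
  E <- matrix(rnorm(n * 10), n, 10)
  E[, 2] <- motion                        # edge equals motion exactly
  tcs <- set_from_tasks(list(E), 5)
  sel_raw <- select_edges(tcs, y)
  sel_ctl <- select_edges(tcs, y, motion = motion)
  expect_true(sel_raw$mask[2, 1])
  expect_false(sel_ctl$mask[2, 1])
})

test_that("selection is invariant to adding a motion component to every edge", {
  set.seed(63)
  cfg <- small_config(n_nodes = 20, n_tasks = 2, n_signal_edges = 20,
                      n_group_edges = 0,
                      group_deltas = c(HC = 0, SCZ = 0, BPAD = 0, ADHD = 0),
                      n_motion_edges = 0, motion_edge_coeff = 0,
                      signal_task_profile = c(1, 1))
  coh <- simulate_cohort(cfg, seed = 3)
  y <- coh$truth$latent_trait
  motion <- coh$phenotypes$motion_grand_mean
  sel0 <- select_edges(coh$connectomes, y, motion = motion)
  shifted <- coh$connectomes
  shifted$edges <- coh$connectomes$edges + 4 *
    array(motion, dim = dim(coh$connectomes$edges))
  sel1 <- select_edges(shifted, y, motion = motion)
  expect_identical(sel0$mask, sel1$mask)
  expect_equal(sel0$r, sel1$r, tolerance = 1e-8)
})

test_that("a noiseless univariate fit reproduces the outcome", {
  set.seed(64)
  n <- 40
  e <- rnorm(n)
  y <- 2 * e
  E <- matrix(rnorm(n * 6), n, 6)
  E[, 3] <- e
  tcs <- set_from_tasks(list(E), 4)
  fit <- rcpm(tcs, y, lambda = 1e-6)
  expect_true(fit$mask[3, 1])
  expect_lt(max(abs(predict(fit, tcs) - y)), 1e-4)
})

test_that("infinite shrinkage collapses predictions to the training mean", {
  set.seed(65)
  n <- 40
  y <- rnorm(n)
  E <- matrix(rnorm(n * 6), n, 6)
  E[, 1] <- y + rnorm(n, 0, 0.1)
  tcs <- set_from_tasks(list(E), 4)
  fit <- rcpm(tcs, y, lambda = 1e6)
  expect_lt(max(abs(predict(fit, tcs) - mean(y))), 1e-3)
})

test_that("ridge weights match the closed-form penalized normal equations", {
  set.seed(66)
  n <- 50; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  lambda <- 3.7
  for (pp in c(30, 60)) {            # both p <= n and p > n code paths
    Xp <- matrix(rnorm(n * pp), n, pp)
    beta <- transcpm:::ridge_solve(Xp, y - mean(y), lambda)
    oracle <- solve(crossprod(Xp) + diag(lambda, pp), crossprod(Xp, y - mean(y)))
    expect_lt(max(abs(beta - drop(oracle))), 1e-8)
  }
})

test_that("training RSS is non-decreasing in the ridge penalty", {
  set.seed(67)
  n <- 60
  E <- matrix(rnorm(n * 21), n, 21)  # edge_count(7) = 21
  y <- E[, 1] - 0.5 * E[, 7] + rnorm(n, 0, 0.5)
  tcs <- set_from_tasks(list(E), 7)
  sel <- select_edges(tcs, y, alpha = 0.5)
  rss <- sapply(c(0.01, 1, 100, 1e4), function(l) {
    fit <- rcpm(tcs, y, selection = sel, lambda = l)
    sum((y - predict(fit, tcs))^2)
  })
  expect_true(all(diff(rss) >= 0))
})

test_that("prediction at the training feature means returns the intercept", {
  set.seed(68)
  cfg <- small_config(n_nodes = 12, n_tasks = 2, n_signal_edges = 10,
                      n_group_edges = 0,
                      group_deltas = c(HC = 0, SCZ = 0, BPAD = 0, ADHD = 0),
                      n_motion_edges = 0, signal_task_profile = c(1, 1))
  coh <- simulate_cohort(cfg, seed = 2)
  y <- coh$truth$latent_trait
  fit <- rcpm(coh$connectomes, y, lambda = 1)
  # one synthetic subject whose every edge equals the training mean
  mean_edges <- apply(coh$connectomes$edges, c(2, 3), mean)
  newset <- task_connectome_set(
    array(mean_edges, c(1, dim(mean_edges))), "avg",
    coh$connectomes$task_names, coh$connectomes$n_nodes)
  expect_equal(unname(predict(fit, newset)), fit$intercept, tolerance = 1e-10)
})

test_that("predictions are invariant to affine rescaling of an input edge", {
  set.seed(69)
  n <- 60
  E <- matrix(rnorm(n * 15), n, 15)
  y <- E[, 2] + rnorm(n, 0, 0.3)
  tcs <- set_from_tasks(list(E), 6)
  sel <- select_edges(tcs, y, alpha = 0.1)
  fit <- rcpm(tcs, y, selection = sel, lambda = 2)
  E2 <- E; E2[, 2] <- 5 * E[, 2] - 3
  tcs2 <- set_from_tasks(list(E2), 6)
  sel2 <- select_edges(tcs2, y, alpha = 0.1)
  expect_identical(sel$mask, sel2$mask)
  fit2 <- rcpm(tcs2, y, selection = sel2, lambda = 2)
  expect_equal(predict(fit2, tcs2), predict(fit, tcs), tolerance = 1e-8)
})

test_that("held-out prediction succeeds on planted-signal cohorts", {
  hits <- 0
  for (seed in 1:10) {
    cfg <- small_config(n_nodes = 60, n_tasks = 3, n_signal_edges = 150,
                        n_group_edges = 0,
                        group_deltas = c(HC = 0, SCZ = 0, BPAD = 0, ADHD = 0),
                        n_motion_edges = 0,
                        group_sizes = c(HC = 75, SCZ = 30, BPAD = 35, ADHD = 32),
                        signal_task_profile = c(1, 0, 0))
    coh <- simulate_cohort(cfg, seed = 100 + seed)
    y <- coh$truth$latent_trait
    train <- sample(172, 120)
    test <- setdiff(1:172, train)
    fit <- rcpm(coh$connectomes[train], y[train])
    r <- cor(predict(fit, coh$connectomes[test]), y[test])
    if (r > 0.3) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("empty selections yield a flagged mean-predicting model", {
  set.seed(70)
  n <- 30
  E <- matrix(rnorm(n * 10), n, 10)
  y <- rnorm(n)
  tcs <- set_from_tasks(list(E), 5)
  sel <- select_edges(tcs, y, alpha = 1e-12)
  expect_warning(fit <- rcpm(tcs, y, selection = sel), "no edges selected")
  expect_true(fit$empty)
  expect_equal(predict(fit, tcs), rep(mean(y), n))
})

test_that("task mismatches and bad inputs are rejected", {
  set.seed(71)
  tcs <- random_set(20, 2, 5)
  y <- rnorm(20)
  fit <- rcpm(tcs, y, lambda = 1, alpha = 0.5)
  other <- random_set(4, 3, 5)
  expect_error(predict(fit, other), "task mismatch")
  expect_error(select_edges(tcs, y[1:5]), "length")
  expect_error(select_edges(random_set(5, 1, 4), rnorm(5)), "10 training subjects")
})

test_that("the internal fold fitter matches the public pipeline functions", {
  set.seed(72)
  cfg <- small_config(n_nodes = 16, n_tasks = 2, n_signal_edges = 15,
                      signal_task_profile = c(1, 1), n_group_edges = 5,
                      n_motion_edges = 10)
  coh <- simulate_cohort(cfg, seed = 9)
  n <- length(coh$phenotypes$subject_ids)
  train <- sort(sample(n, 50)); test <- setdiff(seq_len(n), train)
  Elist <- transcpm:::edge_matrix_list(coh$connectomes)
  motion <- coh$phenotypes$motion_grand_mean
  internal <- transcpm:::rcpm_fold(Elist, coh$phenotypes$measures, motion,
                                   train, test, alpha = 0.01,
                                   lambda = 5, lambda_grid = NULL,
                                   n_inner_folds = 5)
  # public route on the same split
  lat <- fit_latent(coh$phenotypes$measures[train, ])
  y_tr <- apply_latent(lat, coh$phenotypes$measures[train, ])
  sel <- select_edges(coh$connectomes[train], y_tr, motion[train])
  fit <- rcpm(coh$connectomes[train], y_tr, selection = sel, lambda = 5)
  pred <- predict(fit, coh$connectomes[test])
  expect_equal(internal$mask, unname(sel$mask))
  expect_equal(internal$pred, unname(pred), tolerance = 1e-10)
  expect_equal(internal$actual,
               unname(apply_latent(lat, coh$phenotypes$measures[test, ])),
               tolerance = 1e-12)
})
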
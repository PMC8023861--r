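test_that("cross-validated R-squared follows its defining formula", {
  a <- c(1, 2, 3)
  expect_equal(r2_cv(a, a), list(q2 = 1, root = 1))
  expect_equal(r2_cv(a, rep(2, 3))$q2, 0)
  # SSres = 1, SStot = 2
  res <- r2_cv(c(1, 2, 3), c(1, 2, 4))
  expect_equal(res$q2, 0.5)
  expect_equal(res$root, sqrt(0.5), tolerance = 1e-4)
  # negative q2 reported as-is with undefined root
  res <- r2_cv(c(1, 2, 3), c(5, -4, 9))
  expect_lt(res$q2, 0)
  expect_true(is.na(res$root))
  expect_error(r2_cv(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(r2_cv(1:2, 1:2), "3 observations")
})

test_that("permutation p-values follow the (k+1)/(n+1) rule", {
  obs <- 0.5
  expect_equal(transcpm:::perm_pvalue(rep(0, 1000), obs), 1 / 1001)
  expect_equal(transcpm:::perm_pvalue(rep(1, 1000), obs), 1)
  null <- c(rep(0.9, 49), rep(0.1, 951))
  expect_equal(transcpm:::perm_pvalue(null, obs), 50 / 1001)
})

test_that("k-fold CV partitions subjects and is seed-deterministic", {
  cfg <- small_config(n_nodes = 16, n_tasks = 2, n_signal_edges = 15,
                      signal_task_profile = c(1, 1), n_group_edges = 5,
                      n_motion_edges = 10)
  coh <- simulate_cohort(cfg, seed = 20)
  cv1 <- kfold_cv(coh$connectomes, coh$phenotypes, k = 10, iterations = 2,
                  lambda = 5, seed = 33)
  cv2 <- kfold_cv(coh$connectomes, coh$phenotypes, k = 10, iterations = 2,
                  lambda = 5, seed = 33)
  expect_identical(cv1$q2, cv2$q2)
  expect_identical(cv1$fold_assignments, cv2$fold_assignments)
  # every subject predicted exactly once per iteration
  expect_false(anyNA(cv1$predicted))
  # folds approximately equal
  sizes <- table(cv1$fold_assignments[, 1])
  expect_lte(diff(range(sizes)), 1)
  # q2 of every iteration is at most 1
  expect_true(all(cv1$q2 <= 1))
  expect_error(kfold_cv(coh$connectomes, coh$phenotypes, k = 200), "k exceeds")
})

test_that("null cohorts give non-positive median q2, signal cohorts positive", {
  # out-of-fold residuals exceed the outcome variance in expectation under
  # the null; a single cohort can drift marginally above zero because its
  # spurious sample correlations are shared across folds, so the check runs
  # over several independent null cohorts
  meds <- sapply(1:10, function(s) {
    coh0 <- simulate_cohort(null_config(n_nodes = 16, n_tasks = 2,
                                        signal_task_profile = c(1, 1)),
                            seed = 20 + s)
    kfold_cv(coh0$connectomes, coh0$phenotypes, k = 10, iterations = 20,
             lambda = 10, seed = s)$median_q2
  })
  expect_lt(mean(meds), 0)
  expect_gte(sum(meds <= 0), 7)
  cfg <- small_config(n_nodes = 30, n_tasks = 2, n_signal_edges = 80,
                      signal_task_profile = c(1, 1), n_group_edges = 0,
                      group_deltas = c(HC = 0, SCZ = 0, BPAD = 0, ADHD = 0),
                      n_motion_edges = 0)
  coh1 <- simulate_cohort(cfg, seed = 22)
  cv1 <- kfold_cv(coh1$connectomes, coh1$phenotypes, k = 10, iterations = 5,
                  seed = 2)
  expect_gt(cv1$median_q2, 0.1)
})

test_that("behavior permutation destroys prediction and p is valid in form", {
  cfg <- small_config(n_nodes = 16, n_tasks = 2, n_signal_edges = 30,
                      signal_task_profile = c(1, 1), n_group_edges = 0,
                      group_deltas = c(HC = 0, SCZ = 0, BPAD = 0, ADHD = 0),
                      n_motion_edges = 0,
                      group_sizes = c(HC = 20, SCZ = 14, BPAD = 14, ADHD = 14))
  coh <- simulate_cohort(cfg, seed = 23)
  pt <- permutation_test_behavior(coh$connectomes, coh$phenotypes,
                                  n_perm = 30, iterations = 3, k = 5,
                                  lambda = 10, seed = 4)
  expect_equal(pt$p, transcpm:::perm_pvalue(pt$null, pt$observed))
  expect_gte(pt$p, 1 / 31)
  expect_lte(pt$p, 1)
  # planted signal should beat every shuffled null here
  expect_equal(pt$p, 1 / 31)
  expect_true(all(pt$null < pt$observed))
})

test_that("leave-one-group-out is deterministic and validates groups", {
  cfg <- small_config(n_nodes = 16, n_tasks = 2, n_signal_edges = 20,
                      signal_task_profile = c(1, 1))
  coh <- simulate_cohort(cfg, seed = 24)
  lg1 <- leave_group_out(coh$connectomes, coh$phenotypes, lambda = 5, seed = 1)
  lg2 <- leave_group_out(coh$connectomes, coh$phenotypes, lambda = 5, seed = 1)
  expect_identical(lg1$performance, lg2$performance)
  expect_setequal(lg1$performance$group, c("HC", "SCZ", "BPAD", "ADHD"))
  # group-independent planted signal predicts in every left-out group
  expect_true(all(lg1$performance$r > 0))

  tiny <- phenotype_table(c("a", "b", "c", "d"),
                          c("HC", "HC", "HC", "SCZ"),
                          rep(0.1, 4),
                          matrix(0.1, 4, 2, dimnames = list(NULL, c("t1", "t2"))),
                          matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("m1", "m2"))))
  tcs <- random_set(4, 2, 5)
  tcs$subject_ids <- tiny$subject_ids
  dimnames(tcs$edges)[[1]] <- tiny$subject_ids
  expect_error(leave_group_out(tcs, tiny), "at least 3 subjects")
})

test_that("group permutation classifies group-independent signal as uninformative", {
  cfg <- small_config(n_nodes = 16, n_tasks = 2, n_signal_edges = 30,
                      signal_task_profile = c(1, 1), n_group_edges = 0,
                      group_deltas = c(HC = 0, SCZ = 0, BPAD = 0, ADHD = 0),
                      n_motion_edges = 0,
                      group_sizes = c(HC = 20, SCZ = 12, BPAD = 12, ADHD = 12))
  coh <- simulate_cohort(cfg, seed = 25)
  gp <- group_permutation_test(coh$connectomes, coh$phenotypes, n_perm = 40,
                               lambda = 10, seed = 6)
  expect_true(all(gp$table$classification == "uninformative"))
  expect_warning(
    group_permutation_test(coh$connectomes, coh$phenotypes, n_perm = 10,
                           lambda = 10, seed = 6),
    "unstable")
})

test_that("the group-permutation null preserves group sizes and the seed", {
  cfg <- small_config(n_nodes = 12, n_tasks = 1, n_signal_edges = 10,
                      signal_task_profile = 1, n_group_edges = 5,
                      n_motion_edges = 5,
                      group_sizes = c(HC = 12, SCZ = 8, BPAD = 8, ADHD = 8))
  coh <- simulate_cohort(cfg, seed = 27)
  suppressWarnings({
    g1 <- group_permutation_test(coh$connectomes, coh$phenotypes, n_perm = 15,
                                 lambda = 10, seed = 9)
    g2 <- group_permutation_test(coh$connectomes, coh$phenotypes, n_perm = 15,
                                 lambda = 10, seed = 9)
  })
  expect_identical(g1$null, g2$null)
  expect_equal(g1$table$n, c(12, 8, 8, 8))
})

test_that("consistency degree matches a brute-force recount", {
  set.seed(26)
  n_nodes <- 8
  ne <- edge_count(n_nodes)
  masks <- matrix(runif(100 * ne) < 0.4, 100, ne)
  masks[, 3] <- TRUE                         # always selected
  masks[, 5] <- c(rep(TRUE, 94), rep(FALSE, 6))  # 94% < 95%
  cd <- consistency_degree(masks, n_nodes, threshold = 0.95)
  expect_true(cd$consistent[3])
  expect_false(cd$consistent[5])
  # brute force: recount incident consistent edges per node
  pairs <- edge_nodes(n_nodes)
  brute <- sapply(seq_len(n_nodes), function(v)
    sum(cd$consistent & (pairs[, 1] == v | pairs[, 2] == v)))
  expect_equal(cd$degree, brute)
  expect_equal(sum(cd$degree), 2 * cd$n_consistent)
  expect_error(consistency_degree(masks, n_nodes, threshold = 0), "threshold")
  expect_error(consistency_degree(masks[1, , drop = FALSE], n_nodes), "2 iterations")
})

test_that("external validation transfers planted signal across cohorts", {
  cfg <- small_config(n_nodes = 24, n_tasks = 1, n_signal_edges = 60,
                      signal_task_profile = 1, n_group_edges = 0,
                      group_deltas = c(HC = 0, SCZ = 0, BPAD = 0, ADHD = 0),
                      n_motion_edges = 0, effect_size = 0.6)
  for (seed in 1:3) {
    train <- simulate_cohort(cfg, seed = 400 + seed)
    # independent cohort from the same generating model (shared truth)
    test <- simulate_cohort(cfg, seed = 500 + seed, truth = train$truth)
    expect_identical(test$truth$signal_edges, train$truth$signal_edges)
    expect_false(identical(test$truth$latent_trait, train$truth$latent_trait))
    ev <- external_validate(train$connectomes, train$phenotypes$measures,
                            test$connectomes, test$phenotypes$measures,
                            seed = seed)
    expect_gt(ev$r, 0)
    # swapped roles also run and give finite r
    ev2 <- external_validate(test$connectomes, test$phenotypes$measures,
                             train$connectomes, train$phenotypes$measures,
                             seed = seed)
    expect_true(is.finite(ev2$r))
  }
})

test_that("no signal transfers to a null test cohort", {
  cfg <- small_config(n_nodes = 24, n_tasks = 1, n_signal_edges = 60,
                      signal_task_profile = 1, n_group_edges = 0,
                      group_deltas = c(HC = 0, SCZ = 0, BPAD = 0, ADHD = 0),
                      n_motion_edges = 0, effect_size = 0.6)
  train <- simulate_cohort(cfg, seed = 600)
  test <- simulate_cohort(null_config(n_nodes = 24, n_tasks = 1,
                                      signal_task_profile = 1),
                          seed = 601)
  ev <- external_validate(train$connectomes, train$phenotypes$measures,
                          test$connectomes, test$phenotypes$measures,
                          seed = 1)
  expect_lt(abs(ev$r), 0.25)  # ~3 sd of a null correlation at n = 172
  expect_error(
    external_validate(train$connectomes, train$phenotypes$measures,
                      simulate_cohort(null_config(n_nodes = 16, n_tasks = 1,
                                                  signal_task_profile = 1),
                                      seed = 5)$connectomes,
                      test$phenotypes$measures),
    "node-count mismatch")
})
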
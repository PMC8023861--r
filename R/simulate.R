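#' Synthetic cohort configuration
#'
#' Defines the data-generating conditions for [simulate_cohort()]: a standard
#' normal latent trait per subject that drives a sparse set of connectome
#' edges and noisy behavioral measures, diagnostic-group mean shifts on a
#' distinct edge set, and a positive per-subject motion confound that can
#' correlate with both edges and behavior.
#'
#' Defaults mirror the transdiagnostic study design this package targets:
#' four diagnostic groups of 75/30/35/32 subjects (172 total), a 268-node
#' atlas, six task connectomes, 150 signal edges whose planted edge-trait
#' correlation is `effect_size / sqrt(effect_size^2 + edge_noise_sd^2)`
#' (0.35 at the defaults), signal concentrated on the first task, 50
#' group-difference edges disjoint from the signal edges, and eight
#' behavioral measures in three construct families (3 working / 2 short /
#' 3 long-term memory instruments).
#'
#' @param group_sizes Named integer vector of subjects per diagnostic group.
#' @param n_nodes Number of atlas nodes.
#' @param n_tasks Number of task connectomes.
#' @param task_names Task names (length `n_tasks`).
#' @param n_signal_edges Number of trait-driven edges.
#' @param effect_size Edge shift per latent-trait SD at signal edges
#'   (`b`; default 0.3735, i.e. planted correlation 0.35 at noise sd 1).
#' @param signal_task_profile Per-task multiplier on `effect_size`.
#' @param n_group_edges Number of edges carrying group mean shifts.
#' @param group_deltas Named numeric vector: edge-unit shift per group at
#'   group edges.
#' @param measure_loadings Named numeric vector of trait loadings, one per
#'   behavioral measure.
#' @param measure_constructs Construct family per measure (same length and
#'   order as `measure_loadings`).
#' @param measure_noise_sd Measurement noise sd.
#' @param edge_noise_sd Edge noise sd (edge units).
#' @param edge_mean,edge_mean_sd Distribution of per-edge baseline means
#'   (Fisher-z units).
#' @param motion_mean,motion_sd Motion is `|Normal(motion_mean, motion_sd)|`
#'   mm, so a realistic small fraction of subjects fails the QC thresholds.
#' @param motion_task_sd Per-task jitter (mm) around each subject's latent
#'   motion level.
#' @param motion_trait_corr Correlation between the latent trait and the
#'   (pre-absolute-value) motion level, induced via a Gaussian copula.
#' @param motion_edge_coeff Edge shift per mm of motion at motion-affected
#'   edges.
#' @param n_motion_edges Number of motion-affected edges (disjoint from
#'   signal and group edges).
#' @param seed Optional integer seed; [simulate_cohort()] is deterministic
#'   given the same config and seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(HC = 75, SCZ = 30, BPAD = 35, ADHD = 32),
                          n_nodes = 268,
                          n_tasks = 6,
                          task_names = c("BART", "PAM-E", "PAM-R", "SCAP", "SS", "TS")[seq_len(n_tasks)],
                          n_signal_edges = 150,
                          effect_size = 0.3735,
                          signal_task_profile = c(1, rep(0, n_tasks - 1)),
                          n_group_edges = 50,
                          group_deltas = c(HC = 0, SCZ = 1, BPAD = -1, ADHD = 0.5),
                          measure_loadings = c(working_1 = 0.9, working_2 = 0.8,
                                               working_3 = 0.7, short_1 = 0.85,
                                               short_2 = 0.75, long_1 = 0.9,
                                               long_2 = 0.8, long_3 = 0.7),
                          measure_constructs = c(rep("working", 3), rep("short", 2),
                                                 rep("long", 3)),
                          measure_noise_sd = 0.5,
                          edge_noise_sd = 1,
                          edge_mean = 0.3,
                          edge_mean_sd = 0.25,
                          motion_mean = 0.08,
                          motion_sd = 0.03,
                          motion_task_sd = 0.02,
                          motion_trait_corr = 0.2,
                          motion_edge_coeff = 5,
                          n_motion_edges = 200,
                          seed = NULL) {
  if (is.null(names(group_sizes))) stop("group_sizes must be named")
  if (any(group_sizes <= 0)) stop("group sizes must be positive")
  if (length(task_names) != n_tasks) stop("task_names length != n_tasks")
  if (length(signal_task_profile) != n_tasks)
    stop("signal_task_profile length != n_tasks")
  if (length(measure_constructs) != length(measure_loadings))
    stop("measure_constructs length != measure_loadings")
  if (!setequal(names(group_deltas), names(group_sizes)))
    stop("group_deltas must name the same groups as group_sizes")
  if (measure_noise_sd < 0 || edge_noise_sd < 0 || motion_sd < 0 ||
      motion_task_sd < 0)
    stop("standard deviations must be >= 0")
  if (abs(motion_trait_corr) >= 1) stop("|motion_trait_corr| must be < 1")
  n_edges <- edge_count(n_nodes)
  if (n_signal_edges + n_group_edges + n_motion_edges > n_edges)
    stop(sprintf("signal + group + motion edges (%d) exceed edge count (%d)",
                 n_signal_edges + n_group_edges + n_motion_edges, n_edges))
  structure(mget(names(formals(cohort_config))), class = "cohort_config")
}

#' Simulate a multi-task connectome cohort with ground truth
#'
#' Draws a latent trait `m_i ~ N(0, 1)` per subject; behavioral measures
#' `x_ij = lambda_j m_i + noise`; edges
#' `e_ikm = mu_k + b p_m m_i 1[k in signal] + delta_g(i) 1[k in group set]
#'  + c 1[k in motion set] motion_i + noise`;
#' and positive motion correlated with the trait through a Gaussian copula.
#' Signal, group, and motion edge sets are drawn disjointly.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; overrides `config$seed` when supplied.
#' @param truth Optional `truth` element of a previous [simulate_cohort()]
#'   call with a compatible config: reuses its planted edge sets and
#'   baseline edge means so that a second, independent cohort is drawn from
#'   the same generating model (fresh subjects, traits, and noise) --- the
#'   setting external validation assumes.
#' @return A list of class `cohort` with elements `connectomes`
#'   ([task_connectome_set()]), `phenotypes` ([phenotype_table()]), and
#'   `truth` (latent trait, per-task signal edge sets, group and motion edge
#'   sets, loadings, realized motion, baseline edge means).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL,
                            truth = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- if (!is.null(seed)) seed else config$seed
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  n <- sum(cfg$group_sizes)
  n_edges <- edge_count(cfg$n_nodes)
  subject_ids <- sprintf("S%04d", seq_len(n))
  group <- factor(rep(names(cfg$group_sizes), cfg$group_sizes),
                  levels = names(cfg$group_sizes))

  trait <- stats::rnorm(n)

  # behavioral measures loading on the trait
  lambda <- cfg$measure_loadings
  measures <- outer(trait, lambda) +
    matrix(stats::rnorm(n * length(lambda), 0, cfg$measure_noise_sd),
           n, length(lambda))
  colnames(measures) <- names(lambda)

  # motion: |N(mean, sd)| with trait correlation via Gaussian copula
  rho <- cfg$motion_trait_corr
  z <- rho * trait + sqrt(1 - rho^2) * stats::rnorm(n)
  motion_level <- abs(cfg$motion_mean + cfg$motion_sd * z)
  motion_per_task <- abs(motion_level +
    matrix(stats::rnorm(n * cfg$n_tasks, 0, cfg$motion_task_sd), n, cfg$n_tasks))
  colnames(motion_per_task) <- cfg$task_names
  motion_grand <- rowMeans(motion_per_task)

  if (is.null(truth)) {
    # disjoint edge sets
    pool <- sample.int(n_edges,
                       cfg$n_signal_edges + cfg$n_group_edges + cfg$n_motion_edges)
    signal_edges <- sort(pool[seq_len(cfg$n_signal_edges)])
    group_edges <- sort(pool[cfg$n_signal_edges + seq_len(cfg$n_group_edges)])
    motion_edges <- sort(pool[cfg$n_signal_edges + cfg$n_group_edges +
                                seq_len(cfg$n_motion_edges)])
    mu <- stats::rnorm(n_edges, cfg$edge_mean, cfg$edge_mean_sd)
  } else {
    if (length(truth$edge_means) != n_edges)
      stop("supplied truth does not match the config's edge count")
    signal_edges <- truth$signal_edges
    group_edges <- truth$group_edges
    motion_edges <- truth$motion_edges
    mu <- truth$edge_means
  }
  deltas <- cfg$group_deltas[as.character(group)]

  edges <- array(NA_real_, dim = c(n, cfg$n_tasks, n_edges))
  for (t in seq_len(cfg$n_tasks)) {
    E <- matrix(stats::rnorm(n * n_edges, 0, cfg$edge_noise_sd), n, n_edges)
    E <- sweep(E, 2L, mu, "+")
    b_t <- cfg$effect_size * cfg$signal_task_profile[t]
    if (b_t != 0 && length(signal_edges))
      E[, signal_edges] <- E[, signal_edges] + outer(trait, rep(b_t, length(signal_edges)))
    if (length(group_edges))
      E[, group_edges] <- E[, group_edges] + outer(deltas, rep(1, length(group_edges)))
    if (cfg$motion_edge_coeff != 0 && length(motion_edges))
      E[, motion_edges] <- E[, motion_edges] +
        outer(cfg$motion_edge_coeff * motion_grand, rep(1, length(motion_edges)))
    edges[, t, ] <- E
  }

  connectomes <- task_connectome_set(edges, subject_ids, cfg$task_names,
                                     cfg$n_nodes)
  phenotypes <- phenotype_table(subject_ids, group, motion_grand,
                                motion_per_task, measures)
  signal_by_task <- lapply(seq_len(cfg$n_tasks), function(t)
    if (cfg$signal_task_profile[t] != 0) signal_edges else integer(0))
  names(signal_by_task) <- cfg$task_names
  truth <- list(latent_trait = trait, signal_edges = signal_edges,
                signal_edges_by_task = signal_by_task,
                group_edges = group_edges, motion_edges = motion_edges,
                measure_loadings = lambda, motion = motion_grand,
                edge_means = mu)
  structure(list(connectomes = connectomes, phenotypes = phenotypes,
                 truth = truth, config = cfg),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("synthetic cohort\n")
  print(x$connectomes)
  print(x$phenotypes)
  invisible(x)
}

#' Simulate node time series with trait-coupled node pairs
#'
#' Generates per-subject, per-task node time series in which the two nodes of
#' each planted signal pair share a common latent signal whose mixing weight
#' increases with the subject's latent trait. Applying [compute_fc()] to the
#' output therefore yields an edge-trait association at the planted pairs,
#' letting the connectome stage be tested end to end.
#'
#' @param config A [cohort_config()]; its signal edges define the planted
#'   pairs and `signal_task_profile` scales the trait coupling per task.
#' @param frames Frames per series (>= 50; correlation estimates are too
#'   unstable below that for testing).
#' @param base_coupling Mixing weight at trait 0.
#' @param coupling_slope Increase in mixing weight per trait SD (scaled by
#'   the task profile); weights are clamped to `[0, 0.95]`.
#' @param seed Integer seed; overrides `config$seed` when supplied.
#' @return A list of class `cohort_timeseries` with `timeseries` (list over
#'   subjects of lists over tasks of frames x nodes matrices), `truth`
#'   (latent trait and planted pairs), and the config.
#' @export
simulate_timeseries <- function(config = cohort_config(), frames = 200,
                                base_coupling = 0.2, coupling_slope = 0.15,
                                seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (frames < 50) stop("frames must be >= 50")
  seed <- if (!is.null(seed)) seed else config$seed
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  n <- sum(cfg$group_sizes)
  subject_ids <- sprintf("S%04d", seq_len(n))
  trait <- stats::rnorm(n)
  n_edges <- edge_count(cfg$n_nodes)
  signal_edges <- sort(sample.int(n_edges, cfg$n_signal_edges))
  pairs <- edge_nodes(cfg$n_nodes)[signal_edges, , drop = FALSE]

  ts <- vector("list", n)
  names(ts) <- subject_ids
  for (i in seq_len(n)) {
    per_task <- vector("list", cfg$n_tasks)
    names(per_task) <- cfg$task_names
    for (t in seq_len(cfg$n_tasks)) {
      X <- matrix(stats::rnorm(frames * cfg$n_nodes), frames, cfg$n_nodes)
      w <- base_coupling + coupling_slope * cfg$signal_task_profile[t] * trait[i]
      w <- min(max(w, 0), 0.95)
      if (w > 0 && nrow(pairs)) {
        for (p in seq_len(nrow(pairs))) {
          s <- stats::rnorm(frames)
          for (node in pairs[p, ]) {
            X[, node] <- sqrt(1 - w^2) * X[, node] + w * s
          }
        }
      }
      per_task[[t]] <- X
    }
    ts[[i]] <- per_task
  }
  structure(list(timeseries = ts,
                 truth = list(latent_trait = trait,
                              signal_edges = signal_edges,
                              signal_pairs = pairs),
                 config = cfg, frames = frames),
            class = "cohort_timeseries")
}
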
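# One-config orchestration of the full analysis graph on a synthetic (or
# loaded) cohort: simulate -> motion QC -> construct scores -> k-fold CV
# (+ behavior permutations) -> leave-one-group-out (+ group permutations) ->
# edgewise MANOVA -> contributions and network overlap, with a hashed run
# manifest for reproducibility.

#' Experiment configuration
#'
#' Aggregates the pipeline defaults: selection threshold 0.01, edgewise FDR
#' 0.05, leave-one-group-out FDR 0.001, consistency threshold 0.95, 1000
#' k-fold divisions, 1000 behavior permutations, 200 group permutations.
#' Desk-scale runs override the iteration counts.
#'
#' @param cohort A [cohort_config()] for the synthetic cohort, or `NULL`
#'   when `paths` point at data on disk.
#' @param paths Optional list with `connectomes` (directory for
#'   [read_connectomes()]) and `phenotypes` (CSV); used instead of
#'   simulation when supplied.
#' @param constructs Named list mapping construct name to measure names;
#'   default: the cohort config's construct families, plus an `"all"`
#'   construct pooling every measure.
#' @param netmap Optional [network_map()]; default: nodes assigned to the
#'   10 canonical networks round-robin (synthetic stand-in).
#' @param alpha Edge-selection threshold.
#' @param fdr_q Edgewise FDR level for the MANOVA.
#' @param logo_fdr_q FDR level for the group-permutation classification.
#' @param consistency_threshold Selection-consistency fraction.
#' @param kfold_iterations,n_perm_behavior,n_perm_group Iteration counts.
#' @param run_behavior_permutation,run_group_permutation,run_mma Stage
#'   switches.
#' @param lambda Fixed ridge penalty or `NULL` for inner CV.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(), paths = NULL,
                              constructs = NULL, netmap = NULL,
                              alpha = 0.01, fdr_q = 0.05, logo_fdr_q = 0.001,
                              consistency_threshold = 0.95,
                              kfold_iterations = 1000L,
                              n_perm_behavior = 1000L, n_perm_group = 200L,
                              run_behavior_permutation = FALSE,
                              run_group_permutation = TRUE,
                              run_mma = TRUE,
                              lambda = NULL, seed = 1L,
                              out_dir = tempfile("transcpm_run_")) {
  structure(mget(names(formals(experiment_config))),
            class = "experiment_config")
}

default_constructs <- function(cohort_cfg) {
  fams <- split(names(cohort_cfg$measure_loadings), cohort_cfg$measure_constructs)
  fams$all <- names(cohort_cfg$measure_loadings)
  fams
}

write_run_csv <- function(df, dir, name) {
  f <- file.path(dir, name)
  data.table::fwrite(df, f, sep = ",")
  f
}

#' Run the full experiment graph
#'
#' Executes every stage of the analysis on one configuration, writing CSV
#' tables, a `metrics.json` of headline quantities, and a `manifest.json`
#' listing every output file with its MD5 hash, the stage log, and the
#' seeds used. Rerunning with the same config reproduces all stochastic
#' results exactly. A stage failure is recorded with its stage name and
#' downstream stages are skipped.
#'
#' @param config An [experiment_config()].
#' @return Invisibly, a list of class `experiment_result` with the in-memory
#'   stage results and the output directory.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  metrics <- list()
  files <- character(0)
  results <- list(out_dir = config$out_dir)
  seed <- as.integer(config$seed)
  failed <- NULL

  stage <- function(name, expr) {
    if (!is.null(failed)) {
      log[[name]] <<- "skipped"
      return(NULL)
    }
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- name
      log[[name]] <<- paste("FAILED:", conditionMessage(res))
      NULL
    } else {
      log[[name]] <<- "ok"
      res
    }
  }

  # --- data ------------------------------------------------------------
  data <- stage("data", {
    if (!is.null(config$paths)) {
      list(connectomes = read_connectomes(config$paths$connectomes),
           phenotypes = read_phenotypes(config$paths$phenotypes),
           truth = NULL)
    } else {
      simulate_cohort(config$cohort, seed = seed)
    }
  })

  # --- motion QC -------------------------------------------------------
  qc <- stage("qc", {
    q <- motion_qc(data$phenotypes)
    keep <- q$retained
    list(qc = q,
         connectomes = data$connectomes[keep],
         phenotypes = data$phenotypes[keep])
  })
  if (!is.null(qc)) {
    metrics$n_total <- length(data$phenotypes$subject_ids)
    metrics$n_retained <- length(qc$qc$retained)
    files <- c(files, write_run_csv(
      if (nrow(qc$qc$exclusions)) qc$qc$exclusions else
        data.frame(subject_id = character(0), reason = character(0)),
      config$out_dir, "qc_exclusions.csv"))
    results$qc <- qc$qc
  }

  constructs <- if (!is.null(config$constructs)) config$constructs
                else default_constructs(config$cohort)
  netmap <- config$netmap
  if (is.null(netmap) && !is.null(qc))
    netmap <- network_map(rep_len(canonical_networks,
                                  qc$connectomes$n_nodes))

  # --- k-fold CV per construct ----------------------------------------
  cv <- stage("kfold", {
    out <- list()
    for (ci in seq_along(constructs)) {
      out[[names(constructs)[ci]]] <- kfold_cv(
        qc$connectomes, qc$phenotypes, constructs[[ci]],
        iterations = config$kfold_iterations, alpha = config$alpha,
        lambda = config$lambda, seed = seed + 1000L + ci)
    }
    out
  })
  if (!is.null(cv)) {
    results$kfold <- cv
    tab <- data.frame(construct = names(cv),
                      median_q2 = vapply(cv, function(x) x$median_q2, numeric(1)),
                      median_root = vapply(cv, function(x) x$median_root, numeric(1)))
    files <- c(files, write_run_csv(tab, config$out_dir, "kfold_performance.csv"))
    metrics$median_q2 <- stats::setNames(as.list(tab$median_q2), tab$construct)
  }

  perm <- if (config$run_behavior_permutation) stage("behavior_permutation", {
    out <- list()
    for (ci in seq_along(constructs)) {
      out[[names(constructs)[ci]]] <- permutation_test_behavior(
        qc$connectomes, qc$phenotypes, constructs[[ci]],
        n_perm = config$n_perm_behavior, alpha = config$alpha,
        lambda = config$lambda, seed = seed + 2000L + ci,
        observed = cv[[names(constructs)[ci]]])
    }
    out
  })
  if (!is.null(perm)) {
    results$behavior_permutation <- perm
    metrics$permutation_p <- lapply(perm, function(x) x$p)
  }

  # --- leave-one-group-out --------------------------------------------
  logo <- stage("logo", {
    out <- list()
    for (ci in seq_along(constructs)) {
      nm <- names(constructs)[ci]
      out[[nm]] <- if (config$run_group_permutation)
        group_permutation_test(qc$connectomes, qc$phenotypes, constructs[[ci]],
                               n_perm = config$n_perm_group,
                               fdr_q = config$logo_fdr_q,
                               alpha = config$alpha, lambda = config$lambda,
                               seed = seed + 3000L + ci)
      else leave_group_out(qc$connectomes, qc$phenotypes, constructs[[ci]],
                           alpha = config$alpha, lambda = config$lambda,
                           seed = seed + 3000L + ci)
    }
    out
  })
  if (!is.null(logo)) {
    results$logo <- logo
    tabs <- lapply(names(logo), function(nm) {
      t <- if (inherits(logo[[nm]], "group_permutation_result"))
        logo[[nm]]$table else logo[[nm]]$performance
      cbind(construct = nm, t)
    })
    files <- c(files, write_run_csv(do.call(rbind, tabs), config$out_dir,
                                    "logo_performance.csv"))
    metrics$logo_r <- lapply(logo, function(x) {
      t <- if (inherits(x, "group_permutation_result")) x$table else x$performance
      stats::setNames(as.list(t$r), t$group)
    })
  }

  # --- mass multivariate analysis -------------------------------------
  mma <- if (config$run_mma) stage("mma", {
    res <- edgewise_manova(qc$connectomes, qc$phenotypes$group)
    mask <- fdr_correct(res$p, config$fdr_q)
    summ <- mma_summaries(res, mask, netmap)
    list(result = res, mask = mask, summaries = summ)
  })
  if (!is.null(mma)) {
    results$mma <- mma
    pairs <- edge_nodes(qc$connectomes$n_nodes)
    files <- c(files, write_run_csv(
      data.frame(edge = seq_along(mma$result$F), node_a = pairs[, 1L],
                 node_b = pairs[, 2L], F = mma$result$F, p = mma$result$p,
                 significant = mma$mask),
      config$out_dir, "mma_edges.csv"))
    metrics$mma_significant_edges <- sum(mma$mask)
  }

  # --- interpretation --------------------------------------------------
  interp <- stage("interpretation", {
    out <- list()
    set.seed(seed + 4000L)
    for (ci in seq_along(constructs)) {
      nm <- names(constructs)[ci]
      meas <- resolve_measures(qc$phenotypes, constructs[[ci]])
      y <- apply_latent(fit_latent(meas), meas)
      model <- rcpm(qc$connectomes, y,
                    motion = qc$phenotypes$motion_grand_mean,
                    alpha = config$alpha, lambda = config$lambda)
      w_n <- node_contribution(model)
      cons <- consistency_degree(cv[[nm]]$masks, qc$connectomes$n_nodes,
                                 config$consistency_threshold)
      out[[nm]] <- list(
        model = model, w_n = w_n,
        w_m = task_contribution(model),
        network_means = network_average(w_n, netmap),
        consistency = cons,
        overlap = edge_set_network_profile(cons$consistent, netmap),
        mma_similarity = if (!is.null(mma))
          profile_similarity(w_n, mma$summaries$node_scores))
    }
    out
  })
  if (!is.null(interp)) {
    results$interpretation <- interp
    wm <- do.call(rbind, lapply(names(interp), function(nm)
      data.frame(construct = nm, task = names(interp[[nm]]$w_m),
                 w_m = as.numeric(interp[[nm]]$w_m))))
    files <- c(files, write_run_csv(wm, config$out_dir, "task_contributions.csv"))
    wn <- do.call(rbind, lapply(names(interp), function(nm)
      data.frame(construct = nm, node = seq_along(interp[[nm]]$w_n),
                 w_n = interp[[nm]]$w_n,
                 consistency_degree = interp[[nm]]$consistency$degree)))
    files <- c(files, write_run_csv(wn, config$out_dir, "node_contributions.csv"))
    ov <- do.call(rbind, lapply(names(interp), function(nm)
      cbind(construct = nm, interp[[nm]]$overlap)))
    files <- c(files, write_run_csv(ov, config$out_dir, "network_overlap.csv"))
    metrics$consistent_edges <- lapply(interp, function(x) x$consistency$n_consistent)
    if (!is.null(mma))
      metrics$mma_node_similarity_r <- lapply(interp, function(x) x$mma_similarity$r)
  }

  # --- manifest --------------------------------------------------------
  metrics_file <- file.path(config$out_dir, "metrics.json")
  jsonlite::write_json(metrics, metrics_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, metrics_file)
  hashes <- as.list(tools::md5sum(files))
  names(hashes) <- basename(names(hashes))
  manifest <- list(seed = seed, stages = log, failed_stage = failed,
                   files = hashes,
                   thresholds = list(alpha = config$alpha, fdr_q = config$fdr_q,
                                     logo_fdr_q = config$logo_fdr_q,
                                     consistency = config$consistency_threshold),
                   iterations = list(kfold = config$kfold_iterations,
                                     behavior_perm = config$n_perm_behavior,
                                     group_perm = config$n_perm_group))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$metrics <- metrics
  results$manifest <- manifest
  results$log <- log
  class(results) <- "experiment_result"
  invisible(results)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment run:", x$out_dir, "\n")
  for (nm in names(x$log)) cat(sprintf("  %-22s %s\n", nm, x$log[[nm]]))
  invisible(x)
}
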
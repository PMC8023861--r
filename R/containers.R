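#' Multi-task connectome container
#'
#' Holds one edge vector per subject per task, in Fisher-z units, with shared
#' subject ordering across tasks. The edge dimension follows the canonical
#' upper-triangle ordering of [vectorize_edges()].
#'
#' @param edges Numeric array with dimensions (subject, task, edge), all
#'   values finite.
#' @param subject_ids Character vector of unique subject identifiers.
#' @param task_names Character vector of unique task names.
#' @param n_nodes Number of atlas nodes; the edge dimension must equal
#'   `n_nodes * (n_nodes - 1) / 2`.
#' @return An object of class `task_connectome_set`.
#' @export
task_connectome_set <- function(edges, subject_ids, task_names, n_nodes) {
  subject_ids <- as.character(subject_ids)
  task_names <- as.character(task_names)
  n_nodes <- as.integer(n_nodes)
  if (!is.array(edges) || length(dim(edges)) != 3L)
    stop("`edges` must be a 3-d array (subject, task, edge)")
  d <- dim(edges)
  if (d[1L] != length(subject_ids))
    stop("subject dimension does not match subject_ids")
  if (d[2L] != length(task_names))
    stop("task dimension does not match task_names")
  if (d[3L] != edge_count(n_nodes))
    stop(sprintf("edge dimension %d does not equal n_nodes*(n_nodes-1)/2 = %d",
                 d[3L], edge_count(n_nodes)))
  if (anyDuplicated(subject_ids))
    stop("duplicate subject IDs")
  if (anyDuplicated(task_names))
    stop("duplicate task names")
  if (!all(is.finite(edges)))
    stop("all edge values must be finite")
  dimnames(edges) <- list(subject_ids, task_names, NULL)
  structure(
    list(subject_ids = subject_ids, task_names = task_names,
         n_nodes = n_nodes, edges = edges),
    class = "task_connectome_set")
}

#' @export
print.task_connectome_set <- function(x, ...) {
  cat(sprintf("task_connectome_set: %d subjects x %d tasks x %d edges (%d nodes)\n",
              length(x$subject_ids), length(x$task_names),
              dim(x$edges)[3L], x$n_nodes))
  cat("  tasks:", paste(x$task_names, collapse = ", "), "\n")
  invisible(x)
}

#' Subset a connectome set by subject
#'
#' @param x A `task_connectome_set`.
#' @param i Subject index (integer, logical, or subject IDs).
#' @param ... Ignored.
#' @return A `task_connectome_set` restricted to the chosen subjects.
#' @export
`[.task_connectome_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$subject_ids)
  task_connectome_set(x$edges[i, , , drop = FALSE],
                      x$subject_ids[i], x$task_names, x$n_nodes)
}

#' Edge matrix for one task
#'
#' @param x A `task_connectome_set`.
#' @param task Task name or index.
#' @return Numeric matrix (subject x edge).
#' @export
task_edges <- function(x, task) {
  stopifnot(inherits(x, "task_connectome_set"))
  if (is.character(task)) {
    task <- match(task, x$task_names)
    if (is.na(task)) stop("unknown task")
  }
  out <- x$edges[, task, , drop = TRUE]
  if (length(x$subject_ids) == 1L) out <- matrix(out, nrow = 1L)
  rownames(out) <- x$subject_ids
  out
}

#' Per-subject phenotype table
#'
#' Stores diagnostic group, motion summaries, and raw behavioral measures,
#' aligned by subject ID with a [task_connectome_set()].
#'
#' @param subject_ids Character vector of unique subject IDs.
#' @param group Diagnostic group label per subject (factor or character).
#' @param motion_grand_mean Grand-mean frame-to-frame displacement (mm) per
#'   subject; `NA` allowed (treated as missing by [motion_qc()]).
#' @param motion_per_task Numeric matrix (subject x task) of per-task mean
#'   displacement in mm, with task column names.
#' @param measures Numeric matrix (subject x measure) of raw behavioral
#'   measures, with measure column names.
#' @return An object of class `phenotype_table`.
#' @export
phenotype_table <- function(subject_ids, group, motion_grand_mean = NULL,
                            motion_per_task = NULL, measures = NULL) {
  subject_ids <- as.character(subject_ids)
  n <- length(subject_ids)
  if (anyDuplicated(subject_ids)) stop("duplicate subject IDs")
  group <- as.factor(group)
  if (length(group) != n) stop("group length does not match subject_ids")
  if (anyNA(group)) stop("every subject must have a group label")
  if (!is.null(motion_grand_mean)) {
    if (length(motion_grand_mean) != n) stop("motion_grand_mean length mismatch")
    if (any(motion_grand_mean < 0, na.rm = TRUE)) stop("motion values must be >= 0")
  }
  if (!is.null(motion_per_task)) {
    motion_per_task <- as.matrix(motion_per_task)
    if (nrow(motion_per_task) != n) stop("motion_per_task row count mismatch")
    if (is.null(colnames(motion_per_task))) stop("motion_per_task needs task names")
    if (any(motion_per_task < 0, na.rm = TRUE)) stop("motion values must be >= 0")
    rownames(motion_per_task) <- subject_ids
  }
  if (!is.null(measures)) {
    measures <- as.matrix(measures)
    if (nrow(measures) != n) stop("measures row count mismatch")
    if (is.null(colnames(measures))) stop("measures need measure names")
    rownames(measures) <- subject_ids
  }
  structure(
    list(subject_ids = subject_ids, group = group,
         motion_grand_mean = motion_grand_mean,
         motion_per_task = motion_per_task, measures = measures),
    class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d subjects, groups: %s\n",
              length(x$subject_ids),
              paste(sprintf("%s=%d", levels(x$group), tabulate(x$group)),
                    collapse = " ")))
  if (!is.null(x$measures))
    cat("  measures:", paste(colnames(x$measures), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.phenotype_table` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$subject_ids)
  phenotype_table(
    x$subject_ids[i], x$group[i],
    if (!is.null(x$motion_grand_mean)) x$motion_grand_mean[i],
    if (!is.null(x$motion_per_task)) x$motion_per_task[i, , drop = FALSE],
    if (!is.null(x$measures)) x$measures[i, , drop = FALSE])
}

#' Canonical network labels
#'
#' The fixed 10-network partition used for network-level summaries: medial
#' frontal (MF), frontoparietal (FP), default mode (DMN), motor (Mot),
#' visual A (VI), visual B (VII), visual association (VAs), salience (SAL),
#' subcortical (SC), and cerebellum (CBL).
#'
#' @export
canonical_networks <- c("MF", "FP", "DMN", "Mot", "VI", "VII",
                        "VAs", "SAL", "SC", "CBL")

#' Node-to-network assignment
#'
#' @param labels Network label per node (length `n_nodes`); every node must
#'   carry exactly one label drawn from `levels`.
#' @param levels Allowed label set (default [canonical_networks]).
#' @return Factor of class `network_map` with one element per node.
#' @export
network_map <- function(labels, levels = canonical_networks) {
  labels <- as.character(labels)
  if (anyNA(labels)) stop("every node must have a network label")
  bad <- setdiff(unique(labels), levels)
  if (length(bad))
    stop("unknown network labels: ", paste(bad, collapse = ", "))
  structure(factor(labels, levels = levels), class = c("network_map", "factor"))
}

#' @export
print.network_map <- function(x, ...) {
  cat(sprintf("network_map: %d nodes over %d networks\n",
              length(x), nlevels(x)))
  print(table(unclass(x)))
  invisible(x)
}

# internal: check a connectome set and phenotype table refer to the same
# subjects in the same order
check_paired <- function(connectomes, phenotypes) {
  if (!identical(connectomes$subject_ids, phenotypes$subject_ids))
    stop("connectome and phenotype subject IDs do not align")
  invisible(TRUE)
}
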
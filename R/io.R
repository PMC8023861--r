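# Readers and writers for the three typed containers. All formats are plain
# text: a packed whitespace-delimited edge table plus a JSON sidecar for
# connectomes (or one square matrix file per subject/task), and headered CSV
# for phenotypes and network maps. Round trips are lossless to full double
# precision.

#' Write a connectome set to disk
#'
#' @param x A [task_connectome_set()].
#' @param path Directory to create/write into.
#' @param format `"packed"` (one edge table `edges.txt`, rows ordered task
#'   within subject, plus `meta.json`) or `"matrices"` (one square matrix
#'   file per subject/task plus `meta.json`).
#' @return `path`, invisibly.
#' @export
write_connectomes <- function(x, path, format = c("packed", "matrices")) {
  stopifnot(inherits(x, "task_connectome_set"))
  format <- match.arg(format)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = format, subject_ids = x$subject_ids,
               task_names = x$task_names, n_nodes = x$n_nodes)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE)
  if (format == "packed") {
    n_s <- length(x$subject_ids); n_t <- length(x$task_names)
    rows <- matrix(aperm(x$edges, c(2L, 1L, 3L)), nrow = n_s * n_t)
    data.table::fwrite(data.table::as.data.table(rows),
                       file.path(path, "edges.txt"),
                       sep = " ", col.names = FALSE)
  } else {
    for (s in seq_along(x$subject_ids)) {
      for (t in seq_along(x$task_names)) {
        m <- restore_matrix(x$edges[s, t, ], x$n_nodes)
        f <- file.path(path, sprintf("%s__%s.txt", x$subject_ids[s],
                                     x$task_names[t]))
        data.table::fwrite(data.table::as.data.table(m), f,
                           sep = " ", col.names = FALSE)
      }
    }
  }
  invisible(path)
}

#' Read a connectome set written by [write_connectomes()]
#'
#' @param path Directory containing `meta.json` and the edge data.
#' @return A [task_connectome_set()].
#' @export
read_connectomes <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file))
    stop("no meta.json found in ", path)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  n_s <- length(meta$subject_ids); n_t <- length(meta$task_names)
  n_e <- edge_count(meta$n_nodes)
  if (identical(meta$format, "packed")) {
    f <- file.path(path, "edges.txt")
    rows <- as.matrix(data.table::fread(f, header = FALSE, sep = " "))
    if (nrow(rows) != n_s * n_t || ncol(rows) != n_e)
      stop(sprintf("%s: expected %d x %d edge table, found %d x %d",
                   f, n_s * n_t, n_e, nrow(rows), ncol(rows)))
    edges <- aperm(array(rows, dim = c(n_t, n_s, n_e)), c(2L, 1L, 3L))
  } else {
    edges <- array(NA_real_, dim = c(n_s, n_t, n_e))
    for (s in seq_len(n_s)) {
      for (t in seq_len(n_t)) {
        f <- file.path(path, sprintf("%s__%s.txt", meta$subject_ids[s],
                                     meta$task_names[t]))
        if (!file.exists(f)) stop("missing matrix file: ", f)
        m <- as.matrix(data.table::fread(f, header = FALSE, sep = " "))
        if (nrow(m) != meta$n_nodes || ncol(m) != meta$n_nodes)
          stop(sprintf("%s: expected %d x %d matrix", f, meta$n_nodes,
                       meta$n_nodes))
        edges[s, t, ] <- vectorize_edges(unname(m))
      }
    }
  }
  task_connectome_set(edges, meta$subject_ids, meta$task_names, meta$n_nodes)
}

#' Write a phenotype table as CSV
#'
#' Columns: `subject_id`, `group`, `motion_grand_mean`, one `motion.<task>`
#' column per task, then one column per behavioral measure.
#'
#' @param x A [phenotype_table()].
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_phenotypes <- function(x, file) {
  stopifnot(inherits(x, "phenotype_table"))
  df <- data.frame(subject_id = x$subject_ids, group = as.character(x$group),
                   stringsAsFactors = FALSE)
  if (!is.null(x$motion_grand_mean)) df$motion_grand_mean <- x$motion_grand_mean
  if (!is.null(x$motion_per_task)) {
    mt <- x$motion_per_task
    colnames(mt) <- paste0("motion.", colnames(mt))
    df <- cbind(df, as.data.frame(mt, row.names = NULL))
  }
  if (!is.null(x$measures))
    df <- cbind(df, as.data.frame(x$measures, row.names = NULL))
  data.table::fwrite(df, file, sep = ",")
  invisible(file)
}

#' Read a phenotype table CSV written by [write_phenotypes()]
#'
#' @param file CSV path with mandatory header row.
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(file) {
  df <- data.table::fread(file, header = TRUE, sep = ",", data.table = FALSE)
  req <- c("subject_id", "group")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(file, ": missing required columns: ", paste(miss, collapse = ", "))
  ids <- as.character(df$subject_id)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("%s: duplicate subject ID '%s' (line %d)",
                 file, dup[1L], which(duplicated(ids))[1L] + 1L))
  motion_cols <- grep("^motion\\.", names(df), value = TRUE)
  meta_cols <- c(req, "motion_grand_mean", motion_cols)
  measure_cols <- setdiff(names(df), meta_cols)
  phenotype_table(
    ids, df$group,
    if ("motion_grand_mean" %in% names(df)) df$motion_grand_mean,
    if (length(motion_cols)) {
      mt <- as.matrix(df[motion_cols])
      colnames(mt) <- sub("^motion\\.", "", motion_cols)
      mt
    },
    if (length(measure_cols)) as.matrix(df[measure_cols]))
}

#' Write a network map as CSV
#'
#' @param x A [network_map()].
#' @param file Output CSV path with columns `node`, `network`.
#' @return `file`, invisibly.
#' @export
write_network_map <- function(x, file) {
  stopifnot(inherits(x, "network_map"))
  data.table::fwrite(
    data.frame(node = seq_along(x), network = as.character(x)), file, sep = ",")
  invisible(file)
}

#' Read a node-to-network CSV
#'
#' The file must assign every node `1..n_nodes` exactly one label.
#'
#' @param file CSV with columns `node`, `network`.
#' @param levels Allowed label set (default [canonical_networks]).
#' @return A [network_map()].
#' @export
read_network_map <- function(file, levels = canonical_networks) {
  df <- data.table::fread(file, header = TRUE, sep = ",", data.table = FALSE)
  if (!all(c("node", "network") %in% names(df)))
    stop(file, ": expected columns 'node' and 'network'")
  n <- max(df$node)
  if (!setequal(df$node, seq_len(n)) || anyDuplicated(df$node))
    stop(file, ": nodes must cover 1..n exactly once (missing: ",
         paste(setdiff(seq_len(n), df$node), collapse = ", "), ")")
  labels <- df$network[order(df$node)]
  bad <- setdiff(unique(labels), levels)
  if (length(bad))
    stop(sprintf("%s: unknown network label '%s' (line %d)", file, bad[1L],
                 which(df$network == bad[1L])[1L] + 1L))
  network_map(labels, levels)
}
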
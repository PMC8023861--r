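#' Motion quality control
#'
#' Excludes subjects with excessive head motion: grand-mean frame-to-frame
#' displacement strictly greater than `grand_mean_limit` across all tasks, or
#' mean displacement strictly greater than `per_task_limit` on any single
#' task. Comparisons are strict, so a subject sitting exactly at a limit is
#' retained. Subjects with missing motion values are excluded with reason
#' `"missing-motion"` rather than imputed.
#'
#' @param phenotypes A [phenotype_table()] with motion fields populated.
#' @param grand_mean_limit Grand-mean displacement limit in mm (default 0.15).
#' @param per_task_limit Single-task mean displacement limit in mm
#'   (default 0.20).
#' @return A list of class `motion_qc` with `retained` (subject IDs) and
#'   `exclusions` (data frame of subject ID and reason).
#' @export
motion_qc <- function(phenotypes, grand_mean_limit = 0.15,
                      per_task_limit = 0.20) {
  stopifnot(inherits(phenotypes, "phenotype_table"))
  gm <- phenotypes$motion_grand_mean
  pt <- phenotypes$motion_per_task
  if (is.null(gm) && is.null(pt))
    stop("phenotype table has no motion fields")
  ids <- phenotypes$subject_ids
  n <- length(ids)
  reasons <- character(n)
  for (i in seq_len(n)) {
    r <- character(0)
    miss <- (!is.null(gm) && is.na(gm[i])) ||
      (!is.null(pt) && anyNA(pt[i, ]))
    if (miss) {
      r <- "missing-motion"
    } else {
      if (!is.null(gm) && gm[i] > grand_mean_limit) r <- c(r, "grand-mean")
      if (!is.null(pt) && any(pt[i, ] > per_task_limit)) r <- c(r, "per-task")
    }
    reasons[i] <- paste(r, collapse = "+")
  }
  excluded <- reasons != ""
  structure(
    list(retained = ids[!excluded],
         exclusions = data.frame(subject_id = ids[excluded],
                                 reason = reasons[excluded],
                                 stringsAsFactors = FALSE),
         grand_mean_limit = grand_mean_limit,
         per_task_limit = per_task_limit),
    class = "motion_qc")
}

#' @export
print.motion_qc <- function(x, ...) {
  cat(sprintf("motion_qc: %d retained, %d excluded (grand-mean > %.2f mm or per-task > %.2f mm)\n",
              length(x$retained), nrow(x$exclusions),
              x$grand_mean_limit, x$per_task_limit))
  if (nrow(x$exclusions)) print(table(x$exclusions$reason))
  invisible(x)
}
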
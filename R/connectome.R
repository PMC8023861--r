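#' Fisher-z functional connectivity from node time series
#'
#' Computes pairwise Pearson correlation between all node time courses and
#' applies the Fisher z transform `atanh(r)`, with `|r|` clipped at
#' `1 - 1e-7` so perfectly correlated nodes stay finite. The diagonal is set
#' to zero. Zero-variance nodes get all their edges set to 0 and are listed
#' in the `flagged_nodes` attribute (with a warning).
#'
#' @param ts Numeric matrix, frames x nodes (frames >= 3).
#' @return Symmetric nodes x nodes Fisher-z matrix with zero diagonal and an
#'   integer attribute `flagged_nodes`.
#' @export
compute_fc <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("at least 3 frames are required")
  sds <- apply(ts, 2L, stats::sd)
  flagged <- which(sds == 0 | !is.finite(sds))
  if (length(flagged)) {
    warning("zero-variance nodes flagged: ",
            paste(flagged, collapse = ", "))
    # give them unit noise-free placeholder to keep cor() finite; zeroed below
    ts[, flagged] <- seq_len(nrow(ts))
  }
  r <- stats::cor(ts)
  clip <- 1 - 1e-7
  r[r > clip] <- clip
  r[r < -clip] <- -clip
  z <- atanh(r)
  diag(z) <- 0
  if (length(flagged)) {
    z[flagged, ] <- 0
    z[, flagged] <- 0
  }
  attr(z, "flagged_nodes") <- as.integer(flagged)
  z
}

#' General functional connectivity by time-course concatenation
#'
#' Builds a single connectome from several runs/tasks of the same nodes:
#' each series is z-scored per node, the series are concatenated along
#' frames, and [compute_fc()] is applied to the concatenation.
#'
#' @param ts_list List of frames x nodes matrices sharing a node dimension.
#' @return Symmetric Fisher-z matrix, as from [compute_fc()].
#' @export
general_fc <- function(ts_list) {
  if (!is.list(ts_list) || !length(ts_list))
    stop("ts_list must be a non-empty list of time-series matrices")
  ncols <- vapply(ts_list, ncol, integer(1))
  if (length(unique(ncols)) != 1L)
    stop(sprintf("node-count mismatch across series: %s",
                 paste(unique(ncols), collapse = " vs ")))
  standardized <- lapply(ts_list, function(m) {
    m <- as.matrix(m)
    s <- scale(m)
    s[, !is.finite(colSums(s))] <- 0  # zero-variance nodes stay zero
    s
  })
  compute_fc(do.call(rbind, standardized))
}
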
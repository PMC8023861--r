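#' Fit a latent construct score by training-set PCA
#'
#' Z-scores each behavioral measure by its training mean and sd, then takes
#' the first principal component as the construct score. The loading sign is
#' fixed so the sum of loadings is non-negative, so that higher scores mean
#' higher (better) performance when measures are positively scored. Only
#' training rows may ever be passed here; held-out subjects are scored with
#' [apply_latent()] using the stored training statistics, never re-fit.
#'
#' @param measures Numeric matrix (training subjects x measures) with
#'   column names and no missing values; >= 3 subjects.
#' @param n_components Number of components retained (default 1; the score
#'   returned by [apply_latent()] is always the first component, further
#'   components are kept for configuration sweeps).
#' @return An object of class `latent_model`: measure names, per-measure
#'   center/scale, unit-norm loading vector(s), and the explained-variance
#'   fraction of the first component.
#' @export
fit_latent <- function(measures, n_components = 1L) {
  measures <- as.matrix(measures)
  if (is.null(colnames(measures)))
    colnames(measures) <- paste0("m", seq_len(ncol(measures)))
  if (nrow(measures) < 3) stop("at least 3 training subjects are required")
  if (anyNA(measures)) stop("measures contain missing values")
  ctr <- colMeans(measures)
  scl <- apply(measures, 2L, stats::sd)
  zero <- which(scl == 0)
  if (length(zero))
    stop("zero-variance measure: ", paste(colnames(measures)[zero], collapse = ", "))
  z <- sweep(sweep(measures, 2L, ctr), 2L, scl, "/")
  sv <- svd(z)
  loadings <- sv$v[, seq_len(min(n_components, ncol(z))), drop = FALSE]
  # sign convention: sum of loadings >= 0, per component
  for (j in seq_len(ncol(loadings)))
    if (sum(loadings[, j]) < 0) loadings[, j] <- -loadings[, j]
  rownames(loadings) <- colnames(measures)
  ev <- sv$d^2 / sum(sv$d^2)
  structure(
    list(measure_names = colnames(measures), center = ctr, scale = scl,
         loading = loadings[, 1L], loadings = loadings,
         explained_variance = ev[1L]),
    class = "latent_model")
}

#' Score subjects with a fitted latent model
#'
#' Applies the training centering, scaling, and loading to new measures.
#' The model is never re-fit, so no test-subject statistic enters scoring.
#'
#' @param model A `latent_model` from [fit_latent()].
#' @param measures Numeric matrix with (at least) the model's measure
#'   columns, matched by name.
#' @return Numeric construct score per subject (first component).
#' @export
apply_latent <- function(model, measures) {
  stopifnot(inherits(model, "latent_model"))
  measures <- as.matrix(measures)
  if (is.null(colnames(measures)) && ncol(measures) == length(model$measure_names))
    colnames(measures) <- model$measure_names
  miss <- setdiff(model$measure_names, colnames(measures))
  if (length(miss))
    stop("missing measures: ", paste(miss, collapse = ", "))
  m <- measures[, model$measure_names, drop = FALSE]
  if (anyNA(m)) stop("measures contain missing values")
  z <- sweep(sweep(m, 2L, model$center), 2L, model$scale, "/")
  drop(z %*% model$loading)
}

#' @export
predict.latent_model <- function(object, newdata, ...) {
  apply_latent(object, newdata)
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("latent_model: %d measures, first PC explains %.1f%% of variance\n",
              length(x$measure_names), 100 * x$explained_variance))
  print(round(x$loading, 3))
  invisible(x)
}
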
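# Correlation-matrix PCA of occurrence-level environments.
#
# Fitted on standardized columns (zero mean, unit variance), i.e. on the
# correlation matrix; rows with any missing value among the selected
# variables are excluded listwise.  Eigenvector signs are fixed so that
# each loading vector's largest-magnitude entry is positive, removing the
# arbitrary sign flip of eigen decompositions.

pc_score_names <- function() c("climate_PC1", "climate_PC2",
                               "soil_PC1", "soil_PC2")

fix_loading_signs <- function(loadings) {
  for (j in seq_len(ncol(loadings))) {
    k <- which.max(abs(loadings[, j]))
    if (loadings[k, j] < 0) loadings[, j] <- -loadings[, j]
  }
  loadings
}

#' Fit a correlation-matrix PCA
#'
#' @param env_matrix Occurrence-by-variable matrix
#'   ([assemble_env_matrix()]).
#' @param variables Variables (>= 2) to ordinate; rows with a missing value
#'   in any of them are dropped listwise.
#' @return An object of class `pca_model` with elements `variables`,
#'   `center` (per-variable means), `scale` (per-variable standard
#'   deviations), `loadings` (variables x axes, orthonormal columns),
#'   `sdev`, `var_explained` (percentages summing to 100) and `n` (rows
#'   used).
#' @export
fit_pca <- function(env_matrix, variables) {
  stopifnot(length(variables) >= 2)
  missing_cols <- setdiff(variables, names(env_matrix))
  if (length(missing_cols))
    stop("variables absent from matrix: ",
         paste(missing_cols, collapse = ", "))
  x <- as.matrix(env_matrix[, variables, drop = FALSE])
  storage.mode(x) <- "double"
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 2) stop("fewer than 2 complete rows for PCA")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(variables[sds == 0], collapse = ", "))
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  loadings <- fix_loading_signs(unclass(fit$rotation))
  ev <- fit$sdev^2
  structure(list(variables = variables, center = fit$center,
                 scale = fit$scale, loadings = loadings, sdev = fit$sdev,
                 var_explained = 100 * ev / sum(ev), n = nrow(x)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d variables, n = %d; PC1 %.2f%%, PC2 %.2f%%\n",
              length(x$variables), x$n, x$var_explained[1],
              if (length(x$var_explained) > 1) x$var_explained[2] else NA))
  invisible(x)
}

#' Project rows onto fitted PCA axes
#'
#' Scores are the standardized rows times the loadings; rows with a missing
#' value in any model variable yield missing scores.
#'
#' @param model A `pca_model` from [fit_pca()].
#' @param rows Data frame carrying the model's variables.
#' @param axes Number of leading axes to return (default all).
#' @return Numeric matrix of scores (`nrow(rows)` x `axes`).
#' @export
project_pca <- function(model, rows, axes = length(model$variables)) {
  stopifnot(inherits(model, "pca_model"))
  missing_cols <- setdiff(model$variables, names(rows))
  if (length(missing_cols))
    stop("rows lack model variable(s): ",
         paste(missing_cols, collapse = ", "))
  x <- as.matrix(rows[, model$variables, drop = FALSE])
  storage.mode(x) <- "double"
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  scores <- z %*% model$loadings[, seq_len(axes), drop = FALSE]
  scores[!stats::complete.cases(x), ] <- NA_real_
  colnames(scores) <- paste0("PC", seq_len(axes))
  scores
}

#' Append PC scores to the environment matrix as derived variables
#'
#' Adds `<prefix>_PC1` (and `_PC2`, ...) columns so that downstream
#' aggregation (species median, group mean-of-medians) treats ordination
#' axes exactly like measured variables.
#'
#' @param model A `pca_model`.
#' @param env_matrix Occurrence-by-variable matrix.
#' @param prefix `"climate"` or `"soil"`.
#' @param axes Number of axes to append (default 2).
#' @return `env_matrix` with the score columns appended.
#' @export
pc_scores_as_variables <- function(model, env_matrix,
                                   prefix = c("climate", "soil"), axes = 2) {
  prefix <- match.arg(prefix)
  axes <- min(axes, length(model$variables))
  scores <- project_pca(model, env_matrix, axes = axes)
  for (a in seq_len(axes))
    env_matrix[[paste0(prefix, "_PC", a)]] <- scores[, a]
  env_matrix
}

#' Serialize a PCA model to JSON
#'
#' @param model A `pca_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pca_model <- function(model, path) {
  jsonlite::write_json(
    list(variables = model$variables, center = unname(model$center),
         scale = unname(model$scale),
         loadings = unname(as.matrix(model$loadings)),
         var_explained = model$var_explained, n = model$n),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
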
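# PCA of contrast maps and the task-active mask.

#' Derive the task-active mask from full-grid contrast maps
#'
#' Runs a one-sample two-sided t-test of mean contrast against zero at every
#' grid voxel and keeps voxels whose Bonferroni-corrected p-value is below
#' `alpha`, pooling significant activations and deactivations. Zero-variance
#' voxels are excluded with a warning.
#'
#' @param grid_data subjects x grid-voxels matrix (attribute `"grid_shape"` or
#'   argument `grid_shape` gives the 3-D shape).
#' @param alpha familywise significance level.
#' @param grid_shape integer triple; overrides the attribute.
#' @return logical 3-D array of class the grid shape.
#' @export
derive_task_active_mask <- function(grid_data, alpha = 0.05, grid_shape = NULL) {
  if (is.null(grid_shape)) grid_shape <- attr(grid_data, "grid_shape")
  if (is.null(grid_shape)) stop("grid shape unknown; pass 'grid_shape'", call. = FALSE)
  n <- nrow(grid_data)
  if (n < 10) stop("at least 10 subjects are needed for the mask t-test", call. = FALSE)
  v <- ncol(grid_data)
  mu <- colMeans(grid_data)
  s <- sqrt(colSums(sweep(grid_data, 2, mu)^2) / (n - 1))
  zero_var <- s == 0
  if (any(zero_var)) warning(sum(zero_var), " zero-variance voxel(s) excluded from the mask")
  tval <- mu / (s / sqrt(n))
  p <- 2 * pt(-abs(tval), df = n - 1)
  p_fwe <- pmin(p * v, 1)
  sig <- !zero_var & (if (alpha >= 1) rep(TRUE, v) else p_fwe < alpha)
  array(sig, dim = grid_shape)
}

#' Principal-component basis of a contrast stack
#'
#' Singular-value decomposition of the column-mean-centred subject x voxel
#' matrix. Components are ordered by decreasing explained variance, and each
#' component's sign is fixed deterministically so its largest-magnitude
#' loading is positive.
#'
#' @param x a [contrast_stack()] or a subjects x voxels matrix.
#' @param P number of components to retain, `1 <= P <= min(N - 1, V)`.
#' @return object of class `"pca_basis"`: `mean_map` (length V), `components`
#'   (P x V, orthonormal rows), `scores` (N x P, column mean zero),
#'   `explained_variance`, `P`.
#' @export
fit_pca <- function(x, P) {
  data <- if (inherits(x, "contrast_stack")) x$data else as.matrix(x)
  n <- nrow(data); v <- ncol(data)
  p_max <- min(n - 1L, v)
  P <- check_count(P, "P")
  if (P > p_max) stop("'P' must be at most min(N - 1, V) = ", p_max, call. = FALSE)
  mu <- colMeans(data)
  xc <- sweep(data, 2, mu)
  sv <- svd(xc, nu = P, nv = P)
  comps <- t(sv$v)
  flip <- apply(comps, 1, function(r) sign(r[which.max(abs(r))]))
  comps <- comps * flip
  scores <- xc %*% t(comps)
  structure(list(mean_map = mu, components = comps, scores = scores,
                 explained_variance = sv$d[seq_len(P)]^2 / (n - 1),
                 total_variance = sum(xc^2) / (n - 1),
                 P = P, n = n, v = v),
            class = "pca_basis")
}

#' @export
#' @method print pca_basis
print.pca_basis <- function(x, ...) {
  cat(sprintf("PCA basis: %d components over %d voxels (N = %d)\n", x$P, x$v, x$n))
  cat(sprintf("  variance explained: %.1f%%\n",
              100 * sum(x$explained_variance) / x$total_variance))
  invisible(x)
}

# Project new (or resampled) contrast rows onto an existing basis.
project_scores <- function(basis, data) {
  sweep(as.matrix(data), 2, basis$mean_map) %*% t(basis$components)
}
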
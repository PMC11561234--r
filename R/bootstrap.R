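# Bootstrap voxelwise inference on the moderation weight map.

#' Order-statistic indices for a bootstrap percentile confidence interval
#'
#' For B ascending bootstrap replicates and confidence `level`, the lower
#' bound is the `floor((1 - level)/2 * B) + 1`-th value and the upper bound
#' the `ceiling((1 + level)/2 * B)`-th value (1-based). With B = 5000 and a
#' 95% interval this yields the 126th and 4875th order statistics.
#'
#' @param B number of bootstrap replicates.
#' @param level confidence level.
#' @return integer vector `c(lower, upper)` of 1-based indices.
#' @examples
#' ci_indices(5000, 0.95)  # 126, 4875
#' @export
ci_indices <- function(B, level = 0.95) {
  B <- check_count(B, "B", min = 2L)
  level <- check_number(level, "level", 0, 1, strict = TRUE)
  tail <- (1 - level) / 2
  if (B * tail < 1)
    stop("B = ", B, " is too small for a ", level * 100, "% interval ",
         "(need B * (1 - level)/2 >= 1)", call. = FALSE)
  c(lower = as.integer(floor(tail * B)) + 1L,
    upper = as.integer(ceiling((1 - tail) * B)))
}

#' Bootstrap the voxelwise moderation weight map
#'
#' Resamples subjects with replacement `B` times. In each iteration the
#' moderation regression is refit on the resampled subjects using the *fixed*
#' full-sample PCA basis (refitting the basis would permute component order
#' and signs across iterations; set `refit_basis = TRUE` for a sensitivity
#' analysis), and the component moderation coefficients are back-projected to
#' a voxel map. Resamples with a singular design are redrawn, keeping `B`
#' exact; more than 10% redraws is an error.
#'
#' @param stack [contrast_stack()] or subjects x voxels matrix.
#' @param basis full-sample [fit_pca()] basis.
#' @param pl,y,covariates as in [fit_moderation()].
#' @param P number of components.
#' @param B number of bootstrap iterations.
#' @param seed integer seed.
#' @param refit_basis refit the PCA inside each resample (default `FALSE`).
#' @return object of class `"bootstrap_result"`: `W_hat` (B x V matrix of
#'   resampled weight maps), `B`, `seed`, `redraws`.
#' @export
bootstrap_pattern <- function(stack, basis, pl, y, covariates = NULL,
                              P = basis$P, B = 1000, seed = 1,
                              refit_basis = FALSE) {
  data <- if (inherits(stack, "contrast_stack")) stack$data else as.matrix(stack)
  B <- check_count(B, "B", min = 2L)
  n <- nrow(data)
  covariates <- if (!is.null(covariates)) as.data.frame(covariates)
  scores_full <- basis$scores[, seq_len(P), drop = FALSE]
  comps <- basis$components[seq_len(P), , drop = FALSE]

  set.seed(as.integer(seed))
  W <- matrix(NA_real_, B, ncol(data))
  redraws <- 0L
  b <- 1L
  while (b <= B) {
    idx <- sample.int(n, n, replace = TRUE)
    fit <- tryCatch({
      if (refit_basis) {
        bb <- fit_pca(data[idx, , drop = FALSE], P)
        f <- fit_moderation(bb, pl[idx], y[idx],
                            covariates = covariates[idx, , drop = FALSE], P = P)
        drop(crossprod(bb$components, f$b3))
      } else {
        X <- reserve_design(scores_full[idx, , drop = FALSE], pl[idx],
                            covariate_design(covariates[idx, , drop = FALSE])$X)
        f <- ols_qr(X, y[idx], context = "bootstrap resample")
        drop(crossprod(comps, f$coefficients[P + 2 + seq_len(P)]))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) {
      redraws <- redraws + 1L
      if (redraws > 0.1 * B)
        stop("more than 10% of bootstrap resamples had singular designs", call. = FALSE)
      next
    }
    W[b, ] <- fit
    b <- b + 1L
  }
  structure(list(W_hat = W, B = B, seed = seed, redraws = redraws),
            class = "bootstrap_result")
}

#' @export
#' @method print bootstrap_result
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap result: %d iterations x %d voxels (%d redraws)\n",
              x$B, ncol(x$W_hat), x$redraws))
  invisible(x)
}

#' Voxelwise percentile confidence intervals and significance
#'
#' Sorts each voxel's bootstrap replicates ascending and reads the bounds off
#' the [ci_indices()] order statistics. A voxel is significant iff its
#' interval excludes zero.
#'
#' @param W_hat B x V matrix of bootstrap weight maps (or a
#'   `"bootstrap_result"`).
#' @param level confidence level.
#' @return data frame with per-voxel `lower`, `upper`, `significant`.
#' @export
voxel_ci_significance <- function(W_hat, level = 0.95) {
  if (inherits(W_hat, "bootstrap_result")) W_hat <- W_hat$W_hat
  if (any(!is.finite(W_hat))) stop("non-finite bootstrap values", call. = FALSE)
  idx <- ci_indices(nrow(W_hat), level)
  srt <- apply(W_hat, 2, sort)
  lower <- srt[idx[1], ]
  upper <- srt[idx[2], ]
  data.frame(lower = lower, upper = upper,
             significant = lower > 0 | upper < 0)
}
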
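# The multivariate reserve model: cognitive performance regressed on
# principal-component scores of the contrast maps, a quadratic pathology term,
# their interactions (the moderation of interest), and covariates.

# Covariate design: numeric columns mean-centred (centres stored for
# prediction), factors/characters dummy-coded dropping the first level.
covariate_design <- function(covariates, centers = NULL) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0)
    return(list(X = NULL, centers = numeric(0)))
  covariates <- as.data.frame(covariates)
  for (j in names(covariates))
    if (is.character(covariates[[j]]) || is.logical(covariates[[j]]))
      covariates[[j]] <- factor(covariates[[j]])
  mm <- model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  if (is.null(centers)) {
    num <- names(covariates)[vapply(covariates, is.numeric, TRUE)]
    centers <- setNames(rep(0, ncol(mm)), colnames(mm))
    centers[intersect(num, colnames(mm))] <- colMeans(mm[, intersect(num, colnames(mm)), drop = FALSE])
  }
  X <- sweep(mm, 2, centers[colnames(mm)])
  list(X = X, centers = centers)
}

# Full design [1 | PC_1..P | PL^2 | PC_1..P * PL^2 | COV].
reserve_design <- function(scores, pl, cov_X) {
  P <- ncol(scores)
  pl2 <- pl^2
  X <- cbind(1, scores, pl2, scores * pl2)
  nm <- c("(Intercept)", paste0("PC", seq_len(P)), "PL2",
          paste0("PC", seq_len(P), ":PL2"))
  if (!is.null(cov_X)) {
    X <- cbind(X, cov_X)
    nm <- c(nm, colnames(cov_X))
  }
  colnames(X) <- nm
  X
}

ols_qr <- function(X, y, context = "reserve model") {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("singular design in ", context, "; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qx, y)
  fitted <- unname(drop(X %*% coefs))
  res <- y - fitted
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  list(coefficients = coefs, fitted = fitted, residuals = res, df = df,
       sigma2 = sigma2, vcov = sigma2 * xtx_inv, qr = qx)
}

#' Fit the moderation regression on a fixed principal-component basis
#'
#' Ordinary least squares of the (transformed) cognitive outcome on
#' `[1 | PC_1..P | PL^2 | PC_1..P * PL^2 | covariates]`. Pathology enters only
#' through its square, matching its established quadratic relationship with
#' the composite outcome. The `PC:PL2` coefficients are the moderation effects
#' that define the reserve pattern.
#'
#' @param basis a [fit_pca()] basis (or any list with `scores`).
#' @param pl pathological-load scores (length N).
#' @param y outcome vector (already transformed if desired).
#' @param covariates optional data frame of covariates (numeric columns are
#'   mean-centred, factors dummy-coded).
#' @param P number of leading components to use (default: all in the basis).
#' @return list of class `"moderation_ols"`: split coefficients (`b0`, `b1`,
#'   `b2`, `b3`, `c`), full `coefficients`, `vcov`, `fitted`, `residuals`,
#'   `sigma2`, `df`, the design matrix `X` and covariate centres.
#' @export
fit_moderation <- function(basis, pl, y, covariates = NULL, P = NULL) {
  scores <- basis$scores
  if (is.null(P)) P <- ncol(scores)
  P <- check_count(P, "P")
  if (P > ncol(scores)) stop("'P' exceeds the number of basis components", call. = FALSE)
  scores <- scores[, seq_len(P), drop = FALSE]
  if (length(pl) != nrow(scores) || length(y) != nrow(scores))
    stop("pl, y and the basis scores must align on subjects", call. = FALSE)
  cd <- covariate_design(covariates)
  X <- reserve_design(scores, pl, cd$X)
  fit <- ols_qr(X, y)
  cf <- fit$coefficients
  idx_b1 <- 1 + seq_len(P)
  idx_b2 <- P + 2
  idx_b3 <- P + 2 + seq_len(P)
  out <- c(fit, list(
    b0 = cf[1], b1 = cf[idx_b1], b2 = cf[[idx_b2]], b3 = cf[idx_b3],
    c = if (length(cf) > 2 * P + 2) cf[(2 * P + 3):length(cf)] else numeric(0),
    P = P, X = X, cov_centers = cd$centers, y = y
  ))
  class(out) <- "moderation_ols"
  out
}

#' Select the number of principal components by cross-validation
#'
#' K-fold cross-validation over candidate component counts. Within each fold
#' the PCA basis is refit on training subjects only (avoiding leakage);
#' held-out subjects are projected onto that basis and their outcome predicted
#' from the training-fold moderation regression. Held-out performance is
#' `R^2 = 1 - SS_res / SS_tot` with `SS_tot` about the held-out mean.
#'
#' With `rule = "max"` the selected `P` maximizes the mean held-out `R^2`,
#' ties going to the smallest `P`. The default `rule = "1se"` guards against
#' the long noisy plateau this curve typically shows once all informative
#' components are included: it returns the smallest `P` whose mean `R^2` lies
#' within one standard error of the maximum.
#'
#' @inheritParams fit_moderation
#' @param x a [contrast_stack()] or subjects x voxels matrix.
#' @param candidates candidate values of `P` (default `1:min(20, floor(N/10))`).
#' @param n_folds number of folds (default 10).
#' @param seed seed for the fold assignment.
#' @param rule selection rule, `"1se"` (default) or `"max"`.
#' @return list of class `"cv_components"`: `P_star`, `cv_table` (data frame of
#'   candidate `P` and mean/SD held-out `R^2`), `fold_r2` (folds x candidates),
#'   `folds`, `seed`.
#' @export
select_num_components <- function(x, pl, y, covariates = NULL,
                                  candidates = NULL, n_folds = 10, seed = 1,
                                  rule = c("1se", "max")) {
  data <- if (inherits(x, "contrast_stack")) x$data else as.matrix(x)
  n <- nrow(data)
  if (n_folds < 2) stop("'n_folds' must be >= 2", call. = FALSE)
  if (is.null(candidates)) candidates <- seq_len(max(1, min(20L, floor(n / 10))))
  candidates <- sort(unique(as.integer(candidates)))
  p_hi <- max(candidates)
  covariates <- if (!is.null(covariates)) as.data.frame(covariates)

  set.seed(as.integer(seed))
  folds <- sample(rep_len(seq_len(n_folds), n))
  fold_r2 <- matrix(NA_real_, n_folds, length(candidates),
                    dimnames = list(NULL, paste0("P", candidates)))
  max_train_p <- min(table(folds))  # not binding; basis limited by train size
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    p_cap <- min(p_hi, sum(tr) - 1L)
    basis <- fit_pca(data[tr, , drop = FALSE], p_cap)
    te_scores <- project_scores(basis, data[!tr, , drop = FALSE])
    for (ci in seq_along(candidates)) {
      P <- candidates[ci]
      if (P > p_cap) next
      fit <- tryCatch(
        fit_moderation(basis, pl[tr], y[tr],
                       covariates = covariates[tr, , drop = FALSE], P = P),
        error = function(e) NULL)
      if (is.null(fit)) {
        warning("fold ", f, ", P = ", P, ": singular design, fold skipped")
        next
      }
      cd <- covariate_design(covariates[!tr, , drop = FALSE],
                             centers = fit$cov_centers)
      Xte <- reserve_design(te_scores[, seq_len(P), drop = FALSE], pl[!tr], cd$X)
      pred <- drop(Xte %*% fit$coefficients)
      yte <- y[!tr]
      fold_r2[f, ci] <- 1 - sum((yte - pred)^2) / sum((yte - mean(yte))^2)
    }
  }
  mean_r2 <- colMeans(fold_r2, na.rm = TRUE)
  if (all(is.na(mean_r2))) stop("cross-validation failed in every fold", call. = FALSE)
  rule <- match.arg(rule)
  i_max <- which.max(mean_r2)             # first (smallest P) exact tie
  best <- if (rule == "max") candidates[i_max] else {
    # one-standard-error rule: the held-out R^2 typically plateaus once the
    # informative components are in; take the smallest P whose mean R^2 is
    # within one standard error of the maximum
    se_max <- sd(fold_r2[, i_max], na.rm = TRUE) /
      sqrt(sum(is.finite(fold_r2[, i_max])))
    candidates[which(mean_r2 >= mean_r2[i_max] - se_max)[1]]
  }
  structure(list(
    P_star = best, rule = rule,
    cv_table = data.frame(P = candidates, mean_r2 = as.numeric(mean_r2),
                          sd_r2 = apply(fold_r2, 2, sd, na.rm = TRUE)),
    fold_r2 = fold_r2, folds = folds, seed = seed
  ), class = "cv_components")
}

#' @export
#' @method print cv_components
print.cv_components <- function(x, ...) {
  cat(sprintf("Component selection: P* = %d (mean held-out R^2 = %.4f)\n",
              x$P_star, max(x$cv_table$mean_r2, na.rm = TRUE)))
  print(x$cv_table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Back-project component coefficients into voxel space
#'
#' The voxelwise moderation weight map is `w_i = sum_p b3_p V_p_i` and the
#' additive activity map `a_i = sum_p b1_p V_p_i`, where `V_p` are the PCA
#' eigen-images.
#'
#' @param fit a `"moderation_ols"` fit (or any list with `b1`, `b3`).
#' @param basis the [fit_pca()] basis the fit was estimated on.
#' @return list of class `"cr_pattern"` with voxel vectors `w` and `a`.
#' @export
backproject <- function(fit, basis) {
  P <- length(fit$b3)
  if (P > nrow(basis$components))
    stop("fit and basis disagree on the number of components", call. = FALSE)
  comps <- basis$components[seq_len(P), , drop = FALSE]
  structure(list(w = drop(crossprod(comps, fit$b3)),
                 a = drop(crossprod(comps, fit$b1)), P = P),
            class = "cr_pattern")
}

#' Subject-level CR and brain-activity-effect scores
#'
#' `CR_score = sum_i w_i beta_i` aggregates a subject's raw contrast map with
#' the group moderation weights; `BAE = sum_i a_i beta_i` is the analogous
#' additive (non-moderating) activity effect. Both are linear in the contrast
#' map.
#'
#' @param pattern a [backproject()] result.
#' @param stack a [contrast_stack()] sharing the pattern's mask/voxel order.
#' @return data frame: `subject_id`, `cr_score`, `bae`.
#' @export
subject_scores <- function(pattern, stack) {
  data <- if (inherits(stack, "contrast_stack")) stack$data else as.matrix(stack)
  if (ncol(data) != length(pattern$w))
    stop("pattern and stack have different voxel counts", call. = FALSE)
  data.frame(subject_id = rownames(data) %||% sprintf("S%04d", seq_len(nrow(data))),
             cr_score = drop(data %*% pattern$w),
             bae = drop(data %*% pattern$a))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standardized regression coefficients
#'
#' `beta_std_j = b_j * SD(x_j) / SD(y)`: the change in outcome SDs per
#' predictor SD, interaction terms standardized on the product column.
#' Zero-SD columns (e.g. the intercept) are reported as `NA`.
#'
#' @param coefficients named coefficient vector.
#' @param X the design matrix the coefficients were estimated on.
#' @param y the outcome vector.
#' @return named numeric vector of standardized coefficients.
#' @export
standardized_coefficients <- function(coefficients, X, y) {
  sx <- apply(X, 2, sd)
  out <- coefficients * sx / sd(y)
  out[sx == 0] <- NA_real_
  out
}

#' Fit the multivariate reserve model
#'
#' The package's central fitting function. Given subject contrast maps, a
#' pathological-load score and a cognitive outcome, it (optionally Box-Cox
#' transforms the outcome,) selects the number of principal components by
#' cross-validation unless `P` is given, fits the moderation regression
#' `y' = b0 + sum_p b1_p PC_p + (b2 + sum_p b3_p PC_p) PL^2 + c COV + eps`,
#' back-projects the component coefficients into voxelwise moderation (`w`)
#' and additive (`a`) weight maps, and computes per-subject CR and BAE scores.
#'
#' Education must not be supplied as a covariate: it is a reserve proxy used
#' for validation, not a nuisance variable.
#'
#' @param stack a [contrast_stack()] (or subjects x voxels matrix).
#' @param pl pathological-load scores; subjects with missing `pl` or `y` are
#'   dropped (complete-case analysis).
#' @param y cognitive outcome (e.g. PACC5).
#' @param covariates optional covariate data frame (age, sex, TIV, site...).
#' @param P number of components; `NULL` selects by cross-validation.
#' @param candidates,n_folds passed to [select_num_components()].
#' @param lambda,shift if `lambda` is non-`NULL`, `y` is Box-Cox transformed
#'   with [boxcox_transform()] before fitting.
#' @param seed seed for the cross-validation fold assignment.
#' @return object of class `"reserve_fit"`; see [summary.reserve_fit()],
#'   [coef.reserve_fit()], [predict.reserve_fit()].
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 60, grid_shape = c(8, 8, 8),
#'                                      mask_fraction = 0.3, seed = 2))
#' fit <- fit_reserve(cohort$stack, pl = cohort$truth$severity,
#'                    y = cohort$phenotypes$pacc5,
#'                    covariates = cohort$phenotypes[c("age", "sex")], P = 4)
#' fit
#' @export
fit_reserve <- function(stack, pl, y, covariates = NULL, P = NULL,
                        candidates = NULL, n_folds = 10,
                        lambda = NULL, shift = NULL, seed = 1,
                        rule = c("1se", "max")) {
  data <- if (inherits(stack, "contrast_stack")) stack$data else as.matrix(stack)
  subjects <- rownames(data) %||% sprintf("S%04d", seq_len(nrow(data)))
  keep <- is.finite(pl) & is.finite(y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- keep & complete.cases(covariates)
    covariates <- droplevels(covariates[keep, , drop = FALSE])
  }
  data <- data[keep, , drop = FALSE]
  pl <- pl[keep]; subjects <- subjects[keep]
  yt <- y[keep]
  transform <- NULL
  if (!is.null(lambda)) {
    yt <- boxcox_transform(yt, lambda = lambda, shift = shift)
    transform <- list(lambda = attr(yt, "lambda"), shift = attr(yt, "shift"))
    yt <- as.numeric(yt)
  }

  cv <- NULL
  if (is.null(P)) {
    cv <- select_num_components(data, pl, yt, covariates,
                                candidates = candidates, n_folds = n_folds,
                                seed = seed, rule = rule)
    P <- cv$P_star
  }
  basis <- fit_pca(data, P)
  fit <- fit_moderation(basis, pl, yt, covariates, P = P)
  pattern <- backproject(fit, basis)
  scores <- subject_scores(pattern, data)
  scores$subject_id <- subjects

  structure(list(
    coefficients = fit$coefficients, b0 = fit$b0, b1 = fit$b1, b2 = fit$b2,
    b3 = fit$b3, c = fit$c, vcov = fit$vcov, sigma2 = fit$sigma2, df = fit$df,
    fitted.values = fit$fitted, residuals = fit$residuals,
    std_beta = standardized_coefficients(fit$coefficients, fit$X, yt),
    P = P, basis = basis, pattern = pattern, scores = scores,
    cv = cv, transform = transform, y = yt, X = fit$X,
    cov_centers = fit$cov_centers, subjects = subjects, n = length(yt),
    r_squared = 1 - sum(fit$residuals^2) / sum((yt - mean(yt))^2)
  ), class = "reserve_fit")
}

#' @export
#' @method print reserve_fit
print.reserve_fit <- function(x, ...) {
  cat("Multivariate reserve model\n")
  cat(sprintf("  N = %d subjects, P = %d components%s\n", x$n, x$P,
              if (!is.null(x$cv)) " (cross-validated)" else ""))
  if (!is.null(x$cv))
    cat(sprintf("  mean held-out R^2 at P*: %.4f\n",
                x$cv$cv_table$mean_r2[x$cv$cv_table$P == x$P]))
  cat(sprintf("  in-sample R^2 = %.4f\n", x$r_squared))
  cat(sprintf("  pathology main effect b2 = %.4f; ||moderation w|| = %.4f\n",
              x$b2, sqrt(sum(x$pattern$w^2))))
  invisible(x)
}

#' Summarize a reserve-model fit
#'
#' @param object a [fit_reserve()] object.
#' @param ... unused.
#' @return data frame of coefficients with standard errors, t statistics,
#'   p-values, 95% confidence intervals and standardized coefficients,
#'   printed with the model's R^2 and cross-validation table.
#' @export
#' @method summary reserve_fit
summary.reserve_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tval <- object$coefficients / se
  pval <- 2 * pt(-abs(tval), df = object$df)
  crit <- qt(0.975, df = object$df)
  tab <- data.frame(
    term = names(object$coefficients), estimate = object$coefficients,
    std_error = se, t = tval, p = pval,
    ci_lower = object$coefficients - crit * se,
    ci_upper = object$coefficients + crit * se,
    std_beta = object$std_beta, row.names = NULL
  )
  out <- list(coefficients = tab, r_squared = object$r_squared, P = object$P,
              n = object$n, df = object$df, cv = object$cv)
  class(out) <- "summary.reserve_fit"
  out
}

#' @export
#' @method print summary.reserve_fit
print.summary.reserve_fit <- function(x, ...) {
  cat(sprintf("Multivariate reserve model: N = %d, P = %d, R^2 = %.4f\n\n",
              x$n, x$P, x$r_squared))
  print(x$coefficients, digits = 4, row.names = FALSE)
  if (!is.null(x$cv)) { cat("\n"); print(x$cv) }
  invisible(x)
}

#' @export
coef.reserve_fit <- function(object, ...) object$coefficients

#' @export
fitted.reserve_fit <- function(object, ...) object$fitted.values

#' @export
residuals.reserve_fit <- function(object, ...) object$residuals

#' @export
vcov.reserve_fit <- function(object, ...) object$vcov

#' Predict cognitive performance for new subjects
#'
#' Projects new contrast maps onto the fitted PCA basis, rebuilds the
#' moderation design with the training covariate centres, and returns the
#' linear prediction on the (transformed) outcome scale.
#'
#' @param object a [fit_reserve()] object.
#' @param stack new contrasts (matrix or [contrast_stack()], same voxel order).
#' @param pl new pathological-load scores.
#' @param covariates new covariates (same columns as at fit time).
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.reserve_fit <- function(object, stack = NULL, pl = NULL,
                                covariates = NULL, ...) {
  if (is.null(stack)) return(object$fitted.values)
  data <- if (inherits(stack, "contrast_stack")) stack$data else as.matrix(stack)
  scores <- project_scores(object$basis, data)
  cd <- covariate_design(covariates, centers = object$cov_centers)
  X <- reserve_design(scores[, seq_len(object$P), drop = FALSE], pl, cd$X)
  unname(drop(X %*% object$coefficients))
}

#' Simulate outcomes from a fitted reserve model
#'
#' @param object a [fit_reserve()] object.
#' @param nsim number of simulated outcome vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data frame with `nsim` columns of `fitted + N(0, sigma)` draws.
#' @export
simulate.reserve_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(replicate(nsim, object$fitted.values +
                                   rnorm(object$n, 0, sqrt(object$sigma2))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a reserve-model fit
#'
#' Shows the cross-validation curve (mean held-out R^2 against the number of
#' components) when available, and the distribution of voxelwise moderation
#' weights.
#'
#' @param x a [fit_reserve()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.reserve_fit <- function(x, ...) {
  op <- par(mfrow = c(1, if (is.null(x$cv)) 1 else 2))
  on.exit(par(op))
  if (!is.null(x$cv)) {
    plot(x$cv$cv_table$P, x$cv$cv_table$mean_r2, type = "b", pch = 16,
         xlab = "number of components P", ylab = "mean held-out R^2",
         main = "Component selection", ...)
    abline(v = x$P, lty = 2)
  }
  hist(x$pattern$w, breaks = 40, main = "Moderation weights w",
       xlab = "w (per voxel)")
  abline(v = 0, lty = 2)
  invisible(x)
}
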
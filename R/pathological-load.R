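# One-dimensional pathological-load score from the three ATN biomarkers.

#' Standardize an ATN biomarker panel
#'
#' Z-scores the CSF Abeta42:40 ratio, CSF p-tau and TIV-corrected hippocampal
#' volume columns so the three channels enter the embedding on a common scale.
#'
#' @param panels data frame with columns `abeta_ratio`, `ptau` and either
#'   `hv_corrected` or both `hv` and `tiv`.
#' @return N x 3 matrix with columns `abeta_z`, `ptau_z`, `hv_z`, each of mean
#'   0 and SD 1.
#' @export
standardize_panels <- function(panels) {
  need <- c("abeta_ratio", "ptau")
  if (!all(need %in% names(panels)))
    stop("panel must contain columns ", paste(need, collapse = ", "), call. = FALSE)
  hvc <- if ("hv_corrected" %in% names(panels)) panels$hv_corrected
         else if (all(c("hv", "tiv") %in% names(panels))) panels$hv / panels$tiv
         else stop("panel must contain 'hv_corrected' or both 'hv' and 'tiv'",
                   call. = FALSE)
  m <- cbind(abeta_z = panels$abeta_ratio, ptau_z = panels$ptau, hv_z = hvc)
  if (nrow(m) < 3) stop("at least 3 subjects are needed", call. = FALSE)
  s <- apply(m, 2, sd)
  if (any(s == 0))
    stop("zero-variance biomarker column(s): ",
         paste(colnames(m)[s == 0], collapse = ", "), call. = FALSE)
  scale(m)
}

# Exact t-SNE to one dimension via Rtsne; seeded, initialised from the first
# principal component (a deterministic, globally ordered start that avoids
# cluster-interleaving artefacts of random 1-D initialisation), at least 1000
# iterations.
tsne_embed_1d <- function(z, seed, perplexity, max_iter) {
  if (nrow(z) < max(4, 3 * perplexity + 1))
    stop("sample too small for perplexity ", perplexity,
         " (need N >= 3 * perplexity + 1)", call. = FALSE)
  set.seed(seed)
  pc1 <- stats::prcomp(z, center = TRUE, scale. = FALSE)$x[, 1]
  init <- matrix(1e-4 * pc1 / max(stats::sd(pc1), .Machine$double.eps), ncol = 1)
  fit <- Rtsne::Rtsne(z, dims = 1, perplexity = perplexity, theta = 0,
                      max_iter = max_iter, pca = FALSE, check_duplicates = FALSE,
                      Y_init = init)
  drop(fit$Y)
}

#' One-dimensional embedding of the standardized biomarker panel
#'
#' Reduces the N x 3 z-scored ATN matrix to a single coordinate per subject,
#' either by t-SNE (nonlinear; captures a curved severity trajectory) or by
#' the first principal component. The sign and scale of the raw coordinates
#' are arbitrary; [orient_and_rescale()] fixes both.
#'
#' @param z N x 3 matrix from [standardize_panels()].
#' @param method `"tsne"` or `"pca"`.
#' @param seed integer seed (t-SNE only).
#' @param perplexity t-SNE perplexity.
#' @param max_iter t-SNE iterations.
#' @return numeric vector of raw 1-D coordinates with attribute `"method"`.
#' @export
embed_1d <- function(z, method = c("tsne", "pca"), seed = 1, perplexity = 30,
                     max_iter = 1000) {
  method <- match.arg(method)
  z <- as.matrix(z)
  coords <- switch(method,
    pca = {
      p <- stats::prcomp(z, center = TRUE, scale. = FALSE)
      drop(p$x[, 1])
    },
    tsne = tsne_embed_1d(z, seed = seed, perplexity = perplexity,
                         max_iter = max_iter)
  )
  attr(coords, "method") <- method
  attr(coords, "seed") <- seed
  coords
}

#' Orient and rescale 1-D coordinates into a pathological-load score
#'
#' A 1-D embedding's sign is arbitrary; the score is oriented so that it
#' increases with CSF p-tau (rising with pathology), falling back to
#' decreasing with the Abeta ratio if the p-tau correlation is exactly zero,
#' and then min-max rescaled so the least affected subject scores 0 and the
#' most affected scores 1.
#'
#' @param coords raw 1-D coordinates.
#' @param ptau_z z-scored p-tau (orientation anchor).
#' @param abeta_z z-scored Abeta ratio (fallback anchor).
#' @return numeric vector in \[0, 1\] with attribute `"flipped"`.
#' @export
orient_and_rescale <- function(coords, ptau_z, abeta_z = NULL) {
  if (length(unique(coords)) == 1)
    stop("embedding coordinates are constant; orientation is undefined", call. = FALSE)
  s <- cor(coords, ptau_z, method = "spearman")
  if (s == 0 && !is.null(abeta_z)) s <- cor(coords, -abeta_z, method = "spearman")
  if (is.na(s) || s == 0)
    stop("cannot orient the embedding: zero rank correlation with both anchors",
         call. = FALSE)
  flipped <- s < 0
  if (flipped) coords <- -coords
  out <- rescale01(as.numeric(coords), "embedding coordinates")
  attr(out, "flipped") <- flipped
  out
}

#' Pathological-load score from an ATN biomarker panel
#'
#' End-to-end construction of the 1-D pathological-load (PL) score:
#' standardize the three biomarkers, embed to one dimension (t-SNE by default,
#' PCA as the linear alternative), orient by p-tau and rescale to \[0, 1\].
#'
#' For out-of-sample subjects the PCA method scores exactly through the fitted
#' rotation; the t-SNE method, being non-parametric, scores new subjects by
#' the score of their nearest neighbour in biomarker z-space (a documented
#' limitation).
#'
#' @inheritParams embed_1d
#' @param panels biomarker data frame (see [standardize_panels()]).
#' @return object of class `"pl_score"`: `score` (in \[0,1\]), `method`,
#'   `seed`, `perplexity`, the standardized matrix `z` and rescaling metadata.
#' @examples
#' bm <- simulate_biomarkers(runif(120), noise = 0.1, seed = 3)
#' pl <- pathological_load(bm, method = "pca")
#' range(pl$score)
#' @export
pathological_load <- function(panels, method = c("tsne", "pca"), seed = 1,
                              perplexity = 30, max_iter = 1000) {
  method <- match.arg(method)
  z <- standardize_panels(panels)
  coords <- embed_1d(z, method = method, seed = seed, perplexity = perplexity,
                     max_iter = max_iter)
  score <- orient_and_rescale(as.numeric(coords), z[, "ptau_z"], z[, "abeta_z"])
  structure(list(score = as.numeric(score), method = method, seed = seed,
                 perplexity = if (method == "tsne") perplexity else NA,
                 flipped = attr(score, "flipped"), z = z,
                 coords = as.numeric(coords)),
            class = "pl_score")
}

#' @export
#' @method print pl_score
print.pl_score <- function(x, ...) {
  cat(sprintf("Pathological-load score (%s): %d subjects, range [%.3f, %.3f]\n",
              x$method, length(x$score), min(x$score), max(x$score)))
  invisible(x)
}

#' Score new subjects on a fitted pathological-load embedding
#'
#' @param object a `"pl_score"` fit.
#' @param newdata biomarker data frame for the new subjects.
#' @param ... unused.
#' @return numeric PL scores (possibly outside \[0,1\] for the PCA method if a
#'   new subject lies beyond the fitting sample's range).
#' @export
predict.pl_score <- function(object, newdata, ...) {
  ctr <- attr(object$z, "scaled:center")
  scl <- attr(object$z, "scaled:scale")
  hvc <- if ("hv_corrected" %in% names(newdata)) newdata$hv_corrected
         else newdata$hv / newdata$tiv
  zn <- sweep(sweep(cbind(newdata$abeta_ratio, newdata$ptau, hvc), 2, ctr), 2, scl, "/")
  if (object$method == "pca") {
    p <- stats::prcomp(object$z, center = TRUE, scale. = FALSE)
    coords <- drop(zn %*% p$rotation[, 1])
    if (object$flipped) coords <- -coords
    r <- range(if (object$flipped) -object$coords else object$coords)
    (coords - r[1]) / (r[2] - r[1])
  } else {
    # nearest neighbour in z-space
    apply(zn, 1, function(row) {
      d2 <- colSums((t(object$z) - row)^2)
      object$score[which.min(d2)]
    })
  }
}

#' Hippocampal-atrophy score
#'
#' The fallback pathology measure for subjects without CSF data: TIV-corrected
#' hippocampal volume multiplied by -1 and min-max rescaled to \[0, 1\], so the
#' subject with the smallest corrected volume scores 1.
#'
#' @param panels data frame with `hv_corrected` or both `hv` and `tiv`.
#' @return numeric vector in \[0, 1\].
#' @export
atrophy_score <- function(panels) {
  hvc <- if ("hv_corrected" %in% names(panels)) panels$hv_corrected
         else if (all(c("hv", "tiv") %in% names(panels))) panels$hv / panels$tiv
         else stop("panel must contain 'hv_corrected' or both 'hv' and 'tiv'",
                   call. = FALSE)
  if (any(hvc <= 0)) stop("volumes must be positive", call. = FALSE)
  rescale01(-hvc, "TIV-corrected hippocampal volumes")
}
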
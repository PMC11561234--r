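# Composite cognition scoring and the outcome transformation.

#' Compose the PACC5 score from its five subitems
#'
#' Each subitem is z-transformed with the mean and standard deviation of the
#' cognitively unimpaired subsample; the composite is the mean of the five
#' z-scores. Subjects with any missing subitem receive a missing composite.
#'
#' @param subitems N x 5 numeric matrix (or data frame) of raw subitem scores.
#' @param unimpaired logical vector of length N marking the cognitively
#'   unimpaired reference subsample.
#' @return numeric vector of PACC5 scores with attributes `"center"` and
#'   `"scale"` (the reference means/SDs used).
#' @export
compose_pacc5 <- function(subitems, unimpaired) {
  subitems <- as.matrix(subitems)
  if (ncol(subitems) != 5) stop("'subitems' must have 5 columns", call. = FALSE)
  if (length(unimpaired) != nrow(subitems))
    stop("'unimpaired' must have one flag per subject", call. = FALSE)
  if (!any(unimpaired)) stop("the unimpaired reference sample is empty", call. = FALSE)
  ref <- subitems[unimpaired, , drop = FALSE]
  ctr <- colMeans(ref, na.rm = TRUE)
  scl <- apply(ref, 2, sd, na.rm = TRUE)
  if (any(!is.finite(scl)) || any(scl == 0))
    stop("a subitem has zero variance in the unimpaired sample", call. = FALSE)
  z <- sweep(sweep(subitems, 2, ctr), 2, scl, "/")
  out <- rowMeans(z)                       # NA if any subitem missing
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Box-Cox transformation of the cognitive outcome
#'
#' `y' = ((y + shift)^lambda - 1) / lambda` for `lambda != 0` and
#' `log(y + shift)` for `lambda = 0`; strictly increasing in `y`. The default
#' shift policy makes the smallest shifted value exactly 1, accommodating the
#' negative composite scores of impaired subjects.
#'
#' @param y numeric outcome vector.
#' @param lambda transformation exponent (default 2.8).
#' @param shift added to `y` before transforming; if `NULL`, `1 - min(y)`.
#' @return transformed vector with attributes `"lambda"` and `"shift"`.
#' @export
boxcox_transform <- function(y, lambda = 2.8, shift = NULL) {
  if (is.null(shift)) shift <- 1 - min(y, na.rm = TRUE)
  z <- y + shift
  if (any(z <= 0, na.rm = TRUE))
    stop("y + shift must be positive for the Box-Cox transform", call. = FALSE)
  out <- if (lambda == 0) log(z) else (z^lambda - 1) / lambda
  attr(out, "lambda") <- lambda
  attr(out, "shift") <- shift
  out
}
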
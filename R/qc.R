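# Behavioural/motion quality control and the parametric modulator.

#' Arcsine parametric modulator for recognition-confidence ratings
#'
#' Maps a 5-point confidence rating x to `asin((x - 3) / 2) * 2 / pi`,
#' the parametric subsequent-memory modulator: odd-symmetric about the neutral
#' rating 3, bounded in \[-1, 1\], and putting more weight on definitely
#' forgotten (1) or remembered (5) items than on uncertain ones.
#'
#' @param x integer ratings in `{1, ..., 5}` (vectorised).
#' @return numeric vector in \[-1, 1\].
#' @examples
#' arcsine_modulator(1:5)
#' @export
arcsine_modulator <- function(x) {
  if (any(!x %in% 1:5)) stop("ratings must lie in {1, ..., 5}", call. = FALSE)
  asin((x - 3) / 2) * 2 / pi
}

#' Framewise displacement from rigid-body motion parameters
#'
#' FD at frame t is the mean absolute difference of the six motion parameters
#' between frames t and t-1, with the three rotations (radians) converted to
#' arc length on a sphere of radius `rot_radius_mm` before differencing.
#'
#' @param motion T x 6 matrix: columns 1-3 translations (mm), 4-6 rotations
#'   (radians).
#' @param rot_radius_mm sphere radius for the rotation-to-mm conversion.
#' @return numeric vector of length T - 1.
#' @export
framewise_displacement <- function(motion, rot_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2 || ncol(motion) != 6)
    stop("'motion' must be a T x 6 matrix with T >= 2", call. = FALSE)
  if (any(!is.finite(motion))) stop("non-finite motion parameters", call. = FALSE)
  motion[, 4:6] <- motion[, 4:6] * rot_radius_mm
  rowMeans(abs(diff(motion)))
}

#' Response bias of a confidence-rating vector
#'
#' Defined as the mean rating minus the scale midpoint 3, so that a subject
#' answering "sure new" throughout has bias -2 and "sure old" throughout +2.
#'
#' @param ratings integer ratings in `{1, ..., 5}`.
#' @return scalar bias.
#' @export
response_bias <- function(ratings) {
  if (any(!ratings %in% 1:5)) stop("ratings must lie in {1, ..., 5}", call. = FALSE)
  mean(ratings) - 3
}

#' Quartile-based outlier bounds
#'
#' Returns `(Q1 - k * IQR, Q3 + k * IQR)` using the linear-interpolation
#' quantile convention (`stats::quantile` type 7). Used per voxel for the
#' extreme-voxel exclusion rule and, with `k = 3`, for the CR-score outlier
#' filter.
#'
#' @param values numeric vector (at least 4 values).
#' @param k IQR multiplier.
#' @return named numeric vector `c(lower, upper)`.
#' @export
iqr_bounds <- function(values, k = 3) {
  values <- values[is.finite(values)]
  if (length(values) < 4) stop("at least 4 values are needed for quartiles", call. = FALSE)
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
}

#' Per-subject fraction of extreme voxels
#'
#' For each voxel, bounds are `Q1 - 3 IQR` and `Q3 + 3 IQR` across subjects;
#' a subject's fraction is the share of their masked voxels outside these
#' bounds. Voxels with zero IQR never flag.
#'
#' @param beta subjects x voxels matrix of contrast values (masked).
#' @param k IQR multiplier.
#' @return numeric vector, one fraction per subject.
#' @export
voxel_outlier_fraction <- function(beta, k = 3) {
  beta <- as.matrix(beta)
  if (nrow(beta) < 4) stop("at least 4 subjects are needed for voxelwise quartiles",
                           call. = FALSE)
  q <- apply(beta, 2, quantile, probs = c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2, ] - q[1, ]
  lo <- q[1, ] - k * iqr
  hi <- q[2, ] + k * iqr
  out <- sweep(beta, 2, lo, "<") | sweep(beta, 2, hi, ">")
  out[, iqr == 0] <- FALSE
  rowMeans(out)
}

#' Apply the behavioural/motion/voxel exclusion rules
#'
#' A subject is excluded iff any rule statistic strictly exceeds its threshold:
#' R1 indoor/outdoor errors > 8; R2 absolute response bias > 1.5; R3 framewise
#' displacement > 0.5 mm in any single EPI or > 0.2 mm in more than 2% of
#' EPIs; R4 extreme outliers (beyond Q1 - 3 IQR or Q3 + 3 IQR across subjects)
#' in more than 10% of masked voxels. Subjects with missing inputs are flagged
#' unevaluable rather than silently kept.
#'
#' @param io_errors integer error counts, one per subject.
#' @param ratings subjects x items rating matrix.
#' @param motion list of T x 6 motion matrices.
#' @param beta subjects x voxels contrast matrix (masked), or `NULL` to skip R4.
#' @param subject_id optional ids.
#' @param rot_radius_mm passed to [framewise_displacement()].
#' @return data frame of class `"exclusion_report"`: per subject the rule
#'   statistics (`io_errors`, `bias`, `max_fd`, `pct_high_fd`,
#'   `extreme_voxel_fraction`), logical columns `R1_errors` ... `R4_voxel_outliers`,
#'   `unevaluable` and `kept`.
#' @export
apply_exclusion_rules <- function(io_errors, ratings, motion, beta = NULL,
                                  subject_id = NULL, rot_radius_mm = 50) {
  n <- length(io_errors)
  if (is.null(subject_id)) subject_id <- sprintf("S%04d", seq_len(n))
  bias <- apply(as.matrix(ratings), 1, function(r)
    if (any(is.na(r))) NA_real_ else response_bias(r))
  fd_stats <- t(vapply(motion, function(m) {
    if (is.null(m) || any(!is.finite(m))) return(c(NA_real_, NA_real_))
    fd <- framewise_displacement(m, rot_radius_mm)
    c(max(fd), mean(fd > 0.2))
  }, numeric(2)))
  evf <- if (is.null(beta)) rep(0, n) else voxel_outlier_fraction(beta)

  r1 <- io_errors > 8
  r2 <- abs(bias) > 1.5
  r3 <- fd_stats[, 1] > 0.5 | fd_stats[, 2] > 0.02
  r4 <- evf > 0.10
  unevaluable <- is.na(r1) | is.na(r2) | is.na(r3) | is.na(r4)
  kept <- !unevaluable & !(r1 | r2 | r3 | r4)

  out <- data.frame(subject_id = subject_id, io_errors = io_errors, bias = bias,
                    max_fd = fd_stats[, 1], pct_high_fd = fd_stats[, 2],
                    extreme_voxel_fraction = evf,
                    R1_errors = r1, R2_bias = r2, R3_motion = r3,
                    R4_voxel_outliers = r4,
                    unevaluable = unevaluable, kept = kept,
                    stringsAsFactors = FALSE)
  class(out) <- c("exclusion_report", "data.frame")
  out
}

#' @export
#' @method print exclusion_report
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Exclusion report: %d of %d subjects kept (%d unevaluable)\n",
              sum(x$kept, na.rm = TRUE), nrow(x), sum(x$unevaluable)))
  trig <- colSums(x[c("R1_errors", "R2_bias", "R3_motion", "R4_voxel_outliers")],
                  na.rm = TRUE)
  cat("  triggered:", paste(names(trig), trig, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
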
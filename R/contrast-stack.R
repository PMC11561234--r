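#' Contrast stack: subject-by-voxel matrix on a shared 3-D grid
#'
#' Container for per-subject contrast values restricted to a task-active mask.
#' Rows follow the lexicographic order of subject ids so that every stage of
#' the pipeline aligns subjects identically.
#'
#' @param data numeric matrix, subjects x voxels. Columns must correspond to
#'   the `TRUE` voxels of `mask` in R's array (column-major) order.
#' @param mask logical 3-D array marking the task-active voxels.
#' @param subjects character vector of subject ids (defaults to rownames).
#' @param voxel_mm isotropic voxel size in mm.
#' @param affine optional 4 x 4 voxel-to-mm affine; defaults to a scaled
#'   identity with the first voxel at the origin.
#' @return an object of class `"contrast_stack"` with elements `data`, `mask`,
#'   `subjects`, `dim`, `voxel_mm`, `affine`.
#' @export
contrast_stack <- function(data, mask, subjects = rownames(data),
                           voxel_mm = 3.5, affine = NULL) {
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    stop("'mask' must be a logical 3-D array", call. = FALSE)
  v <- sum(mask)
  if (v == 0L) stop("mask contains no voxels", call. = FALSE)
  data <- as.matrix(data)
  if (ncol(data) != v)
    stop("ncol(data) [", ncol(data), "] does not match mask voxel count [", v, "]",
         call. = FALSE)
  if (any(!is.finite(data)))
    stop("contrast data contain non-finite values inside the mask", call. = FALSE)
  if (is.null(subjects)) subjects <- sprintf("S%04d", seq_len(nrow(data)))
  ord <- order(subjects)
  data <- data[ord, , drop = FALSE]
  subjects <- subjects[ord]
  rownames(data) <- subjects
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_mm, 3), 1))
  }
  structure(list(data = data, mask = mask, subjects = subjects,
                 dim = dim(mask), voxel_mm = voxel_mm, affine = affine),
            class = "contrast_stack")
}

#' Mask a full-grid contrast matrix into a contrast stack
#'
#' @param grid_data subjects x grid-voxels matrix (column-major voxel order).
#' @param mask logical 3-D array; `ncol(grid_data)` must equal `prod(dim(mask))`.
#' @inheritParams contrast_stack
#' @return a [contrast_stack()].
#' @export
contrast_stack_from_grid <- function(grid_data, mask, subjects = rownames(grid_data),
                                     voxel_mm = 3.5, affine = NULL) {
  if (ncol(grid_data) != prod(dim(mask)))
    stop("grid data and mask have inconsistent voxel counts", call. = FALSE)
  contrast_stack(grid_data[, as.vector(mask), drop = FALSE], mask,
                 subjects = subjects, voxel_mm = voxel_mm, affine = affine)
}

#' @export
#' @method print contrast_stack
print.contrast_stack <- function(x, ...) {
  cat(sprintf("Contrast stack: %d subjects x %d mask voxels on a %s grid (%.2f mm)\n",
              nrow(x$data), ncol(x$data), paste(x$dim, collapse = "x"), x$voxel_mm))
  invisible(x)
}

# (i, j, k) integer coordinates of the TRUE voxels of a mask, array order.
mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE)
}

# Embed a masked vector back into the full grid (zeros elsewhere).
unmask <- function(values, mask) {
  out <- array(0, dim = dim(mask))
  out[mask] <- values
  out
}
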
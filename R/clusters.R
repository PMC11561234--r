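# Connected-component labelling of significant voxels and cluster descriptives.

# Neighbour offsets for 6/18/26-connectivity in 3-D.
connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6, 18, 26))
    stop("'connectivity' must be 6, 18 or 26", call. = FALSE)
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  off[keep, , drop = FALSE]
}

# Label connected components among `voxels` (linear indices into `grid_shape`)
# by breadth-first search. Returns an integer label per voxel.
label_components <- function(voxels, grid_shape, connectivity = 26) {
  if (length(voxels) == 0) return(integer(0))
  off <- connectivity_offsets(connectivity)
  coords <- arrayInd(voxels, grid_shape)
  in_set <- new.env(hash = TRUE, size = length(voxels))
  for (i in seq_along(voxels)) assign(as.character(voxels[i]), i, envir = in_set)
  labels <- integer(length(voxels))
  lab <- 0L
  mult <- c(1L, grid_shape[1], grid_shape[1] * grid_shape[2])
  for (i in seq_along(voxels)) {
    if (labels[i] > 0L) next
    lab <- lab + 1L
    queue <- i
    labels[i] <- lab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      cc <- coords[cur, ]
      nb <- sweep(off, 2, cc, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= grid_shape[1] &
            nb[, 2] >= 1 & nb[, 2] <= grid_shape[2] &
            nb[, 3] >= 1 & nb[, 3] <= grid_shape[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- (nb[, 1] - 1L) * mult[1] + (nb[, 2] - 1L) * mult[2] +
             (nb[, 3] - 1L) * mult[3] + 1L
      for (l in lin) {
        j <- get0(as.character(l), envir = in_set)
        if (!is.null(j) && labels[j] == 0L) {
          labels[j] <- lab
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

#' Label significant voxels into sign-homogeneous clusters
#'
#' Connected components (default 26-connectivity) of significant voxels,
#' computed separately for positive- and negative-weight voxels so every
#' cluster is sign-homogeneous, with components smaller than `min_size`
#' dropped.
#'
#' @param significant logical vector over mask voxels.
#' @param w voxelwise moderation weights (same order).
#' @param mask logical 3-D array defining the voxel order.
#' @param connectivity 6, 18 or 26.
#' @param min_size minimum cluster size in voxels (default 50).
#' @return integer vector over mask voxels: 0 outside any retained cluster,
#'   otherwise a cluster id (ordered by decreasing size).
#' @export
label_clusters <- function(significant, w, mask, connectivity = 26, min_size = 50) {
  if (length(significant) != sum(mask) || length(w) != sum(mask))
    stop("'significant' and 'w' must have one entry per mask voxel", call. = FALSE)
  grid_shape <- dim(mask)
  mask_lin <- which(as.vector(mask))
  out <- integer(length(significant))
  comps <- list()
  for (sgn in c(1, -1)) {
    sel <- which(significant & sign(w) == sgn)
    if (!length(sel)) next
    labs <- label_components(mask_lin[sel], grid_shape, connectivity)
    for (l in unique(labs)) {
      members <- sel[labs == l]
      if (length(members) >= min_size) comps[[length(comps) + 1L]] <- members
    }
  }
  if (length(comps)) {
    comps <- comps[order(-lengths(comps))]
    for (k in seq_along(comps)) out[comps[[k]]] <- k
  }
  out
}

#' Cluster descriptives for the moderation weight map
#'
#' For every labelled cluster: size, mean weight, peak voxel (maximal
#' `|w|`) in grid and mm coordinates, and the percentage of concordant voxels
#' — voxels whose moderation weight has the same sign as the group-mean
#' subsequent-memory contrast there (zero group-mean voxels count as
#' discordant).
#'
#' @param labels integer cluster labels over mask voxels (from
#'   [label_clusters()]).
#' @param w voxelwise moderation weights.
#' @param group_mean group-level mean contrast over mask voxels.
#' @param mask logical 3-D array.
#' @param affine 4 x 4 voxel-to-mm affine (defaults to `voxel_mm` scaling).
#' @param voxel_mm isotropic voxel size used when `affine` is `NULL`.
#' @return data frame of class `"cluster_table"`: `cluster`, `size`, `mean_w`,
#'   `peak_i/j/k`, `peak_x/y/z_mm`, `pct_concordant`.
#' @export
cluster_stats <- function(labels, w, group_mean, mask, affine = NULL,
                          voxel_mm = 3.5) {
  if (is.null(affine)) affine <- diag(c(rep(voxel_mm, 3), 1))
  ids <- sort(unique(labels[labels > 0]))
  coords <- mask_coords(mask)
  rows <- lapply(ids, function(k) {
    sel <- which(labels == k)
    pk <- sel[which.max(abs(w[sel]))]
    ijk <- coords[pk, ]
    mm <- drop(affine %*% c(ijk - 1, 1))[1:3]
    conc <- sign(w[sel]) == sign(group_mean[sel]) & group_mean[sel] != 0
    data.frame(cluster = k, size = length(sel), mean_w = mean(w[sel]),
               peak_i = ijk[1], peak_j = ijk[2], peak_k = ijk[3],
               peak_x_mm = mm[1], peak_y_mm = mm[2], peak_z_mm = mm[3],
               pct_concordant = 100 * mean(conc))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), size = integer(0), mean_w = numeric(0),
               peak_i = integer(0), peak_j = integer(0), peak_k = integer(0),
               peak_x_mm = numeric(0), peak_y_mm = numeric(0),
               peak_z_mm = numeric(0), pct_concordant = numeric(0))
  class(out) <- c("cluster_table", "data.frame")
  rownames(out) <- NULL
  out
}
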
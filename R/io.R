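# NIfTI and table I/O.

nifti_with_geometry <- function(arr, voxel_mm) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(voxel_mm, 3)
  img
}

#' Read a contrast stack from per-subject NIfTI images
#'
#' Reads one 3-D contrast image per subject plus a binary mask, checks that
#' all images share the mask's grid, and returns the masked subject x voxel
#' matrix with subjects in lexicographic id order. `NaN`s inside the mask are
#' rejected with the offending subject named.
#'
#' @param paths named character vector of NIfTI paths (names = subject ids;
#'   unnamed paths use the file name without extension).
#' @param mask_path path to the mask image (non-zero = inside).
#' @return a [contrast_stack()].
#' @export
read_contrast_stack <- function(paths, mask_path) {
  ids <- names(paths)
  if (is.null(ids)) ids <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  mask_img <- RNifti::readNifti(mask_path)
  mask <- array(as.array(mask_img) != 0, dim = dim(mask_img))
  if (sum(mask) == 0) stop("mask contains no voxels", call. = FALSE)
  vm <- RNifti::pixdim(mask_img)[1]
  rows <- lapply(seq_along(paths), function(i) {
    img <- RNifti::readNifti(paths[i])
    if (!identical(dim(img), dim(mask)))
      stop("image for subject ", ids[i], " has grid ",
           paste(dim(img), collapse = "x"), ", expected ",
           paste(dim(mask), collapse = "x"), call. = FALSE)
    vals <- as.array(img)[mask]
    if (any(!is.finite(vals)))
      stop("non-finite contrast values inside the mask for subject ", ids[i],
           call. = FALSE)
    vals
  })
  data <- do.call(rbind, rows)
  rownames(data) <- ids
  contrast_stack(data, mask, subjects = ids, voxel_mm = vm)
}

#' Write a contrast stack as per-subject NIfTI images
#'
#' @param stack a [contrast_stack()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths (subject images plus `mask.nii.gz`).
#' @export
write_contrast_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mask_path <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(nifti_with_geometry(array(as.integer(stack$mask),
                                               dim = stack$dim),
                                         stack$voxel_mm), mask_path)
  paths <- vapply(seq_along(stack$subjects), function(i) {
    p <- file.path(dir, paste0(stack$subjects[i], ".nii.gz"))
    RNifti::writeNifti(nifti_with_geometry(unmask(stack$data[i, ], stack$mask),
                                           stack$voxel_mm), p)
    p
  }, character(1))
  invisible(c(setNames(paths, stack$subjects), mask = mask_path))
}

#' Write pattern and inference maps as NIfTI
#'
#' Serializes the moderation weight map `w`, the additive map `a` and, when
#' given, the bootstrap CI bounds and significance mask, all embedded in the
#' full grid with zeros outside the mask.
#'
#' @param pattern a [backproject()] result.
#' @param mask logical 3-D array.
#' @param dir output directory.
#' @param ci optional [voxel_ci_significance()] data frame.
#' @param voxel_mm voxel size recorded in the headers.
#' @return invisibly, the written paths.
#' @export
write_pattern_maps <- function(pattern, mask, dir, ci = NULL, voxel_mm = 3.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  maps <- list(w = pattern$w, a = pattern$a)
  if (!is.null(ci)) {
    maps$ci_lower <- ci$lower
    maps$ci_upper <- ci$upper
    maps$significant <- as.numeric(ci$significant)
  }
  paths <- vapply(names(maps), function(nm) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(nifti_with_geometry(unmask(maps[[nm]], mask), voxel_mm), p)
    p
  }, character(1))
  invisible(paths)
}

#' Export a synthetic cohort to plain-text files
#'
#' Writes the phenotype/biomarker table, visit table and behavioural table as
#' CSV, the contrast stack and mask as NIfTI, and the scalar ground truth
#' (planted coefficients, severity, expression, seed) as JSON.
#'
#' @param cohort a [simulate_cohort()] bundle.
#' @param dir output directory.
#' @return invisibly, the output directory.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"), row.names = FALSE)
  write.csv(cohort$visits, file.path(dir, "visits.csv"), row.names = FALSE)
  write.csv(cohort$behavior$behavior, file.path(dir, "behavior.csv"),
            row.names = FALSE)
  write_contrast_stack(cohort$stack, file.path(dir, "contrasts"))
  truth <- cohort$truth
  jsonlite::write_json(
    list(seed = cohort$config$seed, coef = truth$coef,
         severity = truth$severity, expression = truth$expression),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
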
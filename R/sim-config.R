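#' Configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the synthetic-data generator into a validated
#' configuration object. The defaults describe the study conditions the package
#' is designed around: a cohort of older adults along the Alzheimer's continuum
#' (age 69.7 +/- 5.6 years, education 14.6 +/- 2.9 years, ~54% female) scanned
#' with an incidental visual memory-encoding task, with three ATN biomarkers
#' that track a latent disease severity, voxelwise subsequent-memory contrast
#' maps carrying a planted reserve pattern, and annual cognitive follow-ups.
#'
#' @param n_subjects number of subjects.
#' @param grid_shape integer triple, 3-D voxel grid of the contrast maps.
#' @param voxel_mm isotropic voxel edge length in mm.
#' @param mask_fraction fraction of grid voxels inside the task-active mask
#'   (the mask is the set of voxels closest to the grid centre).
#' @param n_latent number K of latent contrast components, the first of which
#'   carries the reserve pattern `w_star`.
#' @param w_star_spec list describing the planted moderation pattern: a data
#'   frame `blobs` with columns `cx, cy, cz` (relative grid coordinates in
#'   \[0,1\]), `sigma` (voxels) and `amplitude` (signed), and a scalar
#'   `truncate` (blob support radius in sigmas; exact zeros beyond it).
#' @param coef_truth named list of planted coefficients: `b0` (intercept), `b2`
#'   (quadratic pathology main effect), `moderation` (pattern-expression x
#'   severity^2 interaction), `age`, `sex`, `tiv` (covariate effects), `site`
#'   (length `n_sites` additive offsets), and longitudinal slope effects `g0`,
#'   `g_atrophy`, `g_threeway`.
#' @param noise_sd named list of noise scales: `biomarker` (multiplier of each
#'   biomarker's noise-free signal SD), `contrast` (per-voxel SD), `cognition`
#'   (outcome SD), `subitem` (per-subitem SD around the composite), `visit`
#'   (per-visit SD), `rand_intercept`, `rand_slope` (longitudinal random-effect
#'   SDs).
#' @param latent_sd loading SDs of the nuisance latent components (recycled to
#'   `n_latent - 1`).
#' @param expression_sd SD of the reserve-pattern expression across subjects.
#' @param edu_corr target correlation between education and pattern expression.
#' @param n_visits number of cognitive assessments per subject (including
#'   baseline).
#' @param visit_interval years between assessments.
#' @param n_epi number of EPI volumes in the simulated motion time series.
#' @param n_items number of rated recognition items per subject.
#' @param n_sites number of acquisition sites.
#' @param qc_fail_fractions named fractions of subjects planted to fail each
#'   exclusion rule (`R1_errors`, `R2_bias`, `R3_motion`, `R4_voxel_outliers`);
#'   must sum to less than 1.
#' @param seed master seed; per-stage streams are derived by fixed offsets.
#'
#' @return an object of class `"cr_sim_config"`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_subjects = 300,
                       grid_shape = c(20L, 20L, 20L),
                       voxel_mm = 3.5,
                       mask_fraction = 0.375,
                       n_latent = 5,
                       w_star_spec = NULL,
                       coef_truth = list(),
                       noise_sd = list(),
                       latent_sd = c(3, 2.2, 1.6, 1.25),
                       expression_sd = 1,
                       edu_corr = 0.3,
                       n_visits = 4,
                       visit_interval = 1,
                       n_epi = 206,
                       n_items = 88,
                       n_sites = 3,
                       qc_fail_fractions = c(R1_errors = 0, R2_bias = 0,
                                             R3_motion = 0, R4_voxel_outliers = 0),
                       seed = 1) {
  n_subjects <- check_count(n_subjects, "n_subjects", min = 4L)
  if (length(grid_shape) != 3L || any(grid_shape < 2) || any(grid_shape != round(grid_shape)))
    stop("'grid_shape' must be a triple of integers >= 2", call. = FALSE)
  grid_shape <- as.integer(grid_shape)
  voxel_mm <- check_number(voxel_mm, "voxel_mm", lower = 0, strict = TRUE)
  mask_fraction <- check_number(mask_fraction, "mask_fraction", 0, 1, strict = TRUE)
  n_latent <- check_count(n_latent, "n_latent")
  if (n_latent > prod(grid_shape) * mask_fraction)
    stop("'n_latent' exceeds the number of mask voxels", call. = FALSE)
  expression_sd <- check_number(expression_sd, "expression_sd", lower = 0)
  edu_corr <- check_number(edu_corr, "edu_corr", -1, 1, strict = TRUE)
  n_visits <- check_count(n_visits, "n_visits", min = 2L)
  visit_interval <- check_number(visit_interval, "visit_interval", lower = 0, strict = TRUE)
  n_epi <- check_count(n_epi, "n_epi", min = 2L)
  n_items <- check_count(n_items, "n_items", min = 5L)
  n_sites <- check_count(n_sites, "n_sites")
  seed <- check_count(seed, "seed", min = 0L)

  rules <- c("R1_errors", "R2_bias", "R3_motion", "R4_voxel_outliers")
  qf <- setNames(rep(0, 4), rules)
  qf[names(qc_fail_fractions)] <- qc_fail_fractions
  if (any(qf < 0) || sum(qf) >= 1)
    stop("'qc_fail_fractions' must be non-negative and sum to < 1", call. = FALSE)

  if (is.null(w_star_spec)) {
    w_star_spec <- list(
      blobs = data.frame(
        cx = c(0.30, 0.70, 0.50),
        cy = c(0.35, 0.35, 0.62),
        cz = c(0.32, 0.32, 0.62),
        sigma = c(2.5, 2.5, 2.5),
        amplitude = c(1, 0.8, -1)  # two temporal-like positives, one precuneus-like negative
      ),
      truncate = 2.5
    )
  }

  ct <- list(b0 = 0, b2 = -1.5, moderation = 1.5,
             age = -0.03, sex = 0.2, tiv = 0,
             site = rep(0, n_sites),
             g0 = -0.05, g_atrophy = -0.6, g_threeway = 0.4)
  ct[names(coef_truth)] <- coef_truth
  if (length(ct$site) != n_sites) ct$site <- rep_len(ct$site, n_sites)

  ns <- list(biomarker = 0.2, contrast = 0.02, cognition = 0.8, subitem = 0.2,
             visit = 0.25, rand_intercept = 0.4, rand_slope = 0.08)
  ns[names(noise_sd)] <- noise_sd
  if (any(unlist(ns) < 0)) stop("noise SDs must be >= 0", call. = FALSE)

  structure(list(
    n_subjects = n_subjects, grid_shape = grid_shape, voxel_mm = voxel_mm,
    mask_fraction = mask_fraction, n_latent = n_latent,
    w_star_spec = w_star_spec, coef_truth = ct, noise_sd = ns,
    latent_sd = rep_len(latent_sd, max(0L, n_latent - 1L)),
    expression_sd = expression_sd,
    edu_corr = edu_corr, n_visits = n_visits, visit_interval = visit_interval,
    n_epi = n_epi, n_items = n_items, n_sites = n_sites,
    qc_fail_fractions = qf, seed = seed
  ), class = "cr_sim_config")
}

#' @export
#' @method print cr_sim_config
print.cr_sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  subjects: %d   grid: %s (%.1f mm voxels), mask fraction %.3f\n",
              x$n_subjects, paste(x$grid_shape, collapse = "x"),
              x$voxel_mm, x$mask_fraction))
  cat(sprintf("  latent components: %d   moderation strength: %.3g   edu_corr: %.2f\n",
              x$n_latent, x$coef_truth$moderation, x$edu_corr))
  cat(sprintf("  visits: %d every %.2g y   sites: %d   seed: %d\n",
              x$n_visits, x$visit_interval, x$n_sites, x$seed))
  invisible(x)
}
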
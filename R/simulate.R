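# Synthetic cohort generator. Every stage draws from a seed derived from the
# master seed by a fixed offset, so any stage can be reproduced in isolation.

# The mask is the mask_fraction * V voxels closest to the grid centre:
# deterministic, connected and roughly ellipsoidal.
centre_mask <- function(grid_shape, fraction) {
  v <- prod(grid_shape)
  n_in <- max(1L, floor(fraction * v))
  ctr <- (grid_shape + 1) / 2
  idx <- arrayInd(seq_len(v), grid_shape)
  d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 + (idx[, 3] - ctr[3])^2
  keep <- order(d2)[seq_len(n_in)]
  mask <- array(FALSE, dim = grid_shape)
  mask[keep] <- TRUE
  mask
}

# Sum of truncated Gaussian blobs evaluated on the full grid. Exact zeros
# beyond `truncate` sigmas, so the planted pattern has a well-defined support.
blob_field <- function(grid_shape, blobs, truncate = 2.5) {
  idx <- arrayInd(seq_len(prod(grid_shape)), grid_shape)
  field <- numeric(prod(grid_shape))
  for (b in seq_len(nrow(blobs))) {
    ctr <- c(blobs$cx[b], blobs$cy[b], blobs$cz[b]) * (grid_shape - 1) + 1
    s <- blobs$sigma[b]
    d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 + (idx[, 3] - ctr[3])^2
    g <- exp(-d2 / (2 * s^2))
    g[d2 > (truncate * s)^2] <- 0
    field <- field + blobs$amplitude[b] * g
  }
  field
}

# Ground truth shared by the contrast, cognition and longitudinal stages.
# expression is sample-centred so that it equals the inner product of w_star
# with the (grand-mean-centred) noise-free contrast map exactly.
make_truth <- function(config, severity) {
  gs <- config$grid_shape
  mask <- centre_mask(gs, config$mask_fraction)
  v_mask <- sum(mask)

  w_full <- blob_field(gs, config$w_star_spec$blobs, config$w_star_spec$truncate)
  w_full[!mask] <- 0
  nrm <- sqrt(sum(w_full^2))
  if (nrm == 0) stop("w_star layout places no blob mass inside the mask", call. = FALSE)
  w_full <- w_full / nrm          # unit norm, so u* = w*/||w*||^2 = w*
  w_masked <- w_full[as.vector(mask)]

  # group-mean subsequent-memory map: broad task activation plus a component
  # aligned with the reserve pattern so cluster concordance is non-trivial
  broad <- blob_field(gs, data.frame(cx = .5, cy = .5, cz = .5, sigma = 6, amplitude = .3),
                      truncate = Inf)
  mean_full <- broad + 0.5 * w_full / max(abs(w_full))
  mean_full[!mask] <- 0

  set.seed(stage_seed(config$seed, "contrasts"))
  n <- config$n_subjects
  k_nuis <- config$n_latent - 1L
  expression <- rnorm(n) * config$expression_sd
  expression <- expression - mean(expression)
  comps <- NULL
  loadings <- NULL
  if (k_nuis > 0) {
    comps <- matrix(rnorm(v_mask * k_nuis), v_mask, k_nuis)
    # orthogonalise nuisance maps against w* and each other, unit norm
    basis <- cbind(w_masked, comps)
    q <- qr.Q(qr(basis))
    comps <- q[, seq_len(k_nuis) + 1L, drop = FALSE]
    loadings <- matrix(rnorm(n * k_nuis), n, k_nuis) *
      rep(config$latent_sd, each = n)
  }

  structure(list(
    severity = severity, expression = expression,
    mask = mask, w_star = w_full, w_star_masked = w_masked,
    mean_map = mean_full, mean_map_masked = mean_full[as.vector(mask)],
    nuisance_components = comps, nuisance_loadings = loadings,
    coef = config$coef_truth, seed = config$seed
  ), class = "cr_truth")
}

#' Simulate ATN biomarker panels from a latent severity
#'
#' Generates CSF Abeta42:40 ratio (strictly decreasing in severity), CSF
#' p-tau181 (increasing) and TIV-corrected hippocampal volume (decreasing),
#' each perturbed by Gaussian noise scaled relative to the noise-free signal's
#' standard deviation.
#'
#' @param severity numeric vector in \[0, 1\], one latent severity per subject.
#' @param tiv total intracranial volumes (mm^3); simulated if `NULL`.
#' @param noise noise SD as a multiple of each channel's signal SD.
#' @param seed integer seed.
#' @return data frame with columns `abeta_ratio`, `ptau`, `hv`, `tiv`,
#'   `hv_corrected`.
#' @export
simulate_biomarkers <- function(severity, tiv = NULL, noise = 0.2, seed = 1) {
  if (any(!is.finite(severity)) || any(severity < 0 | severity > 1))
    stop("'severity' must lie in [0, 1]", call. = FALSE)
  noise <- check_number(noise, "noise", lower = 0)
  n <- length(severity)
  set.seed(stage_seed(seed, "biomarkers"))
  if (is.null(tiv)) tiv <- rnorm(n, 1.45e6, 1.3e5)

  sig_ab <- 0.10 - 0.05 * severity
  sig_pt <- 40 + 60 * severity
  sig_hc <- 0.0050 - 0.0015 * severity
  jit <- function(sig) {
    s <- sd(sig)
    if (noise == 0 || s == 0) sig else sig + rnorm(n, 0, noise * s)
  }
  abeta_ratio <- jit(sig_ab)
  ptau <- jit(sig_pt)
  hv_corrected <- jit(sig_hc)
  data.frame(abeta_ratio = abeta_ratio, ptau = ptau,
             hv = hv_corrected * tiv, tiv = tiv, hv_corrected = hv_corrected)
}

#' Simulate subsequent-memory contrast maps
#'
#' Each subject's full-grid map is the group mean map plus
#' `expression * w_star` (the planted reserve pattern, unit norm), plus
#' nuisance latent components orthogonal to `w_star`, plus i.i.d. voxel noise
#' over the whole grid. Structured signal exists only inside the mask.
#'
#' @param truth ground-truth object produced inside [simulate_cohort()].
#' @param config a [sim_config()].
#' @return subjects x grid-voxels matrix, with the grid shape as attribute
#'   `"grid_shape"`.
#' @export
simulate_contrasts <- function(truth, config) {
  stopifnot(inherits(truth, "cr_truth"), inherits(config, "cr_sim_config"))
  n <- config$n_subjects
  vg <- prod(config$grid_shape)
  mv <- as.vector(truth$mask)

  set.seed((stage_seed(config$seed, "contrasts") + 7L) %% 2147483647L)
  sd_c <- config$noise_sd$contrast
  grid <- if (sd_c > 0) matrix(rnorm(n * vg, 0, sd_c), n, vg) else matrix(0, n, vg)

  signal <- outer(truth$expression, truth$w_star_masked)
  if (!is.null(truth$nuisance_components))
    signal <- signal + truth$nuisance_loadings %*% t(truth$nuisance_components)
  signal <- signal + rep(truth$mean_map_masked, each = n)
  grid[, mv] <- grid[, mv] + signal
  attr(grid, "grid_shape") <- config$grid_shape
  rownames(grid) <- sprintf("S%04d", seq_len(n))
  grid
}

#' Simulate longitudinal cognitive trajectories
#'
#' Annual composite-cognition scores follow
#' `pacc5(t) = baseline + (g0 + g_atrophy * atrophy^2 +
#' g_threeway * expression * atrophy^2) * t` plus a subject random intercept
#' and slope and per-visit noise. Higher pattern expression attenuates the
#' atrophy-dependent decline when `g_threeway > 0`.
#'
#' @param baseline numeric vector of baseline cognition scores.
#' @param atrophy numeric vector in \[0, 1\] (higher = smaller hippocampi).
#' @param expression per-subject reserve-pattern expression.
#' @param config a [sim_config()].
#' @param subject_id optional ids; defaults to `S0001...`.
#' @return long-format data frame: `subject_id`, `visit`, `time_years`, `pacc5`.
#' @export
simulate_longitudinal <- function(baseline, atrophy, expression, config,
                                  subject_id = NULL) {
  stopifnot(inherits(config, "cr_sim_config"))
  if (config$n_visits < 2) stop("at least 2 visits are needed to identify a slope",
                                call. = FALSE)
  n <- length(baseline)
  if (is.null(subject_id)) subject_id <- sprintf("S%04d", seq_len(n))
  ct <- config$coef_truth
  ns <- config$noise_sd
  set.seed(stage_seed(config$seed, "longitudinal"))
  b0i <- if (ns$rand_intercept > 0) rnorm(n, 0, ns$rand_intercept) else numeric(n)
  b1i <- if (ns$rand_slope > 0) rnorm(n, 0, ns$rand_slope) else numeric(n)
  slope <- ct$g0 + ct$g_atrophy * atrophy^2 + ct$g_threeway * expression * atrophy^2

  times <- (seq_len(config$n_visits) - 1) * config$visit_interval
  out <- expand.grid(subject = seq_len(n), visit = seq_len(config$n_visits))
  t_ij <- times[out$visit]
  eps <- if (ns$visit > 0) rnorm(nrow(out), 0, ns$visit) else 0
  pacc5 <- baseline[out$subject] + (slope[out$subject] + b1i[out$subject]) * t_ij +
    b0i[out$subject] + eps
  data.frame(subject_id = subject_id[out$subject], visit = out$visit,
             time_years = t_ij, pacc5 = pacc5)[order(out$subject, out$visit), ]
}

#' Simulate behavioural and motion quality-control data
#'
#' Generates per-subject indoor/outdoor error counts, 5-point recognition
#' confidence ratings and a 6-column rigid-body motion time series
#' (3 translations in mm, 3 rotations in radians). Subjects planted to fail an
#' exclusion rule exceed that rule's threshold by construction; all other
#' subjects are safe on every rule by construction.
#'
#' @param config a [sim_config()].
#' @return list with `behavior` (data frame: `subject_id`, `io_errors`),
#'   `ratings` (subjects x items integer matrix), `motion` (list of T x 6
#'   matrices) and `planted` (named list of planted failure indices per rule).
#' @export
simulate_behavior_motion <- function(config) {
  stopifnot(inherits(config, "cr_sim_config"))
  n <- config$n_subjects
  set.seed(stage_seed(config$seed, "behavior"))

  qf <- config$qc_fail_fractions
  n_fail <- round(qf * n)
  perm <- sample.int(n)
  planted <- list()
  pos <- 0L
  for (r in names(qf)) {
    planted[[r]] <- sort(perm[seq_len(n_fail[[r]]) + pos])
    if (n_fail[[r]] == 0L) planted[[r]] <- integer(0)
    pos <- pos + n_fail[[r]]
  }

  io_errors <- sample(0:8, n, replace = TRUE, prob = stats::dpois(0:8, 2))
  io_errors[planted$R1_errors] <- 9L + rpois(length(planted$R1_errors), 2)

  p_ok <- c(.10, .20, .40, .20, .10)          # symmetric about 3: |bias| ~ 0
  p_biased <- c(.00, .00, .05, .15, .80)      # mean ~ 4.75: |bias| > 1.5
  ratings <- matrix(sample(1:5, n * config$n_items, replace = TRUE, prob = p_ok),
                    n, config$n_items)
  for (i in planted$R2_bias)
    ratings[i, ] <- sample(1:5, config$n_items, replace = TRUE, prob = p_biased)

  t_epi <- config$n_epi
  motion <- vector("list", n)
  for (i in seq_len(n)) {
    m <- cbind(
      apply(matrix(rnorm(t_epi * 3, 0, 0.008), t_epi, 3), 2, cumsum),
      apply(matrix(rnorm(t_epi * 3, 0, 0.00016), t_epi, 3), 2, cumsum)
    )
    if (i %in% planted$R3_motion) {
      t0 <- sample(2:t_epi, 1)
      m[t0:t_epi, 1] <- m[t0:t_epi, 1] + 3.6   # one-step jump: FD = 3.6/6 = 0.6 mm
    }
    motion[[i]] <- m
  }

  list(behavior = data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                             io_errors = io_errors),
       ratings = ratings, motion = motion, planted = planted)
}

#' Simulate a complete synthetic cohort
#'
#' Orchestrates all generator stages into one bundle with known ground truth:
#' latent severity, ATN biomarkers, covariates, education correlated with
#' reserve-pattern expression, full-grid contrast maps carrying the planted
#' moderation pattern, baseline cognition following the moderation model,
#' longitudinal follow-ups, and behavioural/motion QC data with planted
#' exclusion-rule failures.
#'
#' Baseline cognition is generated as
#' `y = b0 + b2 * severity^2 + moderation * expression * severity^2 +
#' covariate effects + noise`, with severity playing the role of the
#' pathological-load score.
#'
#' @param config a [sim_config()].
#' @return an object of class `"cr_cohort"`: `phenotypes` (data frame),
#'   `contrasts` (subjects x grid-voxels matrix), `stack` (masked
#'   [contrast_stack()]), `mask`, `behavior` (see
#'   [simulate_behavior_motion()]), `visits`, `truth`, `config`.
#' @examples
#' cfg <- sim_config(n_subjects = 40, grid_shape = c(8, 8, 8), seed = 7)
#' cohort <- simulate_cohort(cfg)
#' head(cohort$phenotypes)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cr_sim_config"))
  n <- config$n_subjects
  ct <- config$coef_truth
  ns <- config$noise_sd

  set.seed(stage_seed(config$seed, "severity"))
  severity <- runif(n)

  set.seed(stage_seed(config$seed, "covariates"))
  age <- rnorm(n, 69.7, 5.6)
  sex <- rbinom(n, 1, 0.537)                 # 1 = female
  site <- sample.int(config$n_sites, n, replace = TRUE)
  tiv <- rnorm(n, 1.45e6, 1.3e5)

  biomark <- simulate_biomarkers(severity, tiv = tiv, noise = ns$biomarker,
                                 seed = config$seed)
  atrophy <- rescale01(-biomark$hv_corrected, "TIV-corrected hippocampal volumes")

  truth <- make_truth(config, severity)

  set.seed(stage_seed(config$seed, "cognition"))
  lin_pred <- ct$b0 + ct$b2 * severity^2 +
    ct$moderation * truth$expression * severity^2 +
    ct$age * (age - mean(age)) + ct$sex * sex +
    ct$tiv * (tiv - mean(tiv)) / sd(tiv) + ct$site[site]
  y <- lin_pred + (if (ns$cognition > 0) rnorm(n, 0, ns$cognition) else 0)
  subitems <- sapply(1:5, function(k)
    y + (if (ns$subitem > 0) rnorm(n, 0, ns$subitem) else 0))
  colnames(subitems) <- paste0("subitem_", 1:5)

  set.seed(stage_seed(config$seed, "education"))
  rho <- config$edu_corr
  z_expr <- if (sd(truth$expression) > 0) truth$expression / sd(truth$expression) else numeric(n)
  education <- 14.6 + 2.9 * (rho * z_expr + sqrt(1 - rho^2) * rnorm(n))

  behavior <- simulate_behavior_motion(config)

  contrasts <- simulate_contrasts(truth, config)
  r4 <- behavior$planted$R4_voxel_outliers
  if (length(r4)) {
    set.seed((stage_seed(config$seed, "behavior") + 13L) %% 2147483647L)
    mvox <- which(as.vector(truth$mask))
    for (i in r4) {
      bad <- sample(mvox, ceiling(0.15 * length(mvox)))
      contrasts[i, bad] <- contrasts[i, bad] + 50
    }
  }

  visits <- simulate_longitudinal(y, atrophy, truth$expression, config,
                                  subject_id = sprintf("S%04d", seq_len(n)))

  phenotypes <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = age, sex = sex, site = factor(site), tiv = tiv,
    education = education, unimpaired = severity < 0.6,
    pacc5 = y, subitems,
    biomark, atrophy = atrophy, stringsAsFactors = FALSE
  )
  truth$linear_predictor <- lin_pred

  stack <- contrast_stack_from_grid(contrasts, truth$mask,
                                    subjects = phenotypes$subject_id,
                                    voxel_mm = config$voxel_mm)
  structure(list(phenotypes = phenotypes, contrasts = contrasts,
                 stack = stack, mask = truth$mask, behavior = behavior,
                 visits = visits, truth = truth, config = config),
            class = "cr_cohort")
}

#' @export
#' @method print cr_cohort
print.cr_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d mask voxels on a %s grid\n",
              nrow(x$phenotypes), sum(x$mask),
              paste(x$config$grid_shape, collapse = "x")))
  cat(sprintf("  visits: %d per subject; planted QC failures: %s\n",
              x$config$n_visits,
              paste(names(x$behavior$planted),
                    lengths(x$behavior$planted), sep = "=", collapse = ", ")))
  invisible(x)
}
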
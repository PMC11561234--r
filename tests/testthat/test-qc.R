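test_that("arcsine modulator reproduces its closed-form values and symmetry", {
  expect_equal(arcsine_modulator(c(5, 3, 1, 4)), c(1, 0, -1, 1 / 3),
               tolerance = 1e-12)
  expect_equal(arcsine_modulator(1:5), -rev(arcsine_modulator(1:5)))
  expect_true(all(abs(arcsine_modulator(1:5)) <= 1))
  expect_true(all(diff(arcsine_modulator(1:5)) > 0))
  expect_error(arcsine_modulator(0), "ratings")
  expect_error(arcsine_modulator(6), "ratings")
})

test_that("framewise displacement matches hand-computed steps", {
  m <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(m), rep(0, 9))

  m2 <- m; m2[6:10, 1] <- 0.3              # single 0.3 mm translation step
  fd <- framewise_displacement(m2)
  expect_equal(fd[5], 0.3 / 6)
  expect_equal(sum(fd != 0), 1L)

  m3 <- m; m3[4:10, 5] <- 0.002            # rotation step at 50 mm radius
  expect_equal(framewise_displacement(m3, rot_radius_mm = 50)[3], 0.002 * 50 / 6)

  expect_error(framewise_displacement(m[1, , drop = FALSE]), "T x 6")
  m4 <- m; m4[2, 3] <- NA
  expect_error(framewise_displacement(m4), "non-finite")
})

test_that("exclusion thresholds are strict exactly as printed", {
  t_epi <- 101
  mk_motion <- function(steps = numeric(0)) {
    m <- matrix(0, t_epi, 6)
    for (i in seq_along(steps)) m[(10 * i):t_epi, 1] <- m[(10 * i):t_epi, 1] + steps[i]
    m
  }
  ratings_bias <- function(bias, n_items = 88) {
    # half 4s / half 5s gives mean 4.5 (bias 1.5); all 5 gives bias 2
    if (bias == 1.5) rep(c(4, 5), n_items / 2)
    else if (bias == 1.6) c(rep(5, 53), rep(4, 35))  # mean 4.602 -> bias > 1.5
    else rep(3, n_items)
  }
  io <- c(9, 8, 8, 8)
  ratings <- rbind(ratings_bias(0), ratings_bias(1.5), ratings_bias(1.6),
                   ratings_bias(0))
  motion <- list(
    mk_motion(),
    # max FD 0.4, two high-FD frames out of 100 = 2% exactly (not > 2%)
    mk_motion(c(2.4, 1.32)),
    mk_motion(),
    mk_motion()
  )
  rep <- apply_exclusion_rules(io, ratings, motion)
  expect_false(rep$kept[1]); expect_true(rep$R1_errors[1])   # 9 errors > 8
  expect_true(rep$kept[2])                                   # all stats at boundary
  expect_equal(rep$max_fd[2], 0.4)
  expect_equal(rep$pct_high_fd[2], 0.02)
  expect_false(rep$kept[3]); expect_true(rep$R2_bias[3])     # |bias| > 1.5
  expect_true(rep$kept[4])
})

test_that("exclusion is monotone: worsening a statistic never un-excludes", {
  base_io <- 5
  ratings <- matrix(3, 1, 88)
  motion <- list(matrix(0, 20, 6))
  kept_at <- function(io) apply_exclusion_rules(io, ratings, motion)$kept
  kept_path <- vapply(c(0, 4, 8, 9, 12, 30), kept_at, logical(1))
  expect_true(all(diff(as.integer(kept_path)) <= 0))
})

test_that("voxel outlier rule flags the constructed offender and respects the 10% boundary", {
  set.seed(1)
  beta <- matrix(rnorm(30 * 200), 30, 200)
  expect_equal(voxel_outlier_fraction(matrix(1, 10, 50)), rep(0, 10))

  beta2 <- beta
  beta2[7, 1:30] <- 1e3                     # 15% of 200 voxels far outside
  fr <- voxel_outlier_fraction(beta2)
  expect_equal(fr[7], 0.15, tolerance = 0.02)
  expect_true(fr[7] > 0.10)

  # exactly 10% extreme voxels must not trigger the strict rule
  beta3 <- beta
  beta3[7, 1:20] <- 1e3
  rep <- apply_exclusion_rules(rep(0, 30), matrix(3, 30, 4),
                               replicate(30, matrix(0, 5, 6), simplify = FALSE),
                               beta = beta3)
  expect_equal(rep$extreme_voxel_fraction[7], 0.10)
  expect_true(rep$kept[7])
})

test_that("generator round-trip: the excluded set equals the planted failure set", {
  cfg <- sim_config(n_subjects = 120, grid_shape = c(6, 6, 6), n_latent = 2,
                    qc_fail_fractions = c(R1_errors = 0.05, R2_bias = 0.05,
                                          R3_motion = 0.05, R4_voxel_outliers = 0.05),
                    seed = 77)
  co <- simulate_cohort(cfg)
  bm <- co$behavior
  rep <- apply_exclusion_rules(bm$behavior$io_errors, bm$ratings, bm$motion,
                               beta = co$stack$data)
  expect_setequal(which(!rep$kept), unlist(bm$planted))
  for (r in names(bm$planted))
    expect_setequal(which(rep[[r]]), bm$planted[[r]])

  # nothing planted, nobody removed
  co0 <- small_cohort()
  rep0 <- apply_exclusion_rules(co0$behavior$behavior$io_errors, co0$behavior$ratings,
                                co0$behavior$motion, beta = co0$stack$data)
  expect_true(all(rep0$kept))
})

test_that("PACC5 composition z-scores against the unimpaired sample", {
  set.seed(3)
  sub <- matrix(rnorm(40 * 5), 40, 5)
  unimp <- rep(TRUE, 40)
  p <- compose_pacc5(sub, unimp)
  expect_equal(mean(p), 0, tolerance = 1e-12)

  rep5 <- matrix(sub[, 1], 40, 5)
  z1 <- (sub[, 1] - mean(sub[, 1])) / sd(sub[, 1])
  expect_equal(as.numeric(compose_pacc5(rep5, unimp)), z1, tolerance = 1e-12)

  # two-subject toy, hand-computed: ref mean/sd from subject 1 and 2
  toy <- rbind(c(1, 2, 3, 4, 5), c(3, 4, 5, 6, 7))
  ctr <- colMeans(toy); scl <- apply(toy, 2, sd)      # sd = sqrt(2) each
  expect_equal(as.numeric(compose_pacc5(toy, c(TRUE, TRUE))),
               c(mean((toy[1, ] - ctr) / scl), mean((toy[2, ] - ctr) / scl)))

  toy_na <- rbind(c(1, 2, 3, 4, NA), c(3, 4, 5, 6, 7), c(2, 3, 4, 5, 6))
  expect_true(is.na(compose_pacc5(toy_na, c(FALSE, TRUE, TRUE))[1]))
  expect_error(compose_pacc5(matrix(1, 5, 5), rep(TRUE, 5)), "zero variance")
})

test_that("Box-Cox transform has its closed-form special cases and preserves ranks", {
  y <- c(-2, 0, 1, 3)
  expect_equal(as.numeric(boxcox_transform(y, lambda = 1, shift = 5)), y + 5 - 1)
  expect_equal(as.numeric(boxcox_transform(0, lambda = 2.8, shift = 1)), 0)
  expect_equal(as.numeric(boxcox_transform(1, lambda = 2, shift = 1)), 1.5)
  set.seed(4)
  yy <- rnorm(50)
  expect_equal(rank(as.numeric(boxcox_transform(yy, 2.8))), rank(yy))
  expect_equal(rank(as.numeric(boxcox_transform(yy, 0))), rank(yy))
  expect_error(boxcox_transform(c(-3, 1), lambda = 2, shift = 1), "positive")
})

test_that("IQR bounds follow the linear-interpolation quantile convention", {
  b <- iqr_bounds(1:8, k = 3)
  expect_equal(unname(b), c(2.75 - 3 * 3.5, 6.25 + 3 * 3.5))
  b0 <- iqr_bounds(1:8, k = 0)
  expect_equal(unname(b0), c(2.75, 6.25))
  bc <- iqr_bounds(rep(4, 10), k = 3)
  expect_equal(unname(bc), c(4, 4))
  expect_error(iqr_bounds(1:3), "at least 4")
})
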
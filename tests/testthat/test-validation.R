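test_that("OLS moderation reports reproduce lm() on a small fixture", {
  set.seed(1)
  n <- 40
  pl <- runif(n); m <- rnorm(n); yy <- rnorm(n)
  cov <- data.frame(age = rnorm(n))
  rep <- fit_proxy_moderation(yy, pl, m, covariates = cov,
                              include_moderator_main = TRUE,
                              moderator_name = "M")
  ref <- lm(yy ~ m + I(pl^2) + I(m * pl^2) + I(cov$age - mean(cov$age)))
  s <- summary(ref)
  expect_equal(unname(rep$coefficients),
               unname(coef(ref))[c(1, 2, 3, 4, 5)], tolerance = 1e-10)
  expect_equal(unname(rep$table$std_error),
               unname(s$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(rep$r_squared, s$r.squared, tolerance = 1e-12)
  expect_equal(rep$df, df.residual(ref))
})

test_that("quadratic pathology model dominates when the truth is quadratic", {
  set.seed(2)
  n <- 200
  pl <- runif(n)
  y_exact <- 1 - 2 * pl^2
  f <- fit_pl_outcome(pl, y_exact, form = "both")
  expect_equal(f$quadratic$r_squared, 1, tolerance = 1e-10)

  wins <- vapply(1:20, function(s) {
    set.seed(s)
    pl <- runif(400)
    yy <- 1 - 2 * pl^2 + rnorm(400, 0, 0.5)
    f <- fit_pl_outcome(pl, yy)
    f$delta_r2 > 0
  }, logical(1))
  expect_gte(sum(wins), 19)

  # no pathology effect: both forms stay near the covariate-only baseline
  r2s <- vapply(1:20, function(s) {
    set.seed(100 + s)
    pl <- runif(300); yy <- rnorm(300)
    f <- fit_pl_outcome(pl, yy)
    max(f$linear$r_squared, f$quadratic$r_squared)
  }, numeric(1))
  expect_lt(mean(r2s), 0.03)
  expect_error(fit_pl_outcome(rep(0.4, 50), rnorm(50)), "singular")
})

test_that("proxy moderation recovers a planted interaction and has power", {
  set.seed(4)
  n <- 120
  pl <- runif(n); m <- rnorm(n)
  y_exact <- 0.5 + 0.8 * m - 1.2 * pl^2 + 0.9 * m * pl^2
  rep <- fit_proxy_moderation(y_exact, pl, m, include_moderator_main = TRUE,
                              moderator_name = "M")
  est <- rep$table$estimate[rep$table$term == "M:PL2"]
  expect_equal(est, 0.9, tolerance = 1e-10)

  tpos <- vapply(1:20, function(s) {
    set.seed(s)
    pl <- runif(300); m <- rnorm(300)
    yy <- -1.2 * pl^2 + 0.6 * m * pl^2 + rnorm(300, 0, 0.5)
    r <- fit_proxy_moderation(yy, pl, m, moderator_name = "M")
    r$table$t[r$table$term == r$interaction_term] > 0
  }, logical(1))
  expect_gte(sum(tpos), 19)
})

test_that("atrophy variant is the substitution of the pathology term", {
  set.seed(5)
  n <- 100
  path <- runif(n); cr <- rnorm(n); bae <- rnorm(n); yy <- rnorm(n)
  a <- atrophy_variant(yy, path, cr, bae)
  b <- fit_proxy_moderation(yy, path, cr, extra_main = data.frame(BAE = bae),
                            moderator_name = "CR", pathology_name = "Atrophy")
  expect_equal(a$table$estimate, b$table$estimate, tolerance = 1e-12)

  y2 <- 0.2 + 0.5 * bae - 1 * path^2 + 0.7 * cr * path^2
  a2 <- atrophy_variant(y2, path, cr, bae)
  expect_equal(a2$table$estimate[a2$table$term == "CR:Atrophy2"], 0.7,
               tolerance = 1e-10)
})

test_that("CR-education correlation reporting matches cor.test behaviour", {
  x <- 1:30
  r <- correlate_cr_education(x, x)
  expect_equal(r$r, 1)
  expect_identical(r$df, 28L)

  nulls <- vapply(1:20, function(s) {
    set.seed(s)
    abs(correlate_cr_education(rnorm(5000), rnorm(5000))$r)
  }, numeric(1))
  expect_gte(sum(nulls < 0.05), 19)
  expect_error(correlate_cr_education(rep(1, 10), rnorm(10)), "variance")

  co <- simulate_cohort(sim_config(n_subjects = 1000, grid_shape = c(4, 4, 4),
                                   n_latent = 2, seed = 8))
  rt <- correlate_cr_education(co$truth$expression, co$phenotypes$education)
  expect_lt(abs(rt$r - 0.3), 0.08)
})

test_that("degenerate zero-variance longitudinal data fall back to exact OLS", {
  co <- simulate_cohort(small_cfg(noise_sd = zero_noise, seed = 17))
  ph <- co$phenotypes
  scores <- data.frame(subject_id = ph$subject_id, cr_score = co$truth$expression,
                       bae = rnorm(nrow(ph), 0, 0.1), atrophy = ph$atrophy)
  lf <- fit_longitudinal(co$visits, scores, drop_cr_outliers = FALSE)
  ct <- co$config$coef_truth
  get_est <- function(term) lf$fixed$estimate[lf$fixed$term == term]
  expect_equal(get_est("atrophy2:time:cr"), ct$g_threeway, tolerance = 1e-6)
  expect_equal(get_est("atrophy2:time"), ct$g_atrophy, tolerance = 1e-6)
  expect_equal(get_est("time"), ct$g0, tolerance = 1e-6)
})

test_that("mixed model recovers the three-way interaction and prefers random slopes", {
  cover <- 0; lrt_wins <- 0
  for (s in 1:20) {
    co <- simulate_cohort(sim_config(n_subjects = 400, grid_shape = c(4, 4, 4),
                                     n_latent = 2, seed = 300 + s))
    ph <- co$phenotypes
    scores <- data.frame(subject_id = ph$subject_id,
                         cr_score = co$truth$expression,
                         bae = rnorm(nrow(ph), 0, 0.5),
                         atrophy = ph$atrophy, age = ph$age, sex = ph$sex)
    lf <- fit_longitudinal(co$visits, scores, covariate_names = c("age", "sex"),
                           drop_cr_outliers = FALSE)
    row <- lf$fixed[lf$fixed$term == "atrophy2:time:cr", ]
    g <- co$config$coef_truth$g_threeway
    cover <- cover + (row$ci_lower <= g && g <= row$ci_upper)
    # boundary-corrected 5% critical value for 2 extra variance parameters:
    # an equal mixture of chi^2(1) and chi^2(2) -> ~5.14
    if (!is.null(lf$lrt)) lrt_wins <- lrt_wins + (lf$lrt$statistic > 5.14)
  }
  expect_gte(cover, 18)
  expect_gte(lrt_wins, 18)
})

test_that("CR outlier filter removes only upper-tail extremes", {
  set.seed(6)
  cr <- rnorm(100)
  cr[5] <- 50
  keep <- cr_outlier_filter(cr)
  expect_false(keep[5])
  expect_equal(sum(!keep), 1L)
})

test_that("cluster moderation curves behave analytically", {
  set.seed(7)
  n <- 150
  pl <- runif(n); act <- rnorm(n)
  # no activity effect at all (noise-free): the two predicted curves coincide
  y0 <- 1 - 1.5 * pl^2
  mc0 <- cluster_moderation_curves(act, pl, y0)
  expect_equal(mc0$curves$fit[mc0$curves$activity_sd == 1],
               mc0$curves$fit[mc0$curves$activity_sd == -1], tolerance = 1e-8)

  y1 <- 1 - 1.5 * pl^2 + 1.2 * act * pl^2 + rnorm(n, 0, 0.1)
  mc1 <- cluster_moderation_curves(act, pl, y1)
  hi <- mc1$curves[mc1$curves$activity_sd == 1, ]
  lo <- mc1$curves[mc1$curves$activity_sd == -1, ]
  gap_curve <- hi$fit - lo$fit
  expect_gt(gap_curve[nrow(hi)], 0)              # high activity wins at max PL
  expect_gt(gap_curve[nrow(hi)], gap_curve[1])   # and the gap grows with PL^2
  expect_true(all(diff(gap_curve) > -1e-10))

  # at PL = 0 the curves differ only through the activity main effect
  mc2 <- cluster_moderation_curves(act, pl - min(pl), y1)
  cf2 <- mc2$model$coefficients
  first_gap <- mc2$curves$fit[mc2$curves$activity_sd == 1][1] -
    mc2$curves$fit[mc2$curves$activity_sd == -1][1]
  expect_equal(first_gap, 2 * sd(act) * cf2[["activity"]], tolerance = 1e-10)
  expect_error(cluster_moderation_curves(numeric(0), pl, y1), "empty")
})
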
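# Brute-force OLS via the normal equations, the independent oracle used below.
brute_ols <- function(X, y) drop(X %*% solve(crossprod(X), crossprod(X, y)))

test_that("task-active mask keeps real activations and respects the familywise level", {
  set.seed(1)
  n <- 60; shape <- c(5, 5, 4); v <- prod(shape)
  g <- matrix(rnorm(n * v), n, v)
  g[, 1] <- g[, 1] + 10                      # one voxel with mean 10 SD
  m <- derive_task_active_mask(g, alpha = 0.05, grid_shape = shape)
  expect_true(m[1])

  m_all <- derive_task_active_mask(g, alpha = 1, grid_shape = shape)
  expect_true(all(m_all))

  frac <- vapply(1:20, function(s) {
    set.seed(100 + s)
    g0 <- matrix(rnorm(200 * v), 200, v)
    mean(derive_task_active_mask(g0, alpha = 0.05, grid_shape = shape))
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
  expect_error(derive_task_active_mask(g[1:5, ], grid_shape = shape), "10 subjects")
})

test_that("PCA basis is orthonormal, ordered and reconstructs the data", {
  set.seed(2)
  x <- matrix(rnorm(30 * 12), 30, 12)
  b <- fit_pca(x, 12)
  expect_equal(tcrossprod(b$components), diag(12), tolerance = 1e-10)
  expect_true(all(diff(b$explained_variance) <= 1e-12))
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(b$scores %*% b$components, xc, tolerance = 1e-8)

  # rank-1 data: first component recovers the planted direction
  dir <- rnorm(12); dir <- dir / sqrt(sum(dir^2))
  x1 <- outer(rnorm(30), dir)
  b1 <- fit_pca(x1, 1)
  expect_gt(abs(sum(b1$components[1, ] * dir)), 1 - 1e-8)

  expect_error(fit_pca(x, 30), "at most")
  expect_error(fit_pca(x, 0), "P")
})

test_that("moderation fit is exact on noise-free data and spans the voxelwise oracle", {
  co <- zero_noise_cohort()
  ph <- co$phenotypes
  P <- co$config$n_latent
  basis <- fit_pca(co$stack, P)
  fit <- fit_moderation(basis, co$truth$severity, ph$pacc5,
                        ph[covariate_cols], P = P)
  ct <- co$config$coef_truth
  expect_equal(fit$b2, ct$b2, tolerance = 1e-8)
  pat <- backproject(fit, basis)
  expect_equal(pat$w, ct$moderation * co$truth$w_star_masked, tolerance = 1e-8)
  expect_lt(max(abs(fit$residuals)), 1e-8)

  # span equivalence at P = V on a tiny problem: Eq-2 fitted values match
  # brute-force OLS on raw voxel values and their PL^2 interactions
  set.seed(9)
  n <- 60; v <- 6
  beta <- matrix(rnorm(n * v), n, v)
  pl <- runif(n)
  yy <- rnorm(n)
  cov <- data.frame(age = rnorm(n))
  bb <- fit_pca(beta, v)
  f2 <- fit_moderation(bb, pl, yy, cov, P = v)
  Xb <- cbind(1, beta, pl^2, beta * pl^2, cov$age - mean(cov$age))
  expect_equal(f2$fitted, brute_ols(Xb, yy), tolerance = 1e-8)
})

test_that("b3 confidence intervals hold nominal coverage under the null", {
  set.seed(11)
  n <- 300; v <- 20; P <- 3
  hits <- 0; total <- 0
  for (s in 1:200) {
    beta <- matrix(rnorm(n * v), n, v)
    pl <- runif(n)
    yy <- rnorm(n)                          # independent of everything
    f <- fit_moderation(fit_pca(beta, P), pl, yy, P = P)
    se <- sqrt(diag(f$vcov))[P + 2 + seq_len(P)]
    crit <- qt(0.975, df = f$df)
    hits <- hits + sum(abs(f$b3) <= crit * se)
    total <- total + P
  }
  expect_lt(abs(hits / total - 0.95), 0.03)
})

test_that("cross-validation selects enough components and is reproducible", {
  set.seed(21)
  n <- 200; v <- 150
  one_run <- function(s) {
    set.seed(s)
    comps <- qr.Q(qr(matrix(rnorm(v * 3), v, 3)))
    load <- matrix(rnorm(n * 3), n, 3) %*% diag(c(3, 2.5, 2))
    x <- load %*% t(comps) + matrix(rnorm(n * v, 0, 0.1), n, v)
    yy <- rowSums(load) + rnorm(n, 0, 0.3)  # three informative components
    pl <- runif(n)
    select_num_components(x, pl, yy, candidates = 1:8, n_folds = 5, seed = s)
  }
  cv1 <- one_run(1)
  cv1b <- one_run(1)
  expect_identical(cv1$cv_table, cv1b$cv_table)
  expect_identical(cv1$folds, cv1b$folds)

  picks <- vapply(1:20, function(s) one_run(s)$P_star, numeric(1))
  expect_gte(sum(picks >= 3), 18)
  tab <- cv1$cv_table
  expect_true(all(diff(tab$mean_r2[1:3]) > 0))

  single <- select_num_components(matrix(rnorm(40 * 10), 40, 10), runif(40),
                                  rnorm(40), candidates = 4, n_folds = 4, seed = 2)
  expect_identical(single$P_star, 4L)
})

test_that("back-projection is the stated matrix product", {
  set.seed(3)
  basis <- fit_pca(matrix(rnorm(20 * 5), 20, 5), 3)
  f <- list(b3 = c(1, 0, 0), b1 = c(0, 0, 0))
  expect_equal(backproject(f, basis)$w, basis$components[1, ])
  f0 <- list(b3 = c(0, 0, 0), b1 = c(0, 1, 0))
  expect_equal(backproject(f0, basis)$w, rep(0, 5))
  expect_equal(backproject(f0, basis)$a, basis$components[2, ])

  b3 <- c(0.3, -1.2, 0.5)
  fr <- list(b3 = b3, b1 = -b3)
  expect_equal(backproject(fr, basis)$w,
               drop(t(basis$components[1:3, ]) %*% b3), tolerance = 1e-12)
  expect_error(backproject(list(b3 = rep(1, 9), b1 = rep(1, 9)), basis), "components")
})

test_that("subject scores are the stated inner products and are linear", {
  pat <- structure(list(w = c(1, -1), a = c(2, 0)), class = "cr_pattern")
  beta <- rbind(c(2, 3), c(0, 0))
  sc <- subject_scores(pat, beta)
  expect_equal(sc$cr_score, c(-1, 0))
  expect_equal(sc$bae, c(4, 0))

  shifted <- subject_scores(pat, beta + 0.7)
  expect_equal(shifted$cr_score, sc$cr_score + 0.7 * sum(pat$w))
  expect_equal(shifted$bae, sc$bae + 0.7 * sum(pat$a))
})

test_that("standardized coefficients equal the z-scored refit", {
  set.seed(5)
  n <- 50
  x1 <- rnorm(n); x2 <- 10 * rnorm(n); x3 <- rnorm(n)
  yy <- 0.4 * x1 - 0.1 * x2 + rnorm(n)
  X <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2, x3 = x3)
  b <- solve(crossprod(X), crossprod(X, yy))
  sb <- standardized_coefficients(drop(b), X, yy)

  Z <- cbind(1, scale(x1), scale(x2), scale(x3))
  bz <- solve(crossprod(Z), crossprod(Z, drop(scale(yy))))
  expect_equal(unname(sb[2:4]), drop(bz)[2:4], tolerance = 1e-10)
  expect_true(is.na(sb[1]))

  # single predictor: standardized slope is the Pearson correlation
  X1 <- cbind(1, x1)
  b1 <- solve(crossprod(X1), crossprod(X1, yy))
  expect_equal(unname(standardized_coefficients(drop(b1), X1, yy)[2]),
               cor(x1, yy), tolerance = 1e-12)
})

test_that("fitted values and the weight map are invariant to basis rotation", {
  co <- small_cohort()
  ph <- co$phenotypes
  basis <- fit_pca(co$stack, 3)
  fit <- fit_moderation(basis, co$truth$severity, ph$pacc5, ph[covariate_cols], P = 3)
  pat <- backproject(fit, basis)

  set.seed(6)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  rot <- basis
  rot$components <- R %*% basis$components
  rot$scores <- basis$scores %*% t(R)
  fit_r <- fit_moderation(rot, co$truth$severity, ph$pacc5, ph[covariate_cols], P = 3)
  pat_r <- backproject(fit_r, rot)
  expect_equal(fit_r$fitted, fit$fitted, tolerance = 1e-8)
  expect_equal(pat_r$w, pat$w, tolerance = 1e-8)
})

test_that("fit_reserve assembles the full model and its methods are coherent", {
  co <- small_cohort()
  ph <- co$phenotypes
  fit <- fit_reserve(co$stack, co$truth$severity, ph$pacc5,
                     ph[covariate_cols], P = 3)
  expect_s3_class(fit, "reserve_fit")
  expect_equal(fitted(fit) + residuals(fit), fit$y, tolerance = 1e-12)
  expect_equal(predict(fit, co$stack, co$truth$severity, ph[covariate_cols]),
               unname(fitted(fit)), tolerance = 1e-8)
  s <- summary(fit)
  expect_true(all(c("estimate", "ci_lower", "ci_upper", "std_beta") %in%
                    names(s$coefficients)))
  expect_equal(nrow(s$coefficients), length(coef(fit)))
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(dim(sim), c(fit$n, 2L))

  # missing PL drops subjects (complete-case analysis)
  pl_na <- co$truth$severity
  pl_na[1:5] <- NA
  fit2 <- fit_reserve(co$stack, pl_na, ph$pacc5, ph[covariate_cols], P = 3)
  expect_equal(fit2$n, nrow(ph) - 5)

  expect_error(fit_reserve(co$stack, rep(0.5, nrow(ph)), ph$pacc5, P = 3),
               "singular")
})
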
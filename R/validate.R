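# Cross-sectional and longitudinal validation of the pathological-load and
# CR scores.

# Shared OLS coefficient report.
ols_report <- function(X, y, context, level = 0.95) {
  fit <- ols_qr(X, y, context = context)
  se <- sqrt(diag(fit$vcov))
  tval <- fit$coefficients / se
  pval <- 2 * pt(-abs(tval), df = fit$df)
  crit <- qt(1 - (1 - level) / 2, df = fit$df)
  list(table = data.frame(
    term = colnames(X), estimate = fit$coefficients, std_error = se,
    t = tval, p = pval,
    ci_lower = fit$coefficients - crit * se,
    ci_upper = fit$coefficients + crit * se,
    std_beta = standardized_coefficients(fit$coefficients, X, y),
    row.names = NULL),
    r_squared = 1 - sum(fit$residuals^2) / sum((y - mean(y))^2),
    df = fit$df, fitted = fit$fitted, residuals = fit$residuals,
    vcov = fit$vcov, coefficients = fit$coefficients)
}

#' Quadratic versus linear pathology models of cognition
#'
#' Regresses the (transformed) outcome on pathological load entered linearly
#' and, separately, as its square (plus covariates in both), and reports each
#' model's coefficients and `R^2` and the quadratic-minus-linear `Delta R^2`.
#'
#' @param pl pathological-load scores.
#' @param y outcome.
#' @param covariates optional covariate data frame.
#' @param form `"both"` (default), `"linear"` or `"quadratic"`.
#' @return list of class `"pl_outcome_fit"` with elements `linear`,
#'   `quadratic` (coefficient reports) and `delta_r2`.
#' @export
fit_pl_outcome <- function(pl, y, covariates = NULL, form = c("both", "linear", "quadratic")) {
  form <- match.arg(form)
  keep <- is.finite(pl) & is.finite(y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- keep & complete.cases(covariates)
    covariates <- droplevels(covariates[keep, , drop = FALSE])
  }
  pl <- pl[keep]; y <- y[keep]
  cd <- covariate_design(covariates)
  one_form <- function(term, nm) {
    X <- cbind(`(Intercept)` = 1, term, cd$X)
    colnames(X)[2] <- nm
    ols_report(X, y, context = paste(nm, "model"))
  }
  out <- list(linear = NULL, quadratic = NULL, delta_r2 = NA_real_, n = sum(keep))
  if (form != "quadratic") out$linear <- one_form(pl, "PL")
  if (form != "linear") out$quadratic <- one_form(pl^2, "PL2")
  if (form == "both") out$delta_r2 <- out$quadratic$r_squared - out$linear$r_squared
  class(out) <- "pl_outcome_fit"
  out
}

#' @export
#' @method print pl_outcome_fit
print.pl_outcome_fit <- function(x, ...) {
  cat("Pathology -> cognition models (N =", x$n, ")\n")
  if (!is.null(x$linear))
    cat(sprintf("  linear:    R^2 = %.4f\n", x$linear$r_squared))
  if (!is.null(x$quadratic))
    cat(sprintf("  quadratic: R^2 = %.4f\n", x$quadratic$r_squared))
  if (is.finite(x$delta_r2))
    cat(sprintf("  delta R^2 (quadratic - linear) = %.4f\n", x$delta_r2))
  invisible(x)
}

#' Moderation of the pathology effect by a proxy or score
#'
#' Fits `y = b0 + [extra main terms] + [moderator] + b2 * PL^2 +
#' b3 * moderator * PL^2 + c * COV + eps`. For an education analysis the
#' moderator's main effect is included (`include_moderator_main = TRUE`); for
#' the CR-score validation model the moderator enters only through the
#' interaction while the additive brain-activity effect (BAE) is supplied as
#' an extra main term.
#'
#' @param y outcome.
#' @param pl pathology score (entered squared).
#' @param moderator the moderating variable (education, CR score...).
#' @param covariates optional covariate data frame.
#' @param extra_main optional data frame of additional main-effect terms
#'   (e.g. BAE).
#' @param include_moderator_main include the moderator's main effect.
#' @param moderator_name,pathology_name labels used in the report.
#' @return list of class `"moderation_report"`: coefficient `table` (with 95%
#'   CIs, t, p, standardized beta), `r_squared`, `df`, `interaction_term`.
#' @export
fit_proxy_moderation <- function(y, pl, moderator, covariates = NULL,
                                 extra_main = NULL,
                                 include_moderator_main = FALSE,
                                 moderator_name = "M", pathology_name = "PL") {
  keep <- is.finite(y) & is.finite(pl) & is.finite(moderator)
  if (!is.null(extra_main)) {
    extra_main <- as.data.frame(extra_main)
    keep <- keep & complete.cases(extra_main)
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- keep & complete.cases(covariates)
    covariates <- droplevels(covariates[keep, , drop = FALSE])
  }
  y <- y[keep]; pl <- pl[keep]; moderator <- moderator[keep]
  pl2 <- pl^2
  p2name <- paste0(pathology_name, "2")
  iname <- paste0(moderator_name, ":", p2name)
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(extra_main)) {
    em <- as.matrix(extra_main[keep, , drop = FALSE])
    X <- cbind(X, em)
  }
  if (include_moderator_main) {
    X <- cbind(X, moderator)
    colnames(X)[ncol(X)] <- moderator_name
  }
  X <- cbind(X, pl2, moderator * pl2)
  colnames(X)[ncol(X) - 1:0] <- c(p2name, iname)
  cd <- covariate_design(covariates)
  if (!is.null(cd$X)) X <- cbind(X, cd$X)
  rep <- ols_report(X, y, context = "moderation model")
  out <- c(rep, list(interaction_term = iname, n = sum(keep)))
  class(out) <- "moderation_report"
  out
}

#' @export
#' @method print moderation_report
print.moderation_report <- function(x, ...) {
  cat(sprintf("Moderation model: N = %d, R^2 = %.4f\n", x$n, x$r_squared))
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' CR-score moderation with hippocampal atrophy as the pathology measure
#'
#' The validation variant for subjects without CSF data: identical to the
#' CR-score moderation model but with the \[0,1\] atrophy score (squared)
#' replacing pathological load.
#'
#' @param y outcome.
#' @param atrophy [atrophy_score()] values.
#' @param cr,bae subject scores from [subject_scores()].
#' @param covariates optional covariate data frame.
#' @return a `"moderation_report"` (see [fit_proxy_moderation()]).
#' @export
atrophy_variant <- function(y, atrophy, cr, bae, covariates = NULL) {
  fit_proxy_moderation(y, atrophy, cr, covariates = covariates,
                       extra_main = data.frame(BAE = bae),
                       include_moderator_main = FALSE,
                       moderator_name = "CR", pathology_name = "Atrophy")
}

#' Correlation between the CR score and education
#'
#' Pearson correlation with Fisher-z 95% confidence interval, via
#' [stats::cor.test()].
#'
#' @param cr_scores CR scores.
#' @param education years of education.
#' @return list: `r`, `ci` (length 2), `p`, `df`, `n`.
#' @export
correlate_cr_education <- function(cr_scores, education) {
  keep <- is.finite(cr_scores) & is.finite(education)
  if (sum(keep) < 4) stop("at least 4 complete pairs are required", call. = FALSE)
  if (sd(cr_scores[keep]) == 0 || sd(education[keep]) == 0)
    stop("zero variance; correlation undefined", call. = FALSE)
  ct <- cor.test(cr_scores[keep], education[keep])
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
       p = ct$p.value, df = unname(ct$parameter), n = sum(keep))
}

#' Flag CR-score extreme outliers
#'
#' Marks scores above `Q3 + 3 IQR` (the upper-tail extreme-outlier rule
#' applied before all CR-score analyses).
#'
#' @param cr_scores CR scores.
#' @return logical vector: `TRUE` for subjects to keep.
#' @export
cr_outlier_filter <- function(cr_scores) {
  b <- iqr_bounds(cr_scores, k = 3)
  cr_scores <= b["upper"]
}

#' Longitudinal mixed model of cognitive decline
#'
#' Linear mixed-effects model of repeated composite-cognition scores on
#' `atrophy^2 * time * CR` (all main effects, two-way and the three-way
#' interaction), plus BAE and BAE-by-time, plus covariates, with a subject
#' random intercept and slope (unstructured covariance, REML). Satterthwaite
#' degrees of freedom are used for the fixed-effect t-tests. A
#' likelihood-ratio comparison against a random-intercept-only model
#' (both refit by maximum likelihood) is reported. If the full random
#' structure fails to converge the model falls back to a diagonal
#' random-effect covariance, and to ordinary least squares in the degenerate
#' zero-variance case; `convergence` records which model was used.
#'
#' @param visits long data frame: `subject_id`, `time_years`, `pacc5`.
#' @param scores per-subject data frame: `subject_id`, `cr_score`, `bae`,
#'   `atrophy`, plus any covariate columns named in `covariate_names`.
#' @param covariate_names character vector of covariate columns in `scores`.
#' @param drop_cr_outliers apply [cr_outlier_filter()] first (default `TRUE`).
#' @param compare_random run the random-slope likelihood-ratio comparison
#'   (default `TRUE`; skip for speed in simulations).
#' @return list of class `"longitudinal_fit"`: `fixed` (coefficient table with
#'   Satterthwaite df and 95% CIs), `random` (variance components), `lrt`
#'   (model comparison), `convergence`, `n_subjects`, `model` (the fitted
#'   object).
#' @export
fit_longitudinal <- function(visits, scores, covariate_names = character(0),
                             drop_cr_outliers = TRUE, compare_random = TRUE) {
  stopifnot(all(c("subject_id", "time_years", "pacc5") %in% names(visits)),
            all(c("subject_id", "cr_score", "bae", "atrophy") %in% names(scores)))
  if (drop_cr_outliers) scores <- scores[cr_outlier_filter(scores$cr_score), ]
  dat <- merge(visits, scores, by = "subject_id")
  dat <- dat[complete.cases(dat[c("pacc5", "time_years", "cr_score", "bae",
                                  "atrophy", covariate_names)]), ]
  dat$atrophy2 <- dat$atrophy^2
  dat$time <- dat$time_years
  dat$cr <- dat$cr_score
  fixed_rhs <- paste(c("atrophy2 * time * cr", "bae", "bae:time",
                       covariate_names), collapse = " + ")

  fit <- NULL; convergence <- "random intercept + slope (unstructured)"
  quiet_fit <- function(form) {
    withCallingHandlers(
      lmerTest::lmer(stats::as.formula(form), data = dat, REML = TRUE),
      warning = function(w) invokeRestart("muffleWarning"),
      message = function(m) invokeRestart("muffleMessage"))
  }
  fit <- tryCatch(quiet_fit(paste0("pacc5 ~ ", fixed_rhs, " + (1 + time | subject_id)")),
                  error = function(e) NULL)
  if (is.null(fit)) {
    convergence <- "random intercept + slope (diagonal fallback)"
    fit <- tryCatch(quiet_fit(paste0("pacc5 ~ ", fixed_rhs, " + (1 + time || subject_id)")),
                    error = function(e) NULL)
  }

  if (is.null(fit)) {
    # degenerate case (e.g. zero noise and zero random effects): OLS fixed effects
    convergence <- "ols fallback (degenerate variance)"
    mm <- model.matrix(stats::as.formula(paste0("~ ", fixed_rhs)), data = dat)
    rep <- ols_report(mm, dat$pacc5, context = "longitudinal fallback")
    tab <- rep$table
    tab$df <- rep$df
    out <- list(fixed = tab, random = NULL, lrt = NULL,
                convergence = convergence,
                n_subjects = length(unique(dat$subject_id)), model = NULL,
                data = dat)
    class(out) <- "longitudinal_fit"
    return(out)
  }

  cs <- suppressWarnings(suppressMessages(as.data.frame(coef(summary(fit)))))  # lmerTest: Satterthwaite df
  crit <- qt(0.975, df = cs$df)
  fixed <- data.frame(term = rownames(cs), estimate = cs$Estimate,
                      std_error = cs$`Std. Error`, df = cs$df,
                      t = cs$`t value`, p = cs$`Pr(>|t|)`,
                      ci_lower = cs$Estimate - crit * cs$`Std. Error`,
                      ci_upper = cs$Estimate + crit * cs$`Std. Error`,
                      row.names = NULL)

  vc <- as.data.frame(lme4::VarCorr(fit))
  lrt <- if (!compare_random) NULL else tryCatch({
    full_ml <- suppressWarnings(suppressMessages(lme4::refitML(fit)))
    red_ml <- withCallingHandlers(
      lme4::lmer(stats::as.formula(paste0("pacc5 ~ ", fixed_rhs, " + (1 | subject_id)")),
                 data = dat, REML = FALSE),
      warning = function(w) invokeRestart("muffleWarning"),
      message = function(m) invokeRestart("muffleMessage"))
    a <- suppressWarnings(suppressMessages(anova(red_ml, full_ml)))
    list(statistic = a$Chisq[2], df = a$Df[2], p = a$`Pr(>Chisq)`[2])
  }, error = function(e) NULL)

  out <- list(fixed = fixed, random = vc, lrt = lrt, convergence = convergence,
              n_subjects = length(unique(dat$subject_id)), model = fit,
              data = dat)
  class(out) <- "longitudinal_fit"
  out
}

#' @export
#' @method print longitudinal_fit
print.longitudinal_fit <- function(x, ...) {
  cat(sprintf("Longitudinal mixed model (%s): %d subjects\n",
              x$convergence, x$n_subjects))
  print(x$fixed, digits = 4, row.names = FALSE)
  if (!is.null(x$lrt))
    cat(sprintf("\nRandom-slope LRT: chi^2(%d) = %.2f, p = %.3g\n",
                x$lrt$df, x$lrt$statistic, x$lrt$p))
  invisible(x)
}

#' Predicted moderation curves for a cluster's mean activity
#'
#' Residualizes the outcome for covariates, fits a single-moderator model
#' (cluster mean contrast moderating the quadratic pathology effect) and
#' returns predicted outcome curves over a pathology grid for a hypothetical
#' subject with cluster activity one SD above and one SD below the mean, with
#' pointwise 95% confidence bands from the coefficient covariance.
#'
#' @param cluster_activity per-subject mean contrast in the cluster.
#' @param pl pathology score.
#' @param y outcome.
#' @param covariates optional covariate data frame (residualized out).
#' @param at activity offsets in SDs (default `c(-1, 1)`).
#' @param n_grid points on the pathology grid.
#' @return list of class `"moderation_curves"`: `curves` (data frame `pl`,
#'   `activity_sd`, `fit`, `lower`, `upper`) and the underlying
#'   `"moderation_report"`.
#' @export
cluster_moderation_curves <- function(cluster_activity, pl, y, covariates = NULL,
                                      at = c(-1, 1), n_grid = 50) {
  if (!length(cluster_activity)) stop("empty cluster activity", call. = FALSE)
  keep <- is.finite(cluster_activity) & is.finite(pl) & is.finite(y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- keep & complete.cases(covariates)
    cd <- covariate_design(droplevels(covariates[keep, , drop = FALSE]))
    res_fit <- ols_qr(cbind(1, cd$X), y[keep], context = "residualization")
    y_res <- res_fit$residuals
  } else {
    y_res <- y[keep] - mean(y[keep])
  }
  act <- cluster_activity[keep]; plk <- pl[keep]
  rep <- fit_proxy_moderation(y_res, plk, act, include_moderator_main = TRUE,
                              moderator_name = "activity")
  grid <- seq(min(plk), max(plk), length.out = n_grid)
  mu_a <- mean(act); sd_a <- sd(act)
  curves <- do.call(rbind, lapply(at, function(k) {
    a0 <- mu_a + k * sd_a
    Xg <- cbind(1, a0, grid^2, a0 * grid^2)
    fit <- drop(Xg %*% rep$coefficients)
    se <- sqrt(rowSums((Xg %*% rep$vcov) * Xg))
    crit <- qt(0.975, df = rep$df)
    data.frame(pl = grid, activity_sd = k, fit = fit,
               lower = fit - crit * se, upper = fit + crit * se)
  }))
  structure(list(curves = curves, model = rep), class = "moderation_curves")
}
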
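#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor cor.test fitted lm lm.fit median pnorm pt qt
#'   quantile rbinom rnorm rpois runif sd setNames var predict resid vcov
#'   model.matrix anova complete.cases qnorm simulate confint
#' @importFrom utils head read.csv write.csv
#' @importFrom graphics abline axis hist legend lines par plot points
NULL

# Min-max rescaling to [0, 1]; errors on constant input because the scores that
# use it (pathological load, atrophy) are undefined for a degenerate sample.
rescale01 <- function(x, what = "values") {
  r <- range(x, na.rm = TRUE)
  if (!all(is.finite(r))) stop(what, " contain non-finite values", call. = FALSE)
  if (r[1] == r[2]) stop(what, " are constant; [0,1] rescaling is undefined", call. = FALSE)
  (x - r[1]) / (r[2] - r[1])
}

# Fixed per-stage offsets on the master seed so any stage is reproducible in
# isolation. Kept well below .Machine$integer.max.
stage_seed <- function(seed, stage) {
  offsets <- c(
    severity = 101L, biomarkers = 202L, contrasts = 303L, cognition = 404L,
    longitudinal = 505L, behavior = 606L, education = 707L, covariates = 808L
  )
  if (!stage %in% names(offsets)) stop("unknown seed stage: ", stage)
  (as.integer(seed) + offsets[[stage]]) %% 2147483647L
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop("'", name, "' must be a single integer >= ", min, call. = FALSE)
  as.integer(x)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  ok <- length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower && x < upper else x >= lower && x <= upper)
  if (!ok) stop("'", name, "' must be a single number in ",
                if (strict) "(" else "[", lower, ", ", upper,
                if (strict) ")" else "]", call. = FALSE)
  as.numeric(x)
}
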
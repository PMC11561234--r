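# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = .fixtures)) assign(name, fn(), envir = .fixtures)
  get(name, envir = .fixtures)
}

zero_noise <- list(biomarker = 0, contrast = 0, cognition = 0, subitem = 0,
                   visit = 0, rand_intercept = 0, rand_slope = 0)

small_cfg <- function(...) {
  sim_config(n_subjects = 80, grid_shape = c(6, 6, 6), mask_fraction = 0.4,
             n_latent = 3, ...)
}

covariate_cols <- c("age", "sex", "tiv", "site")

small_cohort <- function() fixture("small_cohort", function() {
  simulate_cohort(small_cfg(seed = 42))
})

zero_noise_cohort <- function() fixture("zero_noise_cohort", function() {
  simulate_cohort(small_cfg(noise_sd = zero_noise, seed = 7))
})
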
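# shared fixtures: small, fast cohorts and a noise-free config factory

noise_free_config <- function(n_birds = 6, pixel_equation = "by_sex",
                              seed = 1L, ...) {
  cohort_config(n_birds = n_birds, seed = seed,
                noise_cv_weight = 0, morphometric_noise_cv = 0,
                pixel_noise_cv = 0, bird_cv_A = 0, bird_cv_k = 0,
                pixel_equation = pixel_equation, ...)
}

small_cohort <- function(n_birds = 10, seed = 3L, ...) {
  generate_cohort(cohort_config(n_birds = n_birds, seed = seed, ...))
}

# linear toy regression records for harness tests (no day column needed
# when stratify = FALSE)
linear_records <- function(n = 200, seed = 1L, noise_sd = 0) {
  set.seed(seed)
  d <- data.frame(
    back_length_mm = runif(n, 50, 220),
    back_width_mm = runif(n, 30, 170))
  d$live_weight_g <- 2 * d$back_length_mm + 3 * d$back_width_mm +
    rnorm(n, 0, noise_sd)
  d$sex <- rep(c("male", "female"), length.out = n)
  d
}
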
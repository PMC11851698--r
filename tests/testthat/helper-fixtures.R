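# Shared fixtures, all generated in code.

small_cohort <- function(n = 120, seed = 5, ...) {
  generate_cohort(cohort_config(n_records = n, seed = seed, ...))
}

encoded_cohort <- function(n = 120, seed = 5, ...) {
  cohort <- small_cohort(n, seed, ...)
  enc <- encode_features(cohort)
  dat <- enc$X
  dat$severity <- cohort$severity
  dat
}

# A two-feature toy set where x1 alone separates the classes and x2 is noise.
separable_two_feature <- function(n = 60, seed = 3) {
  set.seed(seed)
  tibble::tibble(
    x1 = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
    x2 = rnorm(n),
    severity = factor(rep(c("a", "b"), each = n / 2))
  )
}

# Fast IWOA configuration for unit tests.
fast_iwoa <- function(seed = 1, ...) {
  iwoa_config(
    population_size = 6, max_iterations = 6, sa_steps_per_whale = 3,
    stall_patience = 5, seed = seed, ...
  )
}
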
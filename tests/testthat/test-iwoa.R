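test_that("population initialization sets Bernoulli(0.5) bits with repair", {
  cfg <- iwoa_config(population_size = 10, seed = 1)
  set.seed(1)
  pop1 <- init_population(1, cfg)
  expect_true(all(vapply(pop1, function(w) identical(w$mask, 1L), logical(1))))

  set.seed(2)
  a <- init_population(20, cfg)
  set.seed(2)
  b <- init_population(20, cfg)
  expect_identical(
    lapply(a, `[[`, "mask"),
    lapply(b, `[[`, "mask")
  )

  set.seed(3)
  big <- init_population(20, iwoa_config(population_size = 10000))
  bits <- vapply(big, function(w) sum(w$mask), numeric(1))
  se <- sqrt(20 * 0.25 / 10000)
  expect_lt(abs(mean(bits) - 10), 3 * se)
  expect_true(all(bits >= 1))
  expect_error(init_population(0, cfg), "n_features")
})

test_that("search coefficients follow the linear decay and uniform draws", {
  cfg <- iwoa_config(max_iterations = 50)
  set.seed(1)
  cc <- compute_coefficients(50, cfg)
  expect_equal(cc$a, 0)
  expect_equal(cc$A, 0)
  cc0 <- compute_coefficients(0, cfg)
  expect_equal(cc0$a, 2)
  set.seed(4)
  ls <- replicate(1e4, compute_coefficients(10, cfg)$l)
  se <- sqrt(1 / 3 / 1e4) # var of U(-1,1) is 1/3
  expect_lt(abs(mean(ls)), 3 * se)
  expect_true(all(abs(ls) <= 1))
  expect_error(compute_coefficients(51, cfg), "max_iterations")
})

test_that("encircling and spiral updates match their closed forms", {
  expect_equal(encircle_update(c(0, 0), c(1, 0), A = 0, C = 1), c(1, 0))
  expect_equal(encircle_update(c(1, 1), c(1, 1), A = 0.7, C = 1), c(1, 1))
  expect_equal(encircle_update(c(0, 0), c(1, 0), A = 0.5, C = 1), c(0.5, 0))
  expect_error(encircle_update(c(0, 0), c(1, 0, 0), 0.5, 1), "length")

  expect_equal(spiral_update(c(1, 1), c(1, 1), b = 1, l = 0.3), c(1, 1))
  expect_equal(spiral_update(c(0, 0), c(1, 1), b = 1, l = 0), c(2, 2))
  got <- spiral_update(c(0), c(1), b = 1, l = -1)
  expect_equal(got, 1 * exp(-1) * cos(-2 * pi) + 1)
  expect_error(spiral_update(1:2, 1:3, 1, 0), "length")
})

test_that("the sigmoid transfer sets bits at the closed-form frequencies", {
  set.seed(5)
  freq0 <- mean(replicate(1e4, binarize_position(0)))
  expect_lt(abs(freq0 - 0.5), 3 * sqrt(0.25 / 1e4))
  p2 <- 1 / (1 + exp(-2))
  freq2 <- mean(replicate(1e4, binarize_position(2)))
  expect_lt(abs(freq2 - p2), 3 * sqrt(p2 * (1 - p2) / 1e4))
  expect_true(all(replicate(1e4, binarize_position(50)) == 1))
  # printed (decreasing) variant inverts the inclusion direction
  expect_true(all(replicate(100, binarize_position(50, "printed")) == 0))
  expect_error(binarize_position(c(1, Inf)), "finite")
})

test_that("wrapper fitness rewards accuracy and penalizes subset size", {
  dat <- separable_two_feature()
  cfg <- iwoa_config(seed = 2)
  expect_equal(evaluate_fitness(c(0, 0), dat, config = cfg), 0)
  f1 <- evaluate_fitness(c(1, 0), dat, config = cfg)
  f12 <- evaluate_fitness(c(1, 1), dat, config = cfg)
  expect_gt(f1, f12)
  # w = 1 degenerates to plain CV accuracy
  facc <- evaluate_fitness(c(1, 0), dat, config = iwoa_config(fitness_weight = 1, seed = 2))
  expect_lte(facc, 1)
  expect_gt(facc, 0.9)
  expect_error(
    evaluate_fitness(c(1, 0), dplyr::mutate(dat, severity = factor("a"))),
    "single class"
  )
})

test_that("SA acceptance follows the Boltzmann law", {
  expect_equal(sa_acceptance_probability(-0.2, 1), 1)
  expect_equal(sa_acceptance_probability(0.1, 1), exp(-0.1))
  set.seed(6)
  acc <- mean(replicate(1e4, sa_accept(0.1, 1)))
  p <- exp(-0.1)
  expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / 1e4))
  # frozen limit: worsening moves are never accepted
  expect_false(any(replicate(1e4, sa_accept(0.1, 1e-12))))
  # improvements always accepted
  expect_true(all(replicate(100, sa_accept(-0.01, 1e-12))))
  expect_error(sa_acceptance_probability(0.1, 0), "positive")
})

test_that("SA refinement returns the best visited state and repairs empty masks", {
  # fitness = fraction of bits set: the all-ones mask is optimal
  fit_fn <- function(mask) mean(mask)
  set.seed(7)
  out <- sa_refine(c(1L, 0L, 0L, 0L), fit_fn,
    iwoa_config(sa_steps_per_whale = 50, sa_initial_temperature = 0.05)
  )
  expect_gte(out$fitness, 0.75)
  expect_equal(out$fitness, mean(out$mask))
  # flipping the only set bit must repair to a nonempty mask
  set.seed(8)
  res <- sa_refine(c(1L), fit_fn, iwoa_config(sa_steps_per_whale = 5))
  expect_equal(res$mask, 1L)
})

test_that("run_iwoa is deterministic, elitist, and handles one feature", {
  dat <- separable_two_feature()
  dat1 <- dat[c("x1", "severity")]
  expect_warning(r1 <- run_iwoa(dat1, config = fast_iwoa(1)), "single feature")
  expect_equal(unname(r1$best_mask), 1L)

  r <- run_iwoa(dat, config = fast_iwoa(2))
  r2 <- run_iwoa(dat, config = fast_iwoa(2))
  expect_identical(r[c("best_mask", "best_fitness", "trajectory")],
    r2[c("best_mask", "best_fitness", "trajectory")])
  expect_true(all(diff(r$trajectory) >= 0))
  expect_gte(sum(r$best_mask), 1)
  expect_equal(r$best_fitness, r$trajectory[length(r$trajectory)])
})

test_that("the search matches the exhaustive optimum on a small instance", {
  bench <- make_feature_benchmark(n_rows = 80, n_features = 5, seed = 7)
  dat <- bench
  names(dat)[names(dat) == "class"] <- "severity"
  cfg <- iwoa_config(
    population_size = 10, max_iterations = 15,
    sa_steps_per_whale = 8, stall_patience = 10, seed = 3
  )
  ex <- exhaustive_search(dat, config = cfg)
  r <- run_iwoa(dat, config = cfg)
  expect_equal(r$best_fitness, ex$best_fitness)
})

test_that("result tidiers and the trajectory plot expose the run", {
  dat <- separable_two_feature()
  r <- run_iwoa(dat, config = fast_iwoa(4))
  td <- tidy(r)
  expect_equal(td$feature, c("x1", "x2"))
  expect_type(td$selected, "logical")
  g <- glance(r)
  expect_equal(g$n_features, 2L)
  expect_s3_class(autoplot(r), "ggplot")
})
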
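#' IWOA feature-selection configuration
#'
#' Parameters of the binary whale optimization search with
#' simulated-annealing memetic refinement.
#'
#' @param population_size Number of whales `N`.
#' @param max_iterations Global search iterations `T_max`.
#' @param spiral_constant Logarithmic spiral shape constant `b`.
#' @param switch_probability Probability of taking the spiral (exploration)
#'   move instead of the encircling move at each whale update.
#' @param fitness_weight Trade-off weight `w` in
#'   `f = w * cv_accuracy + (1 - w) * (1 - subset_size / n_features)`.
#' @param sa_initial_temperature,sa_cooling_rate,sa_steps_per_whale
#'   Simulated-annealing start temperature `T0`, geometric cooling factor
#'   `alpha` in (0,1), and number of flip proposals per whale.
#' @param sa_mode `"end"` (refine every whale once after the global search,
#'   the default) or `"each"` (refine after every iteration).
#' @param cv_folds_fitness Stratified folds of the wrapper cross-validation.
#' @param stall_patience Stop early when the best fitness has not improved
#'   for this many iterations.
#' @param transfer `"standard"` sigmoid `1/(1+exp(-x))` or the `"printed"`
#'   decreasing variant `1/(1+exp(x))`.
#' @param seed Integer seed; fixes the whale trajectories and the wrapper
#'   CV folds.
#' @return An object of class `iwoa_config`.
#' @export
iwoa_config <- function(population_size = 20,
                        max_iterations = 50,
                        spiral_constant = 1,
                        switch_probability = 0.5,
                        fitness_weight = 0.9,
                        sa_initial_temperature = 0.02,
                        sa_cooling_rate = 0.9,
                        sa_steps_per_whale = 10,
                        sa_mode = c("end", "each"),
                        cv_folds_fitness = 3,
                        stall_patience = 15,
                        transfer = c("standard", "printed"),
                        seed = 1L) {
  sa_mode <- match.arg(sa_mode)
  transfer <- match.arg(transfer)
  if (population_size < 2) abort("`population_size` must be >= 2.")
  if (max_iterations < 1) abort("`max_iterations` must be >= 1.")
  if (sa_cooling_rate <= 0 || sa_cooling_rate >= 1) {
    abort("`sa_cooling_rate` must lie strictly between 0 and 1.")
  }
  if (sa_initial_temperature <= 0) abort("`sa_initial_temperature` must be > 0.")
  if (fitness_weight < 0 || fitness_weight > 1) abort("`fitness_weight` must be in [0, 1].")
  if (switch_probability < 0 || switch_probability > 1) {
    abort("`switch_probability` must be in [0, 1].")
  }
  structure(
    list(
      population_size = as.integer(population_size),
      max_iterations = as.integer(max_iterations),
      spiral_constant = spiral_constant,
      switch_probability = switch_probability,
      fitness_weight = fitness_weight,
      sa_initial_temperature = sa_initial_temperature,
      sa_cooling_rate = sa_cooling_rate,
      sa_steps_per_whale = as.integer(sa_steps_per_whale),
      sa_mode = sa_mode,
      cv_folds_fitness = as.integer(cv_folds_fitness),
      stall_patience = as.integer(stall_patience),
      transfer = transfer,
      seed = as.integer(seed)
    ),
    class = "iwoa_config"
  )
}

# Wrapper-fitness evaluator closure over a fixed dataset. Fold assignment is
# derived once from the config seed so a mask always maps to the same
# fitness; evaluations are cached by mask key and counted.
make_fitness_evaluator <- function(X, y, config) {
  X <- as.data.frame(X)
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2) {
    abort("labels contain a single class; wrapper fitness is undefined.")
  }
  y <- droplevels(y)
  folds <- stratified_folds(y, config$cv_folds_fitness, derive_seed(config$seed, "fitness-folds"))
  n_feat <- ncol(X)
  w <- config$fitness_weight
  cache <- new.env(parent = emptyenv())
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  fn <- function(mask) {
    mask <- as.integer(mask)
    counter$n <- counter$n + 1L
    if (sum(mask) == 0) {
      return(0)
    }
    key <- paste(mask, collapse = "")
    if (!is.null(cache[[key]])) {
      return(cache[[key]])
    }
    cols <- which(mask == 1)
    correct <- 0L
    for (k in seq_len(config$cv_folds_fitness)) {
      tr <- folds != k
      df_tr <- data.frame(X[tr, cols, drop = FALSE], .y = y[tr])
      fit <- rpart::rpart(.y ~ ., data = df_tr, method = "class")
      pred <- predict(fit, newdata = X[!tr, cols, drop = FALSE], type = "class")
      correct <- correct + sum(pred == y[!tr])
    }
    acc <- correct / length(y)
    f <- w * acc + (1 - w) * (1 - sum(mask) / n_feat)
    cache[[key]] <- f
    f
  }
  attr(fn, "counter") <- counter
  fn
}

#' Wrapper fitness of a feature mask
#'
#' Scores a binary feature mask by the stratified cross-validated accuracy
#' of a decision-tree wrapper classifier on the masked columns, traded off
#' against subset size:
#' `f = w * acc_cv + (1 - w) * (1 - |mask| / n_features)`. An empty mask
#' scores 0. Deterministic given the config seed.
#'
#' @param mask Binary (0/1) vector, one entry per feature column.
#' @param data Tibble of encoded numeric features plus the outcome column.
#' @param outcome Name of the class-label column in `data`.
#' @param config An [iwoa_config()].
#' @return Fitness value in `[0, 1]`.
#' @export
evaluate_fitness <- function(mask, data, outcome = "severity", config = iwoa_config()) {
  X <- data[setdiff(names(data), outcome)]
  stopifnot(length(mask) == ncol(X))
  make_fitness_evaluator(X, data[[outcome]], config)(mask)
}

# Continuous position whose sigmoid transfer regenerates `mask` with high
# probability (|x| = 4 puts the inclusion probability at ~0.982).
mask_anchor <- function(mask, transfer = "standard") {
  sgn <- if (transfer == "standard") 1 else -1
  sgn * (2 * as.numeric(mask) - 1) * 4
}

# Ensure a mask keeps at least one feature: set one uniformly random bit.
repair_mask <- function(mask) {
  if (sum(mask) == 0) mask[sample.int(length(mask), 1)] <- 1L
  mask
}

#' Initialize the whale population
#'
#' Each whale gets an independent Bernoulli(0.5) bit per feature (empty
#' masks repaired to a single random bit) and a continuous position drawn
#' uniformly from \[-2, 2\]. Fitness is evaluated when a fitness function is
#' supplied.
#'
#' @param n_features Number of features (>= 1).
#' @param config An [iwoa_config()].
#' @param fitness_fn Optional function(mask) -> fitness.
#' @return List of whales, each a list with `position`, `mask`, `fitness`.
#' @export
init_population <- function(n_features, config = iwoa_config(), fitness_fn = NULL) {
  if (n_features < 1) abort("`n_features` must be >= 1.")
  purrr::map(seq_len(config$population_size), function(i) {
    mask <- repair_mask(as.integer(runif(n_features) < 0.5))
    list(
      position = runif(n_features, -2, 2),
      mask = mask,
      fitness = if (is.null(fitness_fn)) NA_real_ else fitness_fn(mask)
    )
  })
}

#' Search coefficients at iteration t
#'
#' Standard whale-optimization coefficients: `a` decays linearly from 2 to 0
#' over the run, `A = 2*a*r1 - a`, `C = 2*r2` with `r1, r2 ~ U(0,1)`, and the
#' spiral parameter `l ~ U(-1, 1)`.
#'
#' @param t Current iteration in `0..max_iterations`.
#' @param config An [iwoa_config()].
#' @return List with `a`, `A`, `C`, `l`.
#' @export
compute_coefficients <- function(t, config = iwoa_config()) {
  if (t < 0 || t > config$max_iterations) {
    abort("`t` must lie in 0..max_iterations.")
  }
  a <- 2 * (1 - t / config$max_iterations)
  r1 <- runif(1)
  r2 <- runif(1)
  list(a = a, A = 2 * a * r1 - a, C = 2 * r2, l = runif(1, -1, 1))
}

#' Encircling (bubble-net) position update
#'
#' Elementwise `x' = x_star - A * |C * x_star - x|`.
#'
#' @param x,x_star Current and best positions (equal-length numeric vectors).
#' @param A,C Scalar search coefficients.
#' @return Updated position vector.
#' @export
encircle_update <- function(x, x_star, A, C) {
  if (length(x) != length(x_star)) abort("position length mismatch.")
  x_star - A * abs(C * x_star - x)
}

#' Spiral position update
#'
#' Elementwise `x' = |x_star - x| * exp(b*l) * cos(2*pi*l) + x_star`.
#'
#' @param x,x_star Current and best positions (equal-length numeric vectors).
#' @param b Spiral constant.
#' @param l Spiral parameter in `[-1, 1]`.
#' @return Updated position vector.
#' @export
spiral_update <- function(x, x_star, b, l) {
  if (length(x) != length(x_star)) abort("position length mismatch.")
  abs(x_star - x) * exp(b * l) * cos(2 * pi * l) + x_star
}

#' Sigmoid transfer of a continuous position to a bit mask
#'
#' Bit i is set with probability `S(x_i)`; by default the increasing sigmoid
#' `S(x) = 1/(1 + exp(-x))` so larger positions favour inclusion. The
#' decreasing `"printed"` variant `1/(1 + exp(x))` is available for
#' comparison.
#'
#' @param x Finite numeric position vector.
#' @param transfer `"standard"` or `"printed"`.
#' @return Integer 0/1 mask of the same length.
#' @export
binarize_position <- function(x, transfer = c("standard", "printed")) {
  transfer <- match.arg(transfer)
  if (any(!is.finite(x))) abort("positions must be finite.")
  s <- if (transfer == "standard") 1 / (1 + exp(-x)) else 1 / (1 + exp(x))
  as.integer(runif(length(x)) < s)
}

#' Simulated-annealing acceptance rule
#'
#' For a maximization problem with fitness difference
#' `delta_f = f_current - f_proposed`, a proposal is accepted with
#' probability `min(1, exp(-delta_f / T))`: improvements (`delta_f <= 0`)
#' always, worsenings with the Boltzmann probability.
#'
#' @param delta_f Fitness difference `f_current - f_proposed`.
#' @param temperature Current temperature (> 0).
#' @return `sa_acceptance_probability()` the probability;
#'   `sa_accept()` one random accept/reject draw.
#' @export
sa_acceptance_probability <- function(delta_f, temperature) {
  if (any(temperature <= 0)) abort("`temperature` must be positive.")
  pmin(1, exp(-delta_f / temperature))
}

#' @rdname sa_acceptance_probability
#' @export
sa_accept <- function(delta_f, temperature) {
  p <- sa_acceptance_probability(delta_f, temperature)
  delta_f <= 0 | runif(length(p)) < p
}

#' Simulated-annealing refinement of a feature mask
#'
#' Proposes single random bit flips (empty masks repaired), accepting by the
#' Boltzmann rule under a geometrically cooled temperature, and returns the
#' best state visited.
#'
#' @param mask Starting binary mask.
#' @param fitness_fn Function(mask) -> fitness.
#' @param config An [iwoa_config()].
#' @param fitness Optional known fitness of `mask` (saves one evaluation).
#' @return List with `mask` and `fitness` of the best visited state.
#' @export
sa_refine <- function(mask, fitness_fn, config = iwoa_config(), fitness = NULL) {
  if (config$sa_initial_temperature <= 0) abort("invalid initial temperature.")
  cur_mask <- as.integer(mask)
  cur_fit <- if (is.null(fitness)) fitness_fn(cur_mask) else fitness
  best_mask <- cur_mask
  best_fit <- cur_fit
  temp <- config$sa_initial_temperature
  for (step in seq_len(config$sa_steps_per_whale)) {
    prop <- cur_mask
    flip <- sample.int(length(prop), 1)
    prop[flip] <- 1L - prop[flip]
    prop <- repair_mask(prop)
    f_new <- fitness_fn(prop)
    if (sa_accept(cur_fit - f_new, temp)) {
      cur_mask <- prop
      cur_fit <- f_new
      if (f_new > best_fit) {
        best_fit <- f_new
        best_mask <- prop
      }
    }
    temp <- temp * config$sa_cooling_rate
  }
  list(mask = best_mask, fitness = best_fit)
}

#' Wrapper feature selection by improved whale optimization
#'
#' Runs the binary whale optimization search over feature masks: whales move
#' by encircling (toward the best whale when `|A| < 1`, toward a random
#' whale otherwise) or by the logarithmic spiral, chosen with
#' `switch_probability`; positions are binarized through a sigmoid transfer,
#' repaired to non-empty, and scored by the cross-validated wrapper fitness.
#' The global best is updated only on strict improvement (elitism), so the
#' fitness trajectory is nondecreasing. A simulated-annealing memetic pass
#' refines each whale (by default once, after the global search). The run
#' stops at `max_iterations` or after `stall_patience` iterations without
#' improvement.
#'
#' @param data Tibble of encoded numeric feature columns plus the outcome.
#' @param outcome Name of the class-label column.
#' @param config An [iwoa_config()].
#' @return An object of class `iwoa_result`: `best_mask` (named 0/1 vector),
#'   `best_fitness`, `trajectory`, `n_evaluations`, `features`, `seed`,
#'   `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_records = 60, seed = 1))
#' enc <- encode_features(cohort)
#' dat <- dplyr::bind_cols(enc$X, severity = cohort$severity)
#' res <- run_iwoa(dat, config = iwoa_config(
#'   population_size = 4,
#'   max_iterations = 2, sa_steps_per_whale = 2, seed = 1
#' ))
#' glance(res)
run_iwoa <- function(data, outcome = "severity", config = iwoa_config()) {
  features <- setdiff(names(data), outcome)
  X <- data[features]
  if (!all(vapply(X, is.numeric, logical(1)))) {
    abort("all feature columns must be numeric; encode the cohort first.")
  }
  y <- data[[outcome]]
  n_feat <- length(features)
  evaluator <- make_fitness_evaluator(X, y, config)

  set.seed(derive_seed(config$seed, "iwoa"))
  pop <- init_population(n_feat, config, evaluator)
  if (n_feat == 1) {
    warn("single feature: the only valid mask is [1].")
  }
  best_i <- which.max(vapply(pop, `[[`, numeric(1), "fitness"))
  best <- pop[[best_i]]
  trajectory <- best$fitness
  stall <- 0L
  for (t in seq_len(config$max_iterations)) {
    improved <- FALSE
    for (i in seq_along(pop)) {
      cc <- compute_coefficients(t, config)
      if (runif(1) < config$switch_probability) {
        xnew <- spiral_update(pop[[i]]$position, best$position, config$spiral_constant, cc$l)
      } else if (abs(cc$A) < 1) {
        xnew <- encircle_update(pop[[i]]$position, best$position, cc$A, cc$C)
      } else {
        j <- sample.int(length(pop), 1)
        xnew <- encircle_update(pop[[i]]$position, pop[[j]]$position, cc$A, cc$C)
      }
      # keep positions in a range where the sigmoid is numerically sane
      xnew <- pmin(pmax(xnew, -10), 10)
      mask <- repair_mask(binarize_position(xnew, config$transfer))
      f <- evaluator(mask)
      pop[[i]] <- list(position = xnew, mask = mask, fitness = f)
      if (config$sa_mode == "each") {
        ref <- sa_refine(mask, evaluator, config, fitness = f)
        pop[[i]]$mask <- ref$mask
        pop[[i]]$fitness <- ref$fitness
      }
      if (pop[[i]]$fitness > best$fitness) {
        best <- pop[[i]]
        # anchor exploitation on a position that regenerates the best mask
        # near-deterministically through the sigmoid transfer
        best$position <- mask_anchor(best$mask, config$transfer)
        improved <- TRUE
      }
    }
    trajectory <- c(trajectory, best$fitness)
    stall <- if (improved) 0L else stall + 1L
    if (stall >= config$stall_patience) break
  }
  if (config$sa_mode == "end") {
    for (i in seq_along(pop)) {
      ref <- sa_refine(pop[[i]]$mask, evaluator, config, fitness = pop[[i]]$fitness)
      if (ref$fitness > best$fitness) {
        best <- list(
          position = mask_anchor(ref$mask, config$transfer),
          mask = ref$mask, fitness = ref$fitness
        )
      }
    }
    trajectory <- c(trajectory, best$fitness)
  }
  structure(
    list(
      best_mask = stats::setNames(as.integer(best$mask), features),
      best_fitness = best$fitness,
      trajectory = trajectory,
      n_evaluations = attr(evaluator, "counter")$n,
      features = features,
      seed = config$seed,
      config = config
    ),
    class = "iwoa_result"
  )
}

#' Exhaustive wrapper-fitness search
#'
#' Evaluates every nonempty feature mask and returns the maximum fitness.
#' Intended as the ground-truth optimum for small feature counts.
#'
#' @inheritParams run_iwoa
#' @param max_features Guard: refuse more than this many features.
#' @return List with `best_mask`, `best_fitness`, `n_evaluated`.
#' @export
exhaustive_search <- function(data, outcome = "severity", config = iwoa_config(),
                              max_features = 16) {
  features <- setdiff(names(data), outcome)
  n_feat <- length(features)
  if (n_feat > max_features) {
    abort("too many features for exhaustive enumeration.")
  }
  evaluator <- make_fitness_evaluator(data[features], data[[outcome]], config)
  best_f <- -Inf
  best_mask <- NULL
  for (code in seq_len(2^n_feat - 1)) {
    mask <- as.integer(intToBits(code)[seq_len(n_feat)])
    f <- evaluator(mask)
    if (f > best_f) {
      best_f <- f
      best_mask <- mask
    }
  }
  list(
    best_mask = stats::setNames(best_mask, features),
    best_fitness = best_f,
    n_evaluated = 2^n_feat - 1
  )
}

#' @export
print.iwoa_result <- function(x, ...) {
  cat(
    "IWOA feature selection: ", sum(x$best_mask), "/", length(x$best_mask),
    " features, fitness ", format(x$best_fitness, digits = 6),
    " (", x$n_evaluations, " fitness evaluations)\n",
    sep = ""
  )
  cat("selected:", paste(names(x$best_mask)[x$best_mask == 1], collapse = ", "), "\n")
  invisible(x)
}

#' Tidiers for IWOA results
#'
#' `tidy()` returns one row per feature with its selection flag; `glance()`
#' a one-row run summary.
#'
#' @param x An `iwoa_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy iwoa_result
#' @export
tidy.iwoa_result <- function(x, ...) {
  tibble::tibble(
    feature = names(x$best_mask),
    selected = as.logical(x$best_mask)
  )
}

#' @rdname tidy.iwoa_result
#' @method glance iwoa_result
#' @export
glance.iwoa_result <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$best_mask),
    n_selected = sum(x$best_mask),
    best_fitness = x$best_fitness,
    n_iterations = length(x$trajectory) - 1L,
    n_evaluations = x$n_evaluations,
    seed = x$seed
  )
}

#' Fitness-trajectory plot for an IWOA run
#'
#' @param object An `iwoa_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot iwoa_result
#' @export
autoplot.iwoa_result <- function(object, ...) {
  df <- tibble::tibble(
    iteration = seq_along(object$trajectory) - 1,
    best_fitness = object$trajectory
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "Iteration", y = "Best fitness",
      title = "IWOA best-fitness trajectory"
    ) +
    ggplot2::theme_minimal()
}
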
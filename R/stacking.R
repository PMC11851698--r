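supported_base_models <- function() c("RF", "SVM", "GB", "NB", "KNN", "XGB", "DT")

# Deterministic class probabilities from a fitted multiclass SVM via soft
# voting: each pairwise decision value is squashed through a sigmoid with a
# per-pair slope calibrated on the training margins (stored at fit time),
# the winner/loser shares are accumulated per class, and the soft vote
# totals go through a softmax. Avoids libsvm's internally randomized Platt
# scaling while tracking its pairwise voting rule.
svm_calibrated_fit <- function(X, y) {
  fit <- suppressWarnings(e1071::svm(X, y, kernel = "linear", cost = 1))
  dv <- attr(predict(fit, X, decision.values = TRUE), "decision.values")
  # sigmoid slope: a quarter of the median training margin per pair, steep
  # enough that the soft vote tracks libsvm's hard pairwise voting
  scales <- apply(abs(dv), 2, stats::median) * 0.25
  scales[scales == 0 | !is.finite(scales)] <- 1
  list(svm = fit, scales = scales)
}

svm_class_probs <- function(fit, X, classes) {
  dv <- attr(predict(fit$svm, X, decision.values = TRUE), "decision.values")
  soft <- 1 / (1 + exp(-sweep(dv, 2, fit$scales[colnames(dv)], "/")))
  scores <- matrix(0, nrow(X), length(classes), dimnames = list(NULL, classes))
  pairs <- strsplit(colnames(dv), "/", fixed = TRUE)
  for (j in seq_along(pairs)) {
    a <- pairs[[j]][1]
    b <- pairs[[j]][2]
    scores[, a] <- scores[, a] + soft[, j]
    scores[, b] <- scores[, b] + 1 - soft[, j]
  }
  e <- exp(scores - apply(scores, 1, max))
  e / rowSums(e)
}

# Hand-rolled k-nearest-neighbour class probabilities (neighbour class
# proportions under Euclidean distance on train-standardized features).
knn_fit <- function(X, y, k = 5) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  list(X = scale(X, mu, sdv), y = y, mu = mu, sd = sdv, k = min(k, nrow(X)))
}

knn_probs <- function(fit, X, classes) {
  Xs <- scale(as.matrix(X), fit$mu, fit$sd)
  tr <- as.matrix(fit$X)
  out <- matrix(0, nrow(Xs), length(classes), dimnames = list(NULL, classes))
  for (i in seq_len(nrow(Xs))) {
    d <- colSums((t(tr) - Xs[i, ])^2)
    nb <- order(d)[seq_len(fit$k)]
    tab <- table(factor(fit$y[nb], levels = classes))
    out[i, ] <- as.numeric(tab) / fit$k
  }
  out
}

xgb_fit <- function(X, y, seed, params, nrounds) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = as.integer(y) - 1)
  xgboost::xgb.train(
    params = c(params, list(
      objective = "multi:softprob",
      num_class = nlevels(y), nthread = 1, seed = seed
    )),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
}

xgb_probs <- function(fit, X, classes) {
  pr <- predict(fit, xgboost::xgb.DMatrix(as.matrix(X)))
  if (is.null(dim(pr))) pr <- matrix(pr, ncol = length(classes), byrow = TRUE)
  colnames(pr) <- classes
  pr
}

# Registry of base learners: each entry fits on (X, y) and predicts a
# row-stochastic class-probability matrix with columns in levels(y) order.
base_learner <- function(name, seed) {
  name <- match.arg(name, supported_base_models())
  switch(name,
    RF = list(
      fit = function(X, y) {
        set.seed(seed)
        randomForest::randomForest(X, y, ntree = 300)
      },
      prob = function(fit, X, classes) {
        predict(fit, X, type = "prob")[, classes, drop = FALSE]
      }
    ),
    SVM = list(
      fit = function(X, y) {
        set.seed(seed)
        svm_calibrated_fit(X, y)
      },
      prob = svm_class_probs
    ),
    GB = list(
      fit = function(X, y) {
        xgb_fit(X, y, seed, list(max_depth = 3, eta = 0.1), nrounds = 200)
      },
      prob = xgb_probs
    ),
    XGB = list(
      fit = function(X, y) {
        xgb_fit(X, y, seed, list(max_depth = 6, eta = 0.3), nrounds = 60)
      },
      prob = xgb_probs
    ),
    NB = list(
      fit = function(X, y) e1071::naiveBayes(X, y),
      prob = function(fit, X, classes) {
        predict(fit, X, type = "raw")[, classes, drop = FALSE]
      }
    ),
    KNN = list(
      fit = function(X, y) knn_fit(as.matrix(X), y),
      prob = knn_probs
    ),
    DT = list(
      fit = function(X, y) {
        rpart::rpart(.y ~ ., data = data.frame(X, .y = y), method = "class")
      },
      prob = function(fit, X, classes) {
        predict(fit, newdata = as.data.frame(X), type = "prob")[, classes, drop = FALSE]
      }
    )
  )
}

#' Out-of-fold base-model predictions
#'
#' Splits the training data into stratified folds and, for each fold and
#' base model, trains on the remaining folds and predicts the held-out fold,
#' so every row receives exactly one out-of-fold class-probability vector
#' per base model.
#'
#' @param X Numeric feature data frame.
#' @param y Class labels (factor).
#' @param base_specs Character vector of base-model names from
#'   `r paste(supported_base_models(), collapse = ", ")`.
#' @param k_folds Number of folds (>= 2).
#' @param seed Integer seed (folds and model seeds derive from it).
#' @return List with `oof` (named list of n-by-K probability matrices),
#'   `fold_map` (integer fold id per row), `classes`.
#' @export
fit_base_oof <- function(X, y, base_specs = c("RF", "SVM", "GB"), k_folds = 5, seed = 1L) {
  X <- as.data.frame(X)
  y <- droplevels(factor(y))
  classes <- levels(y)
  folds <- stratified_folds(y, k_folds, derive_seed(seed, "oof-folds"))
  oof <- lapply(base_specs, function(nm) {
    matrix(NA_real_, nrow(X), length(classes), dimnames = list(NULL, classes))
  })
  names(oof) <- base_specs
  for (k in seq_len(k_folds)) {
    tr <- folds != k
    for (nm in base_specs) {
      bl <- base_learner(nm, derive_seed(seed, paste0("base-", nm), index = k))
      fit <- bl$fit(X[tr, , drop = FALSE], y[tr])
      oof[[nm]][!tr, ] <- bl$prob(fit, X[!tr, , drop = FALSE], classes)
    }
  }
  list(oof = oof, fold_map = folds, classes = classes)
}

#' Assemble the meta-feature matrix
#'
#' Probability mode concatenates the class-probability block of every base
#' model (width `n_base * K`); label mode keeps one predicted-class code per
#' base model (width `n_base`).
#'
#' @param oof Named list of n-by-K probability matrices (as from
#'   [fit_base_oof()]).
#' @param mode `"probability"` or `"label"`.
#' @return Numeric meta-feature matrix.
#' @export
build_meta_features <- function(oof, mode = c("probability", "label")) {
  mode <- match.arg(mode)
  rows <- vapply(oof, nrow, integer(1))
  if (length(unique(rows)) != 1) abort("base prediction row counts differ.")
  if (mode == "probability") {
    blocks <- lapply(names(oof), function(nm) {
      blk <- oof[[nm]]
      cls <- colnames(blk) %||% paste0("class", seq_len(ncol(blk)))
      colnames(blk) <- paste0(nm, ".", cls)
      blk
    })
    do.call(cbind, blocks)
  } else {
    out <- vapply(oof, function(m) max.col(m, ties.method = "first"), integer(rows[1]))
    out <- matrix(as.numeric(out), nrow = rows[1])
    colnames(out) <- names(oof)
    out
  }
}

#' Softmax class probabilities
#'
#' `P(k | x) = exp(beta_k . x) / sum_j exp(beta_j . x)`, computed with
#' max-subtraction for numerical stability.
#'
#' @param beta K-by-p coefficient matrix (one row per class).
#' @param x Length-p vector or n-by-p matrix of feature rows.
#' @return Length-K probability vector, or n-by-K matrix.
#' @export
#' @examples
#' softmax_probability(matrix(0, 4, 2), c(1, 1))
softmax_probability <- function(beta, x) {
  if (is.vector(x)) {
    if (length(x) != ncol(beta)) abort("feature width does not match coefficients.")
    s <- as.numeric(beta %*% x)
    e <- exp(s - max(s))
    return(e / sum(e))
  }
  if (ncol(x) != ncol(beta)) abort("feature width does not match coefficients.")
  s <- x %*% t(beta)
  s <- s - apply(s, 1, max)
  e <- exp(s)
  e / rowSums(e)
}

# L2-regularized multinomial logistic regression via BFGS. Coefficients are
# penalized, intercepts are not; lambda = 1 by default.
fit_softmax <- function(M, y, lambda = 1, maxit = 500) {
  y <- droplevels(factor(y))
  K <- nlevels(y)
  if (K < 2) abort("meta-classifier undefined for single-class labels.")
  Xa <- cbind(`(Intercept)` = 1, as.matrix(M))
  Y <- outer(y, levels(y), "==") * 1
  p <- ncol(Xa)
  pen_mask <- c(0, rep(1, p - 1))
  nll <- function(par) {
    beta <- matrix(par, K, p)
    s <- Xa %*% t(beta)
    m <- apply(s, 1, max)
    lse <- m + log(rowSums(exp(s - m)))
    -sum(rowSums(Y * s) - lse) + lambda / 2 * sum((beta^2) %*% pen_mask)
  }
  grad <- function(par) {
    beta <- matrix(par, K, p)
    s <- Xa %*% t(beta)
    s <- s - apply(s, 1, max)
    P <- exp(s)
    P <- P / rowSums(P)
    G <- t(P - Y) %*% Xa + lambda * beta * matrix(pen_mask, K, p, byrow = TRUE)
    as.numeric(G)
  }
  opt <- optim(rep(0, K * p), nll, grad, method = "BFGS", control = list(maxit = maxit))
  beta <- matrix(opt$par, K, p, dimnames = list(levels(y), colnames(Xa)))
  beta
}

#' Fit a stacking classifier with a softmax meta-model
#'
#' Trains the base models out-of-fold, fits an L2-regularized softmax
#' (multinomial logistic) meta-classifier on the assembled meta-feature
#' matrix, and refits every base model on all training rows for deployment.
#'
#' @param data Tibble of numeric feature columns plus the outcome column.
#' @param outcome Name of the class-label column.
#' @param base_specs Base-model names (default the RF/SVM/GB trio).
#' @param k_folds Folds for the out-of-fold predictions.
#' @param mode Meta-feature mode, `"probability"` (default) or `"label"`.
#' @param lambda L2 penalty strength of the meta fit.
#' @param seed Integer seed.
#' @return An object of class `stacking_model`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_records = 80, seed = 2))
#' enc <- encode_features(cohort)
#' dat <- dplyr::bind_cols(enc$X, severity = cohort$severity)
#' fit <- fit_stacking(dat, base_specs = c("DT"), k_folds = 2, seed = 1)
#' predict(fit, head(enc$X))
fit_stacking <- function(data, outcome = "severity",
                         base_specs = c("RF", "SVM", "GB"),
                         k_folds = 5, mode = c("probability", "label"),
                         lambda = 1, seed = 1L) {
  mode <- match.arg(mode)
  base_specs <- vapply(base_specs, match.arg, "", choices = supported_base_models())
  features <- setdiff(names(data), outcome)
  X <- as.data.frame(data[features])
  y <- droplevels(factor(data[[outcome]]))
  if (nlevels(y) < 2) abort("training labels contain a single class.")
  res <- fit_base_oof(X, y, base_specs, k_folds, seed)
  M <- build_meta_features(res$oof, mode)
  beta <- fit_softmax(M, y, lambda)
  full_fits <- lapply(base_specs, function(nm) {
    bl <- base_learner(nm, derive_seed(seed, paste0("full-", nm)))
    bl$fit(X, y)
  })
  names(full_fits) <- base_specs
  structure(
    list(
      base_specs = base_specs, base_fits = full_fits, beta = beta,
      classes = res$classes, mode = mode, features = features,
      fold_map = res$fold_map, lambda = lambda, seed = as.integer(seed)
    ),
    class = "stacking_model"
  )
}

# Meta features for new data from the deployed (full-data) base fits.
stack_meta_new <- function(object, X) {
  oof <- lapply(object$base_specs, function(nm) {
    bl <- base_learner(nm, 0L)
    bl$prob(object$base_fits[[nm]], X, object$classes)
  })
  names(oof) <- object$base_specs
  build_meta_features(oof, object$mode)
}

#' Predict method for stacking models
#'
#' @param object A `stacking_model`.
#' @param new_data Tibble/data frame containing the training feature columns.
#' @param type `"class"` for labels, `"prob"` for the K-column probability
#'   matrix.
#' @param ... Unused.
#' @return Factor of labels or a probability matrix. Ties in the argmax are
#'   broken toward the lower severity level index.
#' @export
predict.stacking_model <- function(object, new_data, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  missing_cols <- setdiff(object$features, names(new_data))
  if (length(missing_cols)) {
    abort(paste0(
      "new data lacks training feature column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  X <- as.data.frame(new_data[object$features])
  M <- stack_meta_new(object, X)
  P <- softmax_probability(object$beta, cbind(`(Intercept)` = 1, M))
  colnames(P) <- object$classes
  if (type == "prob") {
    return(P)
  }
  factor(object$classes[max.col(P, ties.method = "first")], levels = object$classes)
}

#' Predict severity labels and class probabilities
#'
#' Tidy prediction wrapper: one row per input row with the predicted label
#' and the four class probabilities.
#'
#' @param model A fitted `stacking_model`.
#' @param new_data Feature tibble.
#' @return Tibble with `.pred_class` and one `.pred_<class>` column per
#'   severity level.
#' @export
predict_severity <- function(model, new_data) {
  P <- predict(model, new_data, type = "prob")
  out <- tibble::as_tibble(as.data.frame(P))
  names(out) <- paste0(".pred_", names(out))
  dplyr::bind_cols(
    tibble::tibble(.pred_class = factor(
      model$classes[max.col(P, ties.method = "first")],
      levels = model$classes
    )),
    out
  )
}

#' @export
print.stacking_model <- function(x, ...) {
  cat(
    "Stacking classifier: base [", paste(x$base_specs, collapse = ", "),
    "], softmax meta (", x$mode, " meta-features, width ",
    ncol(x$beta) - 1, "), classes: ", paste(x$classes, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidiers for stacking models
#'
#' `tidy()` returns the meta-classifier coefficients in long form;
#' `glance()` a one-row model summary.
#'
#' @param x A `stacking_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy stacking_model
#' @export
tidy.stacking_model <- function(x, ...) {
  beta <- x$beta
  tibble::tibble(
    class = rep(rownames(beta), ncol(beta)),
    term = rep(colnames(beta), each = nrow(beta)),
    estimate = as.numeric(beta)
  )
}

#' @rdname tidy.stacking_model
#' @method glance stacking_model
#' @export
glance.stacking_model <- function(x, ...) {
  tibble::tibble(
    n_base_models = length(x$base_specs),
    n_classes = length(x$classes),
    meta_mode = x$mode,
    meta_width = ncol(x$beta) - 1L,
    lambda = x$lambda,
    seed = x$seed
  )
}

#' Serialize a stacking model summary to a JSON-safe list
#'
#' Captures the meta coefficients, base specs, class list, fold map digest
#' and seed (not the base model binaries).
#'
#' @param model A `stacking_model`.
#' @return A list safe for `jsonlite::write_json()`.
#' @export
stacking_model_manifest <- function(model) {
  list(
    base_specs = model$base_specs,
    classes = model$classes,
    mode = model$mode,
    meta_coefficients = as.data.frame(model$beta),
    fold_map_digest = sum(model$fold_map * seq_along(model$fold_map)) %% 2147483647,
    lambda = model$lambda,
    seed = model$seed
  )
}
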
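#' Confusion matrix
#'
#' K-by-K count matrix with true classes on rows and predicted classes on
#' columns.
#'
#' @param truth,estimate Equal-length label vectors.
#' @param labels Class labels (defaults to the union of factor levels or
#'   sorted observed values). Values outside `labels` are an error.
#' @return An object of class `vdd_confusion` wrapping the integer matrix.
#' @export
#' @examples
#' confusion_matrix(c(1, 1, 2), c(1, 2, 2), labels = c(1, 2))
confusion_matrix <- function(truth, estimate, labels = NULL) {
  if (length(truth) != length(estimate)) abort("`truth` and `estimate` lengths differ.")
  if (is.null(labels)) {
    labels <- if (is.factor(truth)) levels(truth) else sort(unique(c(as.character(truth), as.character(estimate))))
  }
  labels <- as.character(labels)
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  unknown <- setdiff(unique(c(truth, estimate)), labels)
  if (length(unknown)) {
    abort(paste0("label(s) outside the class set: ", paste(unknown, collapse = ", ")))
  }
  m <- table(
    factor(truth, levels = labels),
    factor(estimate, levels = labels)
  )
  cm <- matrix(as.integer(m), nrow = length(labels), dimnames = list(truth = labels, predicted = labels))
  structure(list(counts = cm, labels = labels, n = length(truth)), class = "vdd_confusion")
}

#' @export
print.vdd_confusion <- function(x, ...) {
  print(x$counts)
  invisible(x)
}

#' Per-class classification metrics
#'
#' For each class treated one-vs-rest: accuracy `(TP+TN)/n`, precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)`, and F1 (harmonic mean of precision and
#' recall). Zero-denominator cells are reported as 0 with the
#' `zero_division` flag set, keeping the output numeric. The overall
#' (micro) accuracy is attached as the `overall_accuracy` attribute and via
#' [glance.vdd_confusion()].
#'
#' @param cm A [confusion_matrix()].
#' @return Tibble with one row per class.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(inherits(cm, "vdd_confusion"))
  counts <- cm$counts
  n <- sum(counts)
  if (n == 0) abort("empty confusion matrix.")
  rows <- lapply(seq_along(cm$labels), function(k) {
    tp <- counts[k, k]
    fp <- sum(counts[-k, k])
    fn <- sum(counts[k, -k])
    tn <- n - tp - fp - fn
    zd <- FALSE
    prec <- if (tp + fp == 0) {
      zd <- TRUE
      0
    } else {
      tp / (tp + fp)
    }
    rec <- if (tp + fn == 0) {
      zd <- TRUE
      0
    } else {
      tp / (tp + fn)
    }
    f1 <- if (prec + rec == 0) {
      zd <- TRUE
      0
    } else {
      2 * prec * rec / (prec + rec)
    }
    tibble::tibble(
      class = cm$labels[k],
      accuracy = (tp + tn) / n,
      precision = prec, recall = rec, f1 = f1,
      support = tp + fn, zero_division = zd
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "overall_accuracy") <- sum(diag(counts)) / n
  out
}

#' @rdname per_class_metrics
#' @param x A `vdd_confusion`.
#' @param ... Unused.
#' @method glance vdd_confusion
#' @export
glance.vdd_confusion <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_classes = length(x$labels),
    overall_accuracy = sum(diag(x$counts)) / sum(x$counts)
  )
}

#' @rdname per_class_metrics
#' @method tidy vdd_confusion
#' @export
tidy.vdd_confusion <- function(x, ...) {
  df <- as.data.frame(as.table(x$counts))
  names(df) <- c("truth", "predicted", "count")
  tibble::as_tibble(df)
}

#' Confusion-matrix heatmap
#'
#' @param object A `vdd_confusion`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vdd_confusion
#' @export
autoplot.vdd_confusion <- function(object, ...) {
  df <- tidy.vdd_confusion(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth, fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev(object$labels)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Predicted", y = "True", title = "Confusion matrix") +
    ggplot2::theme_minimal()
}

# Default per-fold pipeline: SMOTE-NC balance the training rows (raw mixed
# table), encode, standardize the continuous FDSK score with training
# statistics, optionally subset to a feature mask, fit the stacking model
# and predict the held-out rows.
stack_fold_fit_predict <- function(train, test, outcome, base_specs, mask,
                                   k_folds_inner, seed, balance = TRUE) {
  feats <- setdiff(names(train), c(outcome, "serum_25ohd"))
  ytr <- train[[outcome]]
  Xtr_raw <- train[feats]
  if (balance) {
    bal <- smote_nc_balance(Xtr_raw, ytr, preprocess_config(seed = seed))
    Xtr_raw <- bal$X
    ytr <- factor(bal$y, levels = levels(factor(train[[outcome]])))
  }
  enc_tr <- encode_features(Xtr_raw)
  enc_te <- encode_features(test[feats])
  Xtr <- enc_tr$X
  Xte <- enc_te$X[names(Xtr)]
  if ("fdsk_score" %in% names(Xtr)) {
    mu <- mean(Xtr$fdsk_score)
    s <- sd_pop(Xtr$fdsk_score)
    if (s > 0) {
      Xtr$fdsk_score <- (Xtr$fdsk_score - mu) / s
      Xte$fdsk_score <- (Xte$fdsk_score - mu) / s
    }
  }
  if (!is.null(mask)) {
    keep <- names(Xtr)[as_mask_logical(mask, names(Xtr))]
    Xtr <- Xtr[keep]
    Xte <- Xte[keep]
  }
  train_enc <- Xtr
  train_enc[[outcome]] <- ytr
  fit <- fit_stacking(
    train_enc,
    outcome = outcome, base_specs = base_specs,
    k_folds = k_folds_inner, seed = seed
  )
  predict(fit, Xte, type = "class")
}

as_mask_logical <- function(mask, colnames_x) {
  if (is.character(mask)) {
    return(colnames_x %in% mask)
  }
  if (!is.null(names(mask))) {
    return(colnames_x %in% names(mask)[mask != 0])
  }
  if (length(mask) != length(colnames_x)) abort("mask length mismatch.")
  as.logical(mask)
}

#' Cross-validated evaluation of the severity pipeline
#'
#' Stratified k-fold cross-validation of the full pipeline: per fold the
#' preprocessing (SMOTE-NC balancing, encoding, training-statistics
#' standardization) is fit on the training rows only, the stacking
#' classifier is trained, and the held-out rows are predicted. Metrics are
#' aggregated across folds. When `k` equals the number of rows the split is
#' leave-one-out.
#'
#' @param data Cohort tibble (raw, as from [generate_cohort()]).
#' @param outcome Class-label column name.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @param base_specs Base-model names for the stacking classifier.
#' @param mask Optional feature mask (names or 0/1 vector over encoded
#'   columns) restricting the classifier to a selected subset.
#' @param k_folds_inner Inner folds for the out-of-fold meta features.
#' @param balance Apply SMOTE-NC to each training partition (default TRUE).
#' @param fit_predict Optional custom `function(train, test)` returning
#'   predicted labels for the test rows; replaces the stacking pipeline.
#' @return An object of class `cv_report`: `folds` (per-fold per-class
#'   metrics), `fold_accuracy`, `summary` (mean/SD per metric and class),
#'   `mean_accuracy`, `confusion` (pooled confusion matrix), `seed`.
#' @export
crossval_evaluate <- function(data, outcome = "severity", k = 10, seed = 1L,
                              base_specs = c("RF", "SVM", "GB"), mask = NULL,
                              k_folds_inner = 5, balance = TRUE,
                              fit_predict = NULL) {
  y <- droplevels(factor(data[[outcome]]))
  n <- nrow(data)
  folds <- if (k == n) seq_len(n) else stratified_folds(y, k, derive_seed(seed, "cv-folds"))
  labels <- levels(y)
  pred_all <- rep(NA_character_, n)
  fold_rows <- list()
  fold_acc <- numeric(k)
  for (fk in seq_len(k)) {
    te <- folds == fk
    train <- data[!te, , drop = FALSE]
    test <- data[te, , drop = FALSE]
    pred <- if (is.null(fit_predict)) {
      stack_fold_fit_predict(
        train, test, outcome, base_specs, mask,
        k_folds_inner, derive_seed(seed, "cv-fit", index = fk),
        balance = balance
      )
    } else {
      fit_predict(train, test)
    }
    pred_all[te] <- as.character(pred)
    cmk <- confusion_matrix(as.character(y[te]), as.character(pred), labels)
    mk <- per_class_metrics(cmk)
    fold_acc[fk] <- attr(mk, "overall_accuracy")
    fold_rows[[fk]] <- dplyr::bind_cols(tibble::tibble(fold = fk), mk)
  }
  folds_tbl <- dplyr::bind_rows(fold_rows)
  summary_tbl <- folds_tbl |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(dplyr::across(
      c("accuracy", "precision", "recall", "f1"),
      list(mean = mean, sd = sd)
    ), .groups = "drop")
  structure(
    list(
      folds = folds_tbl,
      fold_accuracy = fold_acc,
      mean_accuracy = mean(fold_acc),
      sd_accuracy = sd(fold_acc),
      summary = summary_tbl,
      confusion = confusion_matrix(as.character(y), pred_all, labels),
      k = k, seed = as.integer(seed)
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(
    x$k, "-fold cross-validation: mean accuracy ",
    format(x$mean_accuracy, digits = 4), " (SD ",
    format(x$sd_accuracy, digits = 3), ")\n",
    sep = ""
  )
  print(x$summary)
  invisible(x)
}

#' @rdname crossval_evaluate
#' @param x A `cv_report`.
#' @param ... Unused.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(
    k = x$k, mean_accuracy = x$mean_accuracy,
    sd_accuracy = x$sd_accuracy, seed = x$seed
  )
}

#' Masked correlation report
#'
#' Pearson correlations between encoded feature columns, reported with the
#' redundant upper triangle (and diagonal) masked out and cells with
#' `|corr| > threshold` flagged. Zero-variance columns yield undefined
#' (`NA`) correlations rather than zeros.
#'
#' @param X Numeric tibble/matrix with at least 2 columns and 3 rows.
#' @param threshold Flagging threshold on `|corr|` (default 0.25).
#' @return An object of class `correlation_report`: `full` (complete
#'   matrix), `masked` (lower triangle retained), and `cells` (long tibble
#'   of retained cells with `flagged`).
#' @export
correlation_report <- function(X, threshold = 0.25) {
  X <- as.data.frame(X)
  if (ncol(X) < 2 || nrow(X) < 3) abort("need >= 2 columns and >= 3 rows.")
  if (!all(vapply(X, is.numeric, logical(1)))) abort("all columns must be numeric.")
  constant <- vapply(X, function(v) sd_pop(v[!is.na(v)]) == 0, logical(1))
  full <- suppressWarnings(cor(as.matrix(X), use = "pairwise.complete.obs"))
  full[constant, ] <- NA_real_
  full[, constant] <- NA_real_
  diag(full) <- ifelse(constant, NA_real_, 1)
  masked <- full
  masked[upper.tri(masked, diag = TRUE)] <- NA_real_
  idx <- which(lower.tri(full), arr.ind = TRUE)
  cells <- tibble::tibble(
    row = colnames(full)[idx[, 1]],
    column = colnames(full)[idx[, 2]],
    correlation = full[idx],
    flagged = !is.na(full[idx]) & abs(full[idx]) > threshold
  )
  structure(
    list(full = full, masked = masked, cells = cells, threshold = threshold),
    class = "correlation_report"
  )
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(
    "Masked correlation report (", sum(x$cells$flagged), " cells with |corr| > ",
    x$threshold, ")\n",
    sep = ""
  )
  print(utils::head(dplyr::arrange(x$cells, dplyr::desc(abs(.data$correlation))), 10))
  invisible(x)
}

#' Correlation heatmap with flagged cells
#'
#' @param object A `correlation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot correlation_report
#' @export
autoplot.correlation_report <- function(object, ...) {
  df <- object$cells
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$row, fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$flagged, "*", "")
    ), size = 5) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(title = "Feature correlations (lower triangle, * |corr| > 0.25)")
}

#' Write a correlation report as TSV
#'
#' Lower-triangle cells, with a `*` suffix on flagged values.
#'
#' @param report A `correlation_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_correlation_tsv <- function(report, path) {
  out <- report$cells |>
    dplyr::mutate(value = paste0(
      format(round(.data$correlation, 4), trim = TRUE),
      ifelse(.data$flagged, "*", "")
    )) |>
    dplyr::select("row", "column", "value")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Within-season z-score normalization of serum values
#'
#' Standardizes serum 25-OH-D within each season, either against the
#' empirical per-season mean and population SD (default) or against supplied
#' reference parameters.
#'
#' @param data Tibble with a serum column and a season column.
#' @param value_col,season_col Column names.
#' @param reference Optional list with named numeric vectors `mean` and `sd`
#'   per season (e.g. [seasonal_preset()]).
#' @return The tibble with an added `<value_col>_norm` column.
#' @export
#' @examples
#' d <- tibble::tibble(season = "Winter", serum_25ohd = 14)
#' seasonal_normalize(d, reference = seasonal_preset("table"))$serum_25ohd_norm
seasonal_normalize <- function(data, value_col = "serum_25ohd",
                               season_col = "season", reference = NULL) {
  v <- data[[value_col]]
  s <- as.character(data[[season_col]])
  out <- rep(NA_real_, length(v))
  for (season in unique(s)) {
    i <- which(s == season)
    if (is.null(reference)) {
      if (length(i) < 2) {
        abort(paste0("season group '", season, "' has a single observation."))
      }
      mu <- mean(v[i])
      sdv <- sd_pop(v[i])
      if (sdv == 0) abort(paste0("season group '", season, "' has zero variance."))
    } else {
      mu <- reference$mean[[season]]
      sdv <- reference$sd[[season]]
    }
    out[i] <- (v[i] - mu) / sdv
  }
  data[[paste0(value_col, "_norm")]] <- out
  data
}
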
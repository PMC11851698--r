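#' Preprocessing configuration
#'
#' @param iqr_multiplier Fence multiplier for IQR outlier handling.
#' @param outlier_action `"cap"` (replace with the nearer fence) or
#'   `"remove"` (drop the value).
#' @param impute_max_sweeps Maximum chained-equation sweeps.
#' @param impute_tolerance Convergence threshold on the largest absolute
#'   change of any imputed continuous cell between sweeps.
#' @param smote_k_neighbors Number of nearest minority neighbours used by
#'   [smote_nc_balance()].
#' @param seed Integer seed (used by SMOTE-NC interpolation draws).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(iqr_multiplier = 1.5,
                              outlier_action = c("cap", "remove"),
                              impute_max_sweeps = 20,
                              impute_tolerance = 1e-6,
                              smote_k_neighbors = 5,
                              seed = 1L) {
  outlier_action <- match.arg(outlier_action)
  if (iqr_multiplier <= 0) abort("`iqr_multiplier` must be positive.")
  if (smote_k_neighbors < 1) abort("`smote_k_neighbors` must be >= 1.")
  if (impute_max_sweeps < 1) abort("`impute_max_sweeps` must be >= 1.")
  structure(
    list(
      iqr_multiplier = iqr_multiplier, outlier_action = outlier_action,
      impute_max_sweeps = as.integer(impute_max_sweeps),
      impute_tolerance = impute_tolerance,
      smote_k_neighbors = as.integer(smote_k_neighbors),
      seed = as.integer(seed)
    ),
    class = "preprocess_config"
  )
}

#' Chained-equation imputation
#'
#' Fills missing cells of a mixed table. Categorical (character/factor)
#' cells are filled with the column mode (ties broken toward the
#' lexicographically first category). Continuous cells are initialized at
#' the column mean and then refined by iterated regression of each
#' incomplete column on all other columns, sweeping until the largest change
#' falls below `impute_tolerance` or `impute_max_sweeps` is reached. This is
#' a single-imputation variant of MICE: one chained pass to convergence,
#' producing one completed table. Observed cells are never altered.
#'
#' @param data A data frame with `NA`s marking missing cells.
#' @param config A [preprocess_config()].
#' @return List with `data` (completed tibble) and `report` (tibble of
#'   imputed-cell counts per column).
#' @export
impute_chained <- function(data, config = preprocess_config()) {
  data <- tibble::as_tibble(data)
  all_missing <- names(data)[vapply(data, function(x) all(is.na(x)), logical(1))]
  if (nrow(data) > 0 && length(all_missing)) {
    abort(paste0(
      "column(s) entirely missing, cannot impute: ",
      paste(all_missing, collapse = ", ")
    ))
  }
  miss <- lapply(data, is.na)
  n_imputed <- vapply(miss, sum, integer(1))
  is_num <- vapply(data, is.numeric, logical(1))

  # categorical columns: mode fill
  for (cl in names(data)[!is_num]) {
    if (any(miss[[cl]])) {
      fill <- stat_mode(data[[cl]])
      if (is.factor(data[[cl]])) {
        data[[cl]][miss[[cl]]] <- factor(fill, levels = levels(data[[cl]]))
      } else {
        data[[cl]][miss[[cl]]] <- fill
      }
    }
  }

  num_cols <- names(data)[is_num]
  incomplete <- num_cols[vapply(num_cols, function(cl) any(miss[[cl]]), logical(1))]
  if (length(incomplete)) {
    for (cl in incomplete) data[[cl]][miss[[cl]]] <- mean(data[[cl]], na.rm = TRUE)
    others <- function(cl) setdiff(names(data), cl)
    for (sweep in seq_len(config$impute_max_sweeps)) {
      delta <- 0
      for (cl in incomplete) {
        obs <- !miss[[cl]]
        df <- data[, others(cl), drop = FALSE]
        # drop constant predictors to keep lm well-posed
        keep <- vapply(df, function(x) length(unique(x)) > 1, logical(1))
        df <- df[, keep, drop = FALSE]
        if (ncol(df) == 0) next
        fit <- stats::lm(y ~ ., data = cbind(df, y = data[[cl]])[obs, , drop = FALSE])
        pred <- predict(fit, newdata = df[miss[[cl]], , drop = FALSE])
        delta <- max(delta, max(abs(pred - data[[cl]][miss[[cl]]])))
        data[[cl]][miss[[cl]]] <- pred
      }
      if (delta < config$impute_tolerance) break
    }
  }
  list(
    data = data,
    report = tibble::tibble(column = names(n_imputed), cells_imputed = unname(n_imputed))
  )
}

#' Cap or remove outliers by the IQR rule
#'
#' Values outside `[Q1 - m*IQR, Q3 + m*IQR]` (quantiles by linear
#' interpolation, R type 7) are outliers: capped to the nearer fence or
#' removed. Missing values pass through untouched and do not enter the
#' quantile computation.
#'
#' @param values Numeric vector with at least 4 non-missing values.
#' @param config A [preprocess_config()]; `iqr_multiplier` and
#'   `outlier_action` are used.
#' @return List with `values` (same length for `"cap"`, shortened for
#'   `"remove"`) and `n_affected`.
#' @export
#' @examples
#' cap_outliers_iqr(c(1:10, 100))$values
cap_outliers_iqr <- function(values, config = preprocess_config()) {
  obs <- values[!is.na(values)]
  if (length(obs) < 4) abort("need at least 4 non-missing values for IQR fences.")
  q <- quantile(obs, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - config$iqr_multiplier * iqr
  hi <- q[2] + config$iqr_multiplier * iqr
  out_idx <- which(!is.na(values) & (values < lo | values > hi))
  if (config$outlier_action == "cap") {
    values[values < lo & !is.na(values)] <- lo
    values[values > hi & !is.na(values)] <- hi
    list(values = values, n_affected = length(out_idx))
  } else {
    keep <- if (length(out_idx)) values[-out_idx] else values
    list(values = keep, n_affected = length(out_idx))
  }
}

#' Z-score standardization
#'
#' Centers to mean 0 and scales to unit population (n-denominator) SD.
#'
#' @param values Numeric vector; its non-missing part must not be constant.
#' @return Standardized numeric vector.
#' @export
zscore_standardize <- function(values) {
  obs <- values[!is.na(values)]
  s <- sd_pop(obs)
  if (!is.finite(s) || s == 0) {
    abort("column is constant; exclude it rather than standardizing.")
  }
  (values - mean(obs)) / s
}

#' Aggregate raw scores into reporting bands
#'
#' Maps a raw calcium intake score to the three reporting bands `>16`,
#' `1-15`, `0-7` (checked in that order, so values in the 1-7 overlap land
#' in `1-15` and only 0 maps to `0-7`), and collapses milk/fish frequency
#' answers (`Never`/`Rarely` vs anything more frequent) to yes/no. Columns
#' already in banded form pass through unchanged.
#'
#' @param data Tibble with a numeric `calcium_score` column and/or
#'   `milk`/`fish` columns.
#' @return The tibble with `calcium_band` replacing `calcium_score` and
#'   milk/fish collapsed to yes/no.
#' @export
#' @examples
#' aggregate_bins(tibble::tibble(calcium_score = c(20, 10, 0)))
aggregate_bins <- function(data) {
  data <- tibble::as_tibble(data)
  if ("calcium_score" %in% names(data)) {
    x <- data$calcium_score
    band <- rep(NA_character_, length(x))
    band[!is.na(x) & x > 16] <- ">16"
    band[is.na(band) & !is.na(x) & x >= 1 & x <= 15] <- "1-15"
    band[is.na(band) & !is.na(x) & x >= 0 & x <= 7] <- "0-7"
    bad <- !is.na(x) & is.na(band)
    if (any(bad)) {
      abort(paste0(
        "calcium score outside every band: ",
        paste(unique(x[bad]), collapse = ", ")
      ))
    }
    data$calcium_band <- band
    data$calcium_score <- NULL
  }
  freq_no <- c("Never", "Rarely", "no")
  freq_yes <- c("Sometimes", "Often", "Daily", "yes")
  for (cl in intersect(c("milk", "fish"), names(data))) {
    v <- as.character(data[[cl]])
    known <- is.na(v) | v %in% c(freq_no, freq_yes)
    if (!all(known)) {
      abort(paste0("unknown ", cl, " category: ", paste(unique(v[!known]), collapse = ", ")))
    }
    data[[cl]] <- ifelse(is.na(v), NA_character_, ifelse(v %in% freq_no, "no", "yes"))
  }
  data
}

#' Encode a cohort into a numeric design matrix
#'
#' Ordered fields (age, BMI, sun exposure, calcium and AQI bands) become
#' integer codes preserving their order (lowest category is 0). Binary
#' fields become 0/1. Unordered multi-category fields (season) become
#' one-hot indicator blocks. Continuous columns pass through. The returned
#' encoding map makes the transformation invertible via [decode_features()].
#'
#' @param data Cohort tibble (the `severity` and `serum_25ohd` columns, if
#'   present, are excluded from the design matrix).
#' @return List with `X` (numeric tibble) and `map` (encoding description).
#' @export
#' @examples
#' enc <- encode_features(generate_cohort(cohort_config(n_records = 8)))
#' names(enc$X)
encode_features <- function(data) {
  data <- tibble::as_tibble(data)
  vocab <- cohort_vocabularies()
  bin <- binary_fields()
  drop <- intersect(c("severity", "serum_25ohd"), names(data))
  feats <- setdiff(names(data), drop)
  X <- list()
  map <- list()
  for (cl in feats) {
    v <- data[[cl]]
    if (is.numeric(v)) {
      X[[cl]] <- as.numeric(v)
      map[[cl]] <- list(type = "numeric")
    } else {
      v <- as.character(v)
      voc <- vocab[[cl]]
      if (is.null(voc)) voc <- sort(unique(v[!is.na(v)]))
      bad <- !is.na(v) & !(v %in% voc)
      if (any(bad)) {
        abort(paste0(
          "unseen category in `", cl, "`: ",
          paste(unique(v[bad]), collapse = ", ")
        ))
      }
      if (cl %in% ordered_fields()) {
        X[[cl]] <- as.numeric(match(v, voc) - 1)
        map[[cl]] <- list(type = "ordinal", levels = voc)
      } else if (cl %in% names(bin)) {
        X[[cl]] <- as.numeric(v == bin[[cl]])
        map[[cl]] <- list(type = "binary", one = bin[[cl]], levels = voc)
      } else {
        for (lev in voc) X[[paste0(cl, "_", lev)]] <- as.numeric(v == lev)
        map[[cl]] <- list(type = "onehot", levels = voc)
      }
    }
  }
  list(X = tibble::as_tibble(X), map = map)
}

#' @rdname encode_features
#' @param X Encoded numeric tibble as produced by `encode_features()`.
#' @param map The encoding map produced alongside it.
#' @export
decode_features <- function(X, map) {
  out <- list()
  for (cl in names(map)) {
    m <- map[[cl]]
    out[[cl]] <- switch(m$type,
      numeric = X[[cl]],
      ordinal = m$levels[X[[cl]] + 1],
      binary = {
        other <- setdiff(m$levels, m$one)[1]
        ifelse(is.na(X[[cl]]), NA_character_, ifelse(X[[cl]] == 1, m$one, other))
      },
      onehot = {
        block <- as.matrix(X[paste0(cl, "_", m$levels)])
        res <- rep(NA_character_, nrow(block))
        hit <- rowSums(block == 1, na.rm = TRUE) == 1
        res[hit] <- m$levels[max.col(block[hit, , drop = FALSE])]
        res
      }
    )
  }
  tibble::as_tibble(out)
}
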
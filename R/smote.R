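#' SMOTE-NC class balancing for mixed tables
#'
#' Oversamples every minority class up to the majority count using the
#' nominal-continuous SMOTE variant: distances between same-class samples
#' are Euclidean over the continuous columns plus one squared
#' median-of-continuous-SDs penalty per mismatching categorical column. A
#' synthetic row interpolates the continuous features between a minority
#' sample and one of its `k` nearest same-class neighbours (uniform gap) and
#' takes each categorical feature as the most frequent category among those
#' neighbours (ties toward the lexicographically first category). Original
#' rows are preserved verbatim as a prefix of the output.
#'
#' Degenerate compositions fall back gracefully: with no categorical column
#' the procedure is plain SMOTE; with no continuous column synthetic rows
#' take neighbour-majority categories throughout (distance by category
#' mismatch count).
#'
#' @param X Data frame of features (numeric and character/factor columns).
#' @param y Class labels, one per row.
#' @param config A [preprocess_config()]; `smote_k_neighbors` and `seed` are
#'   used.
#' @return List with `X` (balanced feature table), `y` (labels), and
#'   `report` (per-class synthetic-row counts plus the parent-pair log used
#'   for interpolation audits: columns `class`, `parent_a`, `parent_b` row
#'   indices into the original table).
#' @export
smote_nc_balance <- function(X, y, config = preprocess_config()) {
  X <- tibble::as_tibble(X)
  stopifnot(nrow(X) == length(y))
  y <- as.character(y)
  counts <- table(y)
  n_major <- max(counts)
  minority <- names(counts)[counts < n_major]
  report_counts <- tibble::tibble(
    class = names(counts),
    synthetic_rows_added = as.integer(n_major - counts[names(counts)])
  )
  if (length(minority) == 0) {
    return(list(X = X, y = y, report = list(
      synthetic = report_counts,
      parents = tibble::tibble(
        class = character(), parent_a = integer(), parent_b = integer()
      )
    )))
  }
  single <- names(counts)[counts < 2]
  if (length(single)) {
    abort(paste0(
      "class '", single[1], "' has a single sample; SMOTE-NC needs >= 2 ",
      "(duplicate the row first if balancing is still wanted)."
    ))
  }
  is_num <- vapply(X, is.numeric, logical(1))
  num_cols <- names(X)[is_num]
  cat_cols <- names(X)[!is_num]
  med_sd <- if (length(num_cols)) {
    stats::median(vapply(X[num_cols], function(v) sd(v), numeric(1)))
  } else {
    1
  }

  set.seed(derive_seed(config$seed, "smote"))
  synth_X <- list()
  synth_y <- character(0)
  parents <- list()
  for (cl in minority) {
    idx <- which(y == cl)
    sub_num <- as.matrix(X[idx, num_cols, drop = FALSE])
    sub_cat <- as.matrix(X[idx, cat_cols, drop = FALSE])
    m <- length(idx)
    # pairwise SMOTE-NC distances within the class
    d2 <- matrix(0, m, m)
    if (length(num_cols)) {
      for (j in seq_along(num_cols)) {
        d2 <- d2 + outer(sub_num[, j], sub_num[, j], "-")^2
      }
    }
    if (length(cat_cols)) {
      for (j in seq_along(cat_cols)) {
        d2 <- d2 + med_sd^2 * outer(sub_cat[, j], sub_cat[, j], "!=")
      }
    }
    diag(d2) <- Inf
    k <- min(config$smote_k_neighbors, m - 1)
    ord <- apply(d2, 1, function(row) order(row)[seq_len(k)])
    nn <- if (k == 1) matrix(ord, ncol = 1) else t(ord)
    need <- n_major - m
    base_pick <- rep_len(seq_len(m), need)
    for (s in seq_len(need)) {
      a <- base_pick[s]
      nb <- nn[a, , drop = TRUE]
      b <- nb[sample.int(k, 1)]
      gap <- runif(1)
      row <- vector("list", ncol(X))
      names(row) <- names(X)
      for (cn in num_cols) {
        va <- X[[cn]][idx[a]]
        vb <- X[[cn]][idx[b]]
        row[[cn]] <- va + gap * (vb - va)
      }
      for (cn in cat_cols) {
        row[[cn]] <- stat_mode(X[[cn]][idx[nb]])
      }
      synth_X[[length(synth_X) + 1]] <- tibble::as_tibble(row)
      synth_y <- c(synth_y, cl)
      parents[[length(parents) + 1]] <- tibble::tibble(
        class = cl, parent_a = idx[a], parent_b = idx[b]
      )
    }
  }
  out_X <- dplyr::bind_rows(c(list(X), synth_X))
  list(
    X = out_X,
    y = c(y, synth_y),
    report = list(
      synthetic = report_counts,
      parents = dplyr::bind_rows(parents)
    )
  )
}
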
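#' Synthetic feature-selection benchmark
#'
#' Small controlled dataset for studying wrapper feature selection: the
#' first `n_informative` features jointly generate a binary class label (sign
#' of their sum, with optional label-flip noise) and the remaining features
#' are independent standard-normal noise.
#'
#' @param n_rows Number of rows.
#' @param n_features Total feature count.
#' @param n_informative How many leading features carry signal.
#' @param flip_noise Probability of flipping a label.
#' @param seed Integer seed.
#' @return Tibble with features `x1..x<n_features>` and a two-level factor
#'   `class`; the informative feature names are attached as the
#'   `informative` attribute.
#' @export
#' @examples
#' bench <- make_feature_benchmark(n_rows = 40, seed = 1)
#' attr(bench, "informative")
make_feature_benchmark <- function(n_rows = 150, n_features = 8,
                                   n_informative = 3, flip_noise = 0.05,
                                   seed = 1L) {
  if (n_informative < 1 || n_informative > n_features) {
    abort("`n_informative` must lie in 1..n_features.")
  }
  set.seed(derive_seed(seed, "benchmark"))
  X <- matrix(rnorm(n_rows * n_features), n_rows, n_features)
  colnames(X) <- paste0("x", seq_len(n_features))
  score <- rowSums(X[, seq_len(n_informative), drop = FALSE])
  y <- score > 0
  flip <- runif(n_rows) < flip_noise
  y[flip] <- !y[flip]
  out <- tibble::as_tibble(as.data.frame(X))
  out$class <- factor(ifelse(y, "case", "control"), levels = c("case", "control"))
  attr(out, "informative") <- paste0("x", seq_len(n_informative))
  out
}

#' Jaccard similarity of two feature sets
#'
#' @param a,b Character vectors of feature names.
#' @return `|a intersect b| / |a union b|` (0 when both empty).
#' @export
jaccard_similarity <- function(a, b) {
  u <- union(a, b)
  if (length(u) == 0) {
    return(0)
  }
  length(intersect(a, b)) / length(u)
}
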
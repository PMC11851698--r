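#' @importFrom rlang %||% abort warn
#' @importFrom stats predict quantile rnorm runif sd var cor coef optim
#' @importFrom utils head
NULL

#' Derive a named sub-seed from a master seed
#'
#' Stage seeds are derived by hashing the stage name into a fixed offset and
#' combining it with the master seed, so changing one stage's configuration
#' never shifts the random stream consumed by another stage.
#'
#' @param seed Master seed (integer).
#' @param stage Character stage name, e.g. `"generator"`, `"folds"`.
#' @param index Optional integer counter for repeated draws within a stage.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "generator")
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 1009)
  val <- (abs(seed) %% 2147483647) + (h %% 2147483647) + 7919 * (index %% 65536)
  as.integer(val %% 2147483647)
}

# Mode of a vector; ties broken toward the lexicographically first category.
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_character_)
  tab <- table(as.character(x))
  cands <- names(tab)[tab == max(tab)]
  sort(cands)[1]
}

# Population (n-denominator) standard deviation.
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

#' Stratified fold assignment
#'
#' Assigns each observation to one of `k` folds so every class is spread as
#' evenly as possible across folds.
#'
#' @param y Class labels (factor or character).
#' @param k Number of folds.
#' @param seed Integer seed controlling the shuffle.
#' @return Integer vector of fold ids in `1..k`, one per observation.
#' @export
stratified_folds <- function(y, k, seed) {
  y <- as.character(y)
  if (k < 2) abort("`k` must be at least 2.")
  counts <- table(y)
  if (any(counts < k)) {
    abort(paste0(
      "Class '", names(counts)[which.min(counts)], "' has fewer than k = ", k,
      " observations; reduce the number of folds."
    ))
  }
  folds <- integer(length(y))
  set.seed(seed)
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}
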
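test_that("imputation preserves observed cells and fills all gaps", {
  cohort <- inject_missingness(small_cohort(150, seed = 2), 0.08, seed = 3)
  res <- impute_chained(cohort)
  expect_false(anyNA(res$data))
  for (cl in names(cohort)) {
    obs <- !is.na(cohort[[cl]])
    expect_identical(res$data[[cl]][obs], cohort[[cl]][obs])
  }
  expect_equal(
    sum(res$report$cells_imputed),
    sum(vapply(cohort, function(x) sum(is.na(x)), integer(1)))
  )
})

test_that("complete tables pass through imputation unchanged", {
  cohort <- small_cohort(60, seed = 4)
  res <- impute_chained(cohort)
  expect_identical(res$data, cohort)
  expect_equal(sum(res$report$cells_imputed), 0)
})

test_that("an exact linear relation is recovered by chained imputation", {
  set.seed(1)
  x <- rnorm(50)
  d <- tibble::tibble(x = x, y = 2 * x)
  d$y[7] <- NA
  res <- impute_chained(d)
  expect_lt(abs(res$data$y[7] - 2 * x[7]), 1e-6)
})

test_that("categorical gaps take the mode with lexicographic tie-breaks", {
  d <- tibble::tibble(v = c(rep("yes", 7), rep("no", 2), NA))
  expect_equal(impute_chained(d)$data$v[10], "yes")
  tie <- tibble::tibble(v = c("b", "b", "a", "a", NA), w = 1:5)
  expect_equal(impute_chained(tie)$data$v[5], "a")
  expect_error(
    impute_chained(tibble::tibble(a = c(NA_real_, NA_real_), b = c(1, 2))),
    "a"
  )
})

test_that("IQR capping uses type-7 fences and is idempotent", {
  res <- cap_outliers_iqr(c(1:10, 100))
  # Q1 = 3.5, Q3 = 8.5 under linear interpolation -> upper fence 16
  expect_equal(max(res$values), 16)
  expect_equal(res$n_affected, 1)
  again <- cap_outliers_iqr(res$values)
  expect_equal(again$values, res$values)
  expect_equal(again$n_affected, 0)

  allsame <- cap_outliers_iqr(rep(5, 10))
  expect_equal(allsame$values, rep(5, 10))
  expect_equal(allsame$n_affected, 0)

  inside <- cap_outliers_iqr(1:20)
  expect_equal(inside$values, 1:20)

  removed <- cap_outliers_iqr(c(1:10, 100), preprocess_config(outlier_action = "remove"))
  expect_equal(removed$values, 1:10)
  expect_error(cap_outliers_iqr(c(1, 2, 3)), "4")
})

test_that("z-score standardization hits mean 0 / population SD 1 and is idempotent", {
  expect_equal(zscore_standardize(c(1, 2, 3)),
    c(-1, 0, 1) * sqrt(3 / 2),
    tolerance = 1e-12
  )
  set.seed(2)
  x <- rnorm(100, 50, 9)
  z <- zscore_standardize(x)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-9)
  expect_equal(zscore_standardize(z), z, tolerance = 1e-9)
  expect_error(zscore_standardize(rep(2, 5)), "constant")
})

test_that("calcium scores fall into the printed bands in printed order", {
  d <- aggregate_bins(tibble::tibble(calcium_score = c(20, 10, 0, 5, 16.5)))
  expect_equal(d$calcium_band, c(">16", "1-15", "0-7", "1-15", ">16"))
  expect_error(
    aggregate_bins(tibble::tibble(calcium_score = c(2, 15.5))),
    "15.5"
  )
  f <- aggregate_bins(tibble::tibble(milk = c("Never", "Daily"), fish = c("Rarely", "Often")))
  expect_equal(f$milk, c("no", "yes"))
  expect_equal(f$fish, c("no", "yes"))
})

test_that("encoding preserves order, codes binaries, one-hots season, and round-trips", {
  cohort <- small_cohort(100, seed = 8)
  enc <- encode_features(cohort)
  sun <- cohort$sun_exposure
  codes <- enc$X$sun_exposure
  expect_equal(
    codes,
    c(Never = 0, Infrequently = 1, Sometimes = 2, Often = 3, Always = 4)[sun],
    ignore_attr = TRUE
  )
  expect_true(all(enc$X$milk %in% c(0, 1)))
  expect_equal(enc$X$milk, as.numeric(cohort$milk == "yes"))
  season_block <- as.matrix(enc$X[paste0("season_", cohort_vocabularies()$season)])
  expect_true(all(rowSums(season_block) == 1))
  dec <- decode_features(enc$X, enc$map)
  for (cl in names(dec)) {
    expect_equal(as.character(dec[[cl]]), as.character(cohort[[cl]]), label = cl)
  }
  bad <- cohort
  bad$sun_exposure[3] <- "Allways"
  expect_error(encode_features(bad), "sun_exposure.*Allways")
})

test_that("SMOTE-NC balances counts exactly and interpolates within parent segments", {
  cohort <- small_cohort(90, seed = 6)
  keep <- cohort$severity %in% c("Suboptimal", "Inadequate", "ExtremelyInadequate")
  X <- cohort[keep, setdiff(names(cohort), c("severity", "serum_25ohd"))]
  y <- droplevels(cohort$severity[keep])
  res <- smote_nc_balance(X, y, preprocess_config(seed = 2))
  tab <- table(res$y)
  expect_true(all(tab == max(table(y))))
  # originals preserved verbatim as a prefix
  expect_identical(res$X[seq_len(nrow(X)), ], X)
  expect_identical(res$y[seq_len(nrow(X))], as.character(y))
  # synthetic continuous cells lie on their parent segment
  synth_rows <- seq(nrow(X) + 1, nrow(res$X))
  parents <- res$report$parents
  expect_equal(length(synth_rows), nrow(parents))
  for (i in seq_along(synth_rows)) {
    v <- res$X$fdsk_score[synth_rows[i]]
    a <- X$fdsk_score[parents$parent_a[i]]
    b <- X$fdsk_score[parents$parent_b[i]]
    expect_true(v >= min(a, b) - 1e-12 && v <= max(a, b) + 1e-12)
  }
  # categorical synthetic values come from the vocabulary
  vocab <- cohort_vocabularies()
  for (cl in setdiff(names(X), "fdsk_score")) {
    expect_true(all(res$X[[cl]] %in% vocab[[cl]]), label = cl)
  }
})

test_that("SMOTE-NC handles balanced input and degenerate classes", {
  X <- tibble::tibble(a = rnorm(8), b = rep(c("x", "y"), 4))
  y <- rep(c("A", "B"), each = 4)
  res <- smote_nc_balance(X, y)
  expect_identical(res$X, X)
  expect_identical(res$y, y)

  expect_error(
    smote_nc_balance(X, c(rep("A", 7), "B")),
    "single sample"
  )

  counts <- smote_nc_balance(
    tibble::tibble(a = rnorm(14), b = rnorm(14)),
    c(rep("A", 10), rep("B", 4)),
    preprocess_config(seed = 1)
  )
  expect_equal(as.integer(table(counts$y)), c(10, 10))
})
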
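test_that("confusion matrix counts truth/prediction pairs", {
  cm <- confusion_matrix(c(1, 1, 2), c(1, 2, 2), labels = c(1, 2))
  expect_equal(unname(cm$counts), rbind(c(1, 1), c(0, 1)))
  perfect <- confusion_matrix(rep(c("a", "b"), c(3, 2)), rep(c("a", "b"), c(3, 2)))
  expect_equal(unname(diag(perfect$counts)), c(3, 2))
  expect_equal(sum(perfect$counts) - sum(diag(perfect$counts)), 0)
  expect_error(confusion_matrix(c("a"), c("z"), labels = c("a", "b")), "z")
  expect_error(confusion_matrix(1:3, 1:2), "length")
})

test_that("confusion-matrix conservation laws hold on random label vectors", {
  set.seed(10)
  labels <- letters[1:4]
  for (i in 1:100) {
    n <- sample(5:40, 1)
    y <- sample(labels, n, replace = TRUE)
    p <- sample(labels, n, replace = TRUE)
    cm <- confusion_matrix(y, p, labels)
    expect_equal(sum(cm$counts), n)
    expect_equal(unname(rowSums(cm$counts)), unname(table(factor(y, labels))[labels]), ignore_attr = TRUE)
  }
})

test_that("per-class metrics match hand computation and algebraic identities", {
  cm <- confusion_matrix(c(1, 1, 2), c(1, 2, 2), labels = c(1, 2))
  m <- per_class_metrics(cm)
  expect_equal(m$precision[1], 1)
  expect_equal(m$recall[1], 0.5)
  expect_equal(m$f1[1], 2 / 3, tolerance = 1e-12)
  expect_equal(m$accuracy[1], 2 / 3, tolerance = 1e-12)
  expect_equal(attr(m, "overall_accuracy"), 2 / 3, tolerance = 1e-12)

  perfect <- confusion_matrix(rep(c("a", "b"), 3), rep(c("a", "b"), 3))
  mp <- per_class_metrics(perfect)
  expect_true(all(mp$precision == 1 & mp$recall == 1 & mp$f1 == 1 & mp$accuracy == 1))

  # micro-averaged recall equals overall accuracy
  set.seed(2)
  y <- sample(letters[1:3], 60, replace = TRUE)
  p <- sample(letters[1:3], 60, replace = TRUE)
  cmr <- confusion_matrix(y, p, letters[1:3])
  mr <- per_class_metrics(cmr)
  micro_recall <- sum(diag(cmr$counts)) / sum(cmr$counts)
  expect_equal(attr(mr, "overall_accuracy"), micro_recall)
  weighted <- sum(mr$recall * mr$support) / sum(mr$support)
  expect_equal(weighted, micro_recall, tolerance = 1e-12)

  # zero-denominator cells are flagged zeros, not NaN
  cz <- confusion_matrix(c("a", "a"), c("a", "a"), labels = c("a", "b"))
  mz <- per_class_metrics(cz)
  expect_equal(mz$precision[2], 0)
  expect_true(mz$zero_division[2])
})

test_that("cross-validation folds partition rows and aggregate by the mean", {
  cohort <- small_cohort(80, seed = 3)
  rep5 <- crossval_evaluate(
    cohort,
    k = 5, seed = 2,
    fit_predict = function(train, test) {
      # majority-class stub keeps the partition logic in focus
      rep(names(which.max(table(train$severity))), nrow(test))
    }
  )
  expect_equal(nrow(rep5$folds), 5 * 4)
  expect_equal(rep5$mean_accuracy, mean(rep5$fold_accuracy))
  expect_equal(sum(rep5$confusion$counts), nrow(cohort))
  acc_mean <- rep5$summary$accuracy_mean[rep5$summary$class == "Optimal"]
  fold_vals <- rep5$folds$accuracy[rep5$folds$class == "Optimal"]
  expect_equal(acc_mean, mean(fold_vals), tolerance = 1e-12)
})

test_that("leave-one-out evaluation matches a hand-rolled loop", {
  dat <- separable_two_feature(n = 16, seed = 4)
  one_nn <- function(train, test) {
    X <- as.matrix(train[c("x1", "x2")])
    apply(as.matrix(test[c("x1", "x2")]), 1, function(r) {
      as.character(train$severity[which.min(colSums((t(X) - r)^2))])
    })
  }
  rep_loo <- crossval_evaluate(dat, k = nrow(dat), seed = 1, fit_predict = one_nn)
  manual <- vapply(seq_len(nrow(dat)), function(i) {
    one_nn(dat[-i, ], dat[i, ])
  }, character(1))
  expect_equal(
    mean(manual == dat$severity),
    sum(diag(rep_loo$confusion$counts)) / nrow(dat)
  )
})

test_that("correlation report masks the upper triangle and flags |corr| > 0.25", {
  set.seed(5)
  n <- 1e4
  X <- tibble::tibble(a = rnorm(n), b = rnorm(n))
  X$dup <- X$a
  rep <- correlation_report(X)
  expect_true(all(is.na(rep$masked[upper.tri(rep$masked, diag = TRUE)])))
  cells <- rep$cells
  dup_cell <- cells[cells$row == "dup" & cells$column == "a", ]
  expect_equal(dup_cell$correlation, 1)
  expect_true(dup_cell$flagged)
  ab <- cells[cells$row == "b" & cells$column == "a", ]
  expect_lt(abs(ab$correlation), 0.25)
  expect_false(ab$flagged)
  # mask law: retained cells always have row index > column index
  idx_row <- match(cells$row, colnames(rep$full))
  idx_col <- match(cells$column, colnames(rep$full))
  expect_true(all(idx_row > idx_col))

  Xz <- tibble::tibble(a = rnorm(10), z = rep(1, 10))
  rz <- correlation_report(Xz)
  expect_true(is.na(rz$cells$correlation[rz$cells$row == "z"]))
  expect_error(correlation_report(X[1:2, 1, drop = FALSE]), "columns")
})

test_that("seasonal normalization standardizes within season and is idempotent", {
  cohort <- small_cohort(200, seed = 6)
  norm <- seasonal_normalize(cohort)
  for (s in unique(cohort$season)) {
    v <- norm$serum_25ohd_norm[norm$season == s]
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-9)
  }
  # reference parameters: winter 14.0 under mu 12.5, sd 1.5 -> exactly 1
  d <- tibble::tibble(season = "Winter", serum_25ohd = 14)
  expect_equal(
    seasonal_normalize(d, reference = seasonal_preset("table"))$serum_25ohd_norm,
    1
  )
  twice <- seasonal_normalize(
    dplyr::mutate(norm, serum_25ohd = serum_25ohd_norm)
  )
  expect_equal(twice$serum_25ohd_norm, norm$serum_25ohd_norm, tolerance = 1e-9)
  expect_error(
    seasonal_normalize(tibble::tibble(season = c("Winter", "Spring"), serum_25ohd = c(1, 2))),
    "single observation"
  )
})

test_that("report writers and plots produce the expected artifacts", {
  cohort <- small_cohort(60, seed = 2)
  enc <- encode_features(cohort)
  rep <- correlation_report(enc$X[, 1:6])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_correlation_tsv(rep, path)
  lines <- readLines(path)
  expect_equal(length(lines), 1 + choose(6, 2))
  expect_s3_class(autoplot(rep), "ggplot")
  cm <- confusion_matrix(cohort$severity, cohort$severity)
  expect_s3_class(autoplot(cm), "ggplot")
  expect_equal(glance(cm)$overall_accuracy, 1)
  td <- tidy(cm)
  expect_equal(sum(td$count), nrow(cohort))
})
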
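# Exhaustive metrics oracle used by the enumeration test.
metrics_oracle <- function(tp, tn, fp, fn) {
  c(accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NaN)
}

test_that("stratified splitting reproduces the cohort arithmetic", {
  # 57 apnea + 32 normal at 90/10 leaves a 10-subject test set
  cohort <- blob_features(n_per_class = 57, seed = 31)[1:89, ]
  cohort$label <- rep(c("apnea", "normal"), c(57, 32))
  cohort$subject_id <- sprintf("s%02d", 1:89)
  sp <- split_dataset(cohort, train_fraction = 0.9, seed = 1)
  expect_identical(nrow(sp$test), 10L)
  expect_identical(nrow(sp$train), 79L)
  expect_identical(sort(c(sp$train$subject_id, sp$test$subject_id)),
                   sort(cohort$subject_id))

  # determinism for a fixed seed
  sp2 <- split_dataset(cohort, train_fraction = 0.9, seed = 1)
  expect_identical(sp, sp2)
  sp3 <- split_dataset(cohort, train_fraction = 0.9, seed = 2)
  expect_false(identical(sp$test$subject_id, sp3$test$subject_id))

  # stratified proportions within one sample of the global ratio
  f <- blob_features(n_per_class = 50, seed = 32)
  sp <- split_dataset(f, train_fraction = 0.7, seed = 3)
  expect_identical(nrow(sp$test), 30L)
  expect_lte(abs(sum(sp$test$label == "apnea") - 15), 1)

  one_class <- dplyr::filter(f, label == "apnea")
  expect_error(split_dataset(one_class), "both classes")
})

test_that("SVM kernels behave as expected on canonical geometries", {
  sep <- blob_features(n_per_class = 25, shift = 6, seed = 33)
  fit <- train_svm(sep, kernel = "linear")
  expect_identical(mean(predict(fit, sep) == sep$label), 1)

  # XOR arrangement: quadratic kernel beats linear on training accuracy
  xor <- blob_features(n_per_class = 20, shift = 0, sd = 0.3, seed = 34)
  corners <- rbind(matrix(rep(c(0, 0), 10), ncol = 2, byrow = TRUE),
                   matrix(rep(c(4, 4), 10), ncol = 2, byrow = TRUE),
                   matrix(rep(c(0, 4), 10), ncol = 2, byrow = TRUE),
                   matrix(rep(c(4, 0), 10), ncol = 2, byrow = TRUE))
  xor$entropy_delta <- xor$entropy_delta + corners[, 1]
  xor$entropy_theta <- xor$entropy_theta + corners[, 2]
  xor$label <- rep(c("apnea", "normal"), each = 20)
  acc <- function(kernel) {
    mean(predict(train_svm(xor, kernel = kernel), xor) == xor$label)
  }
  expect_gt(acc("poly2"), acc("linear"))

  expect_error(train_svm(dplyr::filter(sep, label == "apnea")), "both classes")
  expect_error(train_svm(sep, kernel = "sigmoid"), "unknown kernel")
})

test_that("SVM standardization statistics come from the training rows only", {
  f <- blob_features(n_per_class = 20, seed = 35)
  sp <- split_dataset(f, train_fraction = 0.8, seed = 1)
  fit <- train_svm(sp$train)
  X <- as.matrix(sp$train[feature_names()])
  expect_equal(fit$center, colMeans(X), tolerance = 1e-12)
  expect_equal(fit$scale, apply(X, 2, sd), tolerance = 1e-12)
  # predictions on one test row are unaffected by the rest of the test set
  p_all <- predict(fit, sp$test)
  p_one <- predict(fit, sp$test[1, ])
  expect_identical(as.character(p_all[1]), as.character(p_one[1]))
})

test_that("random forests report OOB error and shrink it with more trees", {
  sep <- blob_features(n_per_class = 30, shift = 6, seed = 36)
  fit <- train_rf(sep, n_trees = 150, seed = 1)
  expect_lt(fit$oob_error, 0.1)
  expect_identical(nrow(tidy(fit)), 150L)
  expect_identical(glance(fit)$n_trees, 150)

  # ensemble-size property: 150 trees beat a single tree on noisy data
  # in at least 90% of seeded replicates
  noisy <- blob_features(n_per_class = 25, shift = 1.0, sd = 1, seed = 37)
  wins <- vapply(1:20, function(s) {
    e1 <- train_rf(noisy, n_trees = 1, seed = s)$oob_error
    e150 <- train_rf(noisy, n_trees = 150, seed = s)$oob_error
    e150 <= e1
  }, logical(1))
  expect_gte(mean(wins), 0.9)

  # a duplicated prototype per class is reproduced exactly
  proto <- blob_features(n_per_class = 1, shift = 6, seed = 38)
  dup <- dplyr::bind_rows(proto, proto, proto)
  fit <- train_rf(dup, n_trees = 50, seed = 2)
  expect_identical(as.character(predict(fit, dup)), dup$label)

  # determinism
  expect_identical(train_rf(sep, seed = 5)$oob_error,
                   train_rf(sep, seed = 5)$oob_error)
})

test_that("cross-validation is stratified, deterministic and oracle-consistent", {
  sep <- blob_features(n_per_class = 20, shift = 6, seed = 39)
  cv <- cross_validate(sep, "svm", k = 10, seed = 4, kernel = "poly2")
  expect_identical(cv$summary$accuracy, 1)
  expect_identical(nrow(tidy(cv)), 10L)

  # leave-one-out boundary: k == n gives folds of size 1
  loo <- cross_validate(sep, "svm", k = nrow(sep), seed = 4)
  expect_true(all(loo$per_fold$n_test == 1))

  # manual fold-loop oracle with the same fold assignments
  noisy <- blob_features(n_per_class = 100, shift = 1.5, sd = 1, seed = 40)
  k <- 10; seed <- 6
  cv <- cross_validate(noisy, "svm", k = k, seed = seed, kernel = "poly2")
  fold <- apneawave:::stratified_folds(noisy$label, k, seed)
  manual <- vapply(seq_len(k), function(i) {
    fit <- train_svm(noisy[fold != i, ], kernel = "poly2", seed = seed + i)
    mean(predict(fit, noisy[fold == i, ]) == noisy$label[fold == i])
  }, numeric(1))
  expect_lt(abs(mean(manual) - cv$summary$accuracy), 0.05)

  cv2 <- cross_validate(noisy, "svm", k = k, seed = seed, kernel = "poly2")
  expect_identical(cv$per_fold, cv2$per_fold)
  expect_error(cross_validate(sep, "svm", k = 100), "must lie in")
})

test_that("metrics match exhaustive enumeration of small confusion tables", {
  perfect <- compute_metrics(list(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_identical(unlist(perfect), c(accuracy = 1, sensitivity = 1,
                                      specificity = 1))

  m <- compute_metrics(list(tp = 4, fn = 0, tn = 5, fp = 1))
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 5 / 6, tolerance = 1e-12)

  expect_warning(m0 <- compute_metrics(list(tp = 0, fn = 0, tn = 3, fp = 1)),
                 "sensitivity undefined")
  expect_true(is.nan(m0$sensitivity))
  expect_equal(m0$specificity, 0.75)

  for (total in c(1, 5, 12, 20)) {
    got <- list(); want <- list()
    for (tp in 0:total) for (tn in 0:(total - tp)) for (fp in 0:(total - tp - tn)) {
      fn <- total - tp - tn - fp
      m <- suppressWarnings(compute_metrics(list(tp = tp, tn = tn,
                                                 fp = fp, fn = fn)))
      got[[length(got) + 1]] <- unname(unlist(m))
      want[[length(want) + 1]] <- unname(metrics_oracle(tp, tn, fp, fn))
    }
    expect_identical(got, want, info = sprintf("total = %d", total))
  }
})

test_that("confusion counts treat apnea as the positive class", {
  truth <- c("apnea", "apnea", "normal", "normal", "apnea")
  est <- c("apnea", "normal", "normal", "apnea", "apnea")
  cc <- confusion_counts(truth, est)
  expect_identical(cc, list(tp = 2L, tn = 1L, fp = 1L, fn = 1L))
  expect_error(confusion_counts(c("apnea", "bad"), c("apnea", "apnea")))
})
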
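#' @title Classifier training and evaluation
#' @description
#' Binary classification of subjects as sleep apnea vs normal from the
#' 14-feature table, with a support vector machine (linear, radial,
#' polynomial order 2 and 3 kernels) and a random forest (150 trees,
#' out-of-bag error), evaluated by a stratified 90/10 hold-out split and
#' stratified 10-fold cross-validation. The apnea class is the positive
#' class throughout, so sensitivity is the apnea detection rate.
#' @name classify
NULL

check_feature_table <- function(features, require_label = TRUE) {
  needed <- c("subject_id", if (require_label) "label", feature_names())
  missing <- setdiff(needed, names(features))
  if (length(missing)) {
    stop(sprintf("feature table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (require_label) {
    bad <- setdiff(unique(features$label), c("apnea", "normal"))
    if (length(bad)) {
      stop(sprintf("unknown class label(s): %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
  }
  invisible(features)
}

label_factor <- function(x) factor(x, levels = c("apnea", "normal"))

#' Stratified train/test split of a feature table
#'
#' Splits rows into a training and a test set, stratified by class so both
#' classes keep their proportions. The per-class training count is
#' `floor(train_fraction * n_class)`; with the 89-subject cohort
#' (57 apnea / 32 normal) and the default 0.9 fraction this leaves a
#' 10-subject test set. Deterministic for a fixed seed.
#'
#' @param features Feature table with a `label` column.
#' @param train_fraction Fraction of each class assigned to training;
#'   default 0.9.
#' @param stratified Stratify by class (default `TRUE`); when `FALSE` a
#'   simple random split of the pooled rows is drawn.
#' @param seed Integer seed controlling the draw.
#' @return List with tibbles `train` and `test`.
#' @export
split_dataset <- function(features, train_fraction = 0.9, stratified = TRUE,
                          seed = 1L) {
  check_feature_table(features)
  stopifnot(train_fraction > 0, train_fraction < 1)
  classes <- unique(features$label)
  if (length(classes) < 2) {
    stop("both classes must be present to split", call. = FALSE)
  }
  idx <- with_local_seed(seed, {
    if (stratified) {
      unlist(lapply(c("apnea", "normal"), function(cl) {
        rows <- which(features$label == cl)
        n_train <- floor(train_fraction * length(rows))
        sample(rows, n_train)
      }))
    } else {
      sample(nrow(features), floor(train_fraction * nrow(features)))
    }
  })
  list(train = features[sort(idx), , drop = FALSE],
       test = features[setdiff(seq_len(nrow(features)), idx), , drop = FALSE])
}

# Evaluate an expression with a temporary RNG state; restores the caller's
# .Random.seed so pipeline results do not depend on call order.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

svm_kernel_args <- function(kernel, n_features) {
  switch(kernel,
    linear = list(kernel = "linear"),
    rbf = list(kernel = "radial", gamma = 1 / n_features),
    poly2 = list(kernel = "polynomial", degree = 2, gamma = 1 / n_features,
                 coef0 = 1),
    poly3 = list(kernel = "polynomial", degree = 3, gamma = 1 / n_features,
                 coef0 = 1),
    stop(sprintf("unknown kernel '%s'; use linear, rbf, poly2 or poly3", kernel),
         call. = FALSE)
  )
}

#' Train a support vector machine on a feature table
#'
#' Features are standardized (zero mean, unit variance) using statistics
#' from the training rows only — energies span orders of magnitude and
#' would otherwise dominate every kernel distance — then an SVM is fitted
#' with [e1071::svm()]. The polynomial order-2 kernel is the default
#' configuration. Deterministic for fixed data and seed.
#'
#' @param train Training feature table (both classes present).
#' @param kernel One of `"linear"`, `"rbf"`, `"poly2"` (default), `"poly3"`.
#' @param cost Soft-margin cost `C`; default 1.
#' @param seed Integer seed (e1071 draws only for probability models, but a
#'   seed keeps the call reproducible regardless).
#' @return Object of class `apnea_svm` wrapping the fitted model and the
#'   training scaler; use [predict()][predict.apnea_svm()] and
#'   [evaluate_model()].
#' @export
train_svm <- function(train, kernel = "poly2", cost = 1, seed = 1L) {
  check_feature_table(train)
  if (length(unique(train$label)) < 2) {
    stop("training set must contain both classes", call. = FALSE)
  }
  X <- as.matrix(train[feature_names()])
  center <- colMeans(X)
  scale_sd <- apply(X, 2, stats::sd)
  scale_sd[scale_sd == 0] <- 1
  Xs <- scale(X, center = center, scale = scale_sd)
  args <- svm_kernel_args(kernel, ncol(X))
  fit <- with_local_seed(seed, do.call(e1071::svm, c(
    list(x = Xs, y = label_factor(train$label), cost = cost, scale = FALSE),
    args
  )))
  structure(
    list(fit = fit, center = center, scale = scale_sd, kernel = kernel,
         cost = cost, features = feature_names(), n_train = nrow(train)),
    class = "apnea_svm"
  )
}

#' @export
print.apnea_svm <- function(x, ...) {
  cat(sprintf("<apnea_svm> kernel %s, cost %g, %d training subjects, %d SVs\n",
              x$kernel, x$cost, x$n_train, x$fit$tot.nSV))
  invisible(x)
}

#' Predict class labels from a fitted SVM
#'
#' @param object An `apnea_svm`.
#' @param newdata Feature table.
#' @param ... Unused.
#' @return Factor of predicted labels with levels `apnea`, `normal`.
#' @export
predict.apnea_svm <- function(object, newdata, ...) {
  check_feature_table(newdata, require_label = FALSE)
  X <- as.matrix(newdata[object$features])
  Xs <- scale(X, center = object$center, scale = object$scale)
  stats::predict(object$fit, Xs)
}

#' Train a random forest on a feature table
#'
#' Fits [randomForest::randomForest()] with 150 trees by default and
#' reports the out-of-bag (OOB) error estimate alongside the model. The
#' forest receives raw (unstandardized) features: trees split on order
#' statistics and are scale-invariant.
#'
#' @param train Training feature table.
#' @param n_trees Number of trees; default 150.
#' @param seed Integer seed; the forest is deterministic given it.
#' @return Object of class `apnea_rf` with elements `fit` and `oob_error`.
#' @export
train_rf <- function(train, n_trees = 150, seed = 1L) {
  check_feature_table(train)
  stopifnot(n_trees >= 1)
  X <- as.data.frame(train[feature_names()])
  y <- label_factor(train$label)
  if (length(unique(train$label)) < 2) {
    stop("training set must contain both classes", call. = FALSE)
  }
  fit <- with_local_seed(seed,
    randomForest::randomForest(x = X, y = y, ntree = n_trees)
  )
  oob <- as.numeric(fit$err.rate[n_trees, "OOB"])
  structure(
    list(fit = fit, oob_error = oob, n_trees = n_trees,
         features = feature_names(), n_train = nrow(train)),
    class = "apnea_rf"
  )
}

#' @export
print.apnea_rf <- function(x, ...) {
  cat(sprintf("<apnea_rf> %d trees, %d training subjects, OOB error %.3f\n",
              x$n_trees, x$n_train, x$oob_error))
  invisible(x)
}

#' @rdname predict.apnea_svm
#' @export
predict.apnea_rf <- function(object, newdata, ...) {
  check_feature_table(newdata, require_label = FALSE)
  stats::predict(object$fit, as.data.frame(newdata[object$features]))
}

#' Confusion counts of predictions against reference labels
#'
#' Sleep apnea is the positive class: TP counts apnea subjects recognized
#' as apnea, TN normal subjects recognized as normal.
#'
#' @param truth,estimate Vectors of labels in `{apnea, normal}`.
#' @return Named list with integer `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, estimate) {
  truth <- label_factor(as.character(truth))
  estimate <- label_factor(as.character(estimate))
  stopifnot(length(truth) == length(estimate), !anyNA(truth), !anyNA(estimate))
  list(
    tp = sum(truth == "apnea" & estimate == "apnea"),
    tn = sum(truth == "normal" & estimate == "normal"),
    fp = sum(truth == "normal" & estimate == "apnea"),
    fn = sum(truth == "apnea" & estimate == "normal")
  )
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `accuracy = (TP + TN) / total`, `sensitivity = TP / (TP + FN)` (apnea
#' detection rate), `specificity = TN / (TN + FP)`. An undefined ratio
#' (zero denominator) is reported as `NaN` with a warning, never silently
#' as 0.
#'
#' @param counts A list with `tp`, `tn`, `fp`, `fn` (as from
#'   [confusion_counts()]), or `tp` alone with the remaining counts given
#'   separately.
#' @param tn,fp,fn Individual counts when `counts` is the scalar `tp`.
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity` as
#'   proportions in `[0, 1]`.
#' @examples
#' compute_metrics(list(tp = 4, fn = 0, tn = 5, fp = 1))
#' @export
compute_metrics <- function(counts, tn = NULL, fp = NULL, fn = NULL) {
  if (!is.list(counts)) counts <- list(tp = counts, tn = tn, fp = fp, fn = fn)
  stopifnot(all(c("tp", "tn", "fp", "fn") %in% names(counts)))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn > 0)
  sens <- if (tp + fn == 0) {
    warning("sensitivity undefined: no apnea subjects in the test set",
            call. = FALSE)
    NaN
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0) {
    warning("specificity undefined: no normal subjects in the test set",
            call. = FALSE)
    NaN
  } else tn / (tn + fp)
  tibble::tibble(
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = sens,
    specificity = spec
  )
}

#' Evaluate a fitted model on a test set
#'
#' @param model An `apnea_svm` or `apnea_rf`.
#' @param test Labeled feature table.
#' @return One-row tibble with `accuracy`, `sensitivity`, `specificity`,
#'   `tp`, `tn`, `fp`, `fn`, `n_test`.
#' @export
evaluate_model <- function(model, test) {
  check_feature_table(test)
  counts <- confusion_counts(test$label, predict(model, test))
  dplyr::mutate(compute_metrics(counts),
                tp = counts$tp, tn = counts$tn, fp = counts$fp, fn = counts$fn,
                n_test = nrow(test))
}

# Stratified fold assignment: rows are shuffled within class and folds
# cycle continuously across the class blocks, so every fold gets n_c/k
# (+-1) rows of each class and k == n reduces to leave-one-out.
stratified_folds <- function(labels, k, seed) {
  with_local_seed(seed, {
    fold <- integer(length(labels))
    pos <- 0L
    for (cl in unique(labels)) {
      rows <- sample(which(labels == cl))
      fold[rows] <- ((pos + seq_along(rows) - 1L) %% k) + 1L
      pos <- pos + length(rows)
    }
    fold
  })
}

#' Stratified k-fold cross-validation
#'
#' Rows are assigned to `k` stratified folds; for each fold the model is
#' trained on the remainder and evaluated on the held-out fold, and the
#' per-fold metrics are averaged. Standardization for the SVM is refit
#' inside every fold from its training rows only, so no information leaks
#' from the held-out fold. Deterministic for fixed seed.
#'
#' @param features Labeled feature table.
#' @param model `"svm"` or `"rf"`.
#' @param k Number of folds; default 10.
#' @param seed Integer seed driving fold assignment and model fits.
#' @param ... Passed to [train_svm()] or [train_rf()] (e.g. `kernel`,
#'   `n_trees`).
#' @return Object of class `apnea_cv`: list with `per_fold` (tibble, one
#'   row per fold) and `summary` (one-row tibble of mean metrics, `NaN`
#'   folds excluded per metric).
#' @export
cross_validate <- function(features, model = c("svm", "rf"), k = 10,
                           seed = 1L, ...) {
  check_feature_table(features)
  model <- match.arg(model)
  if (k < 2 || k > nrow(features)) {
    stop(sprintf("k = %d must lie in [2, %d]", k, nrow(features)),
         call. = FALSE)
  }
  fold <- stratified_folds(features$label, k, seed)
  trainer <- switch(model, svm = train_svm, rf = train_rf)
  per_fold <- purrr::map(seq_len(k), function(i) {
    train <- features[fold != i, , drop = FALSE]
    test <- features[fold == i, , drop = FALSE]
    if (nrow(test) == 0) return(NULL)
    fit <- trainer(train, seed = seed + i, ...)
    m <- suppressWarnings(evaluate_model(fit, test))
    dplyr::mutate(m, fold = i, .before = 1)
  })
  per_fold <- dplyr::bind_rows(per_fold)
  summary <- dplyr::summarise(
    per_fold,
    accuracy = mean(.data$accuracy),
    sensitivity = mean(.data$sensitivity, na.rm = TRUE),
    specificity = mean(.data$specificity, na.rm = TRUE)
  )
  structure(list(per_fold = per_fold, summary = summary, model = model,
                 k = k, seed = seed),
            class = "apnea_cv")
}

#' @export
print.apnea_cv <- function(x, ...) {
  cat(sprintf("<apnea_cv> %s, %d folds\n", x$model, x$k))
  cat(sprintf("  mean accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              x$summary$accuracy, x$summary$sensitivity, x$summary$specificity))
  invisible(x)
}

#' Tidy per-fold cross-validation metrics
#'
#' @param x An `apnea_cv` object.
#' @param ... Unused.
#' @return Tibble with one row per fold.
#' @method tidy apnea_cv
#' @export
tidy.apnea_cv <- function(x, ...) x$per_fold

#' One-row cross-validation summary
#'
#' @param x An `apnea_cv` object.
#' @param ... Unused.
#' @return One-row tibble of mean metrics.
#' @method glance apnea_cv
#' @export
glance.apnea_cv <- function(x, ...) {
  dplyr::mutate(x$summary, model = x$model, k = x$k, .before = 1)
}

#' @rdname tidy.apnea_cv
#' @method tidy apnea_rf
#' @export
tidy.apnea_rf <- function(x, ...) {
  err <- as.data.frame(x$fit$err.rate)
  tibble::tibble(trees = seq_len(nrow(err)), oob_error = err$OOB)
}

#' @rdname glance.apnea_cv
#' @method glance apnea_rf
#' @export
glance.apnea_rf <- function(x, ...) {
  tibble::tibble(n_trees = x$n_trees, n_train = x$n_train,
                 oob_error = x$oob_error)
}

#' @rdname glance.apnea_cv
#' @method glance apnea_svm
#' @export
glance.apnea_svm <- function(x, ...) {
  tibble::tibble(kernel = x$kernel, cost = x$cost, n_train = x$n_train,
                 n_support_vectors = x$fit$tot.nSV)
}
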
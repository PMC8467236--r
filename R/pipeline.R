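#' @title End-to-end pipeline orchestration
#' @description
#' [run_extract()] and [run_classify()] compose the module-level functions
#' into the full EDF-to-metrics pipeline under a single serializable
#' configuration, writing a feature CSV, a metrics JSON and a run manifest
#' next to each other. [run_pipeline()] chains the two. For a fixed
#' configuration and seed every output is byte-identical across runs. A
#' thin command-line wrapper over these functions ships in
#' `inst/cli/apneawave`.
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' A nested list covering every tunable of the pipeline; override fields
#' via `...` (overrides are merged recursively by name).
#'
#' @param ... Named overrides, e.g. `notch = list(f0 = 60)`,
#'   `seed = 11`.
#' @return Configuration list with components `paths` (`input_dir`,
#'   `labels`, `output_dir`), `channel`, `epoch_seconds`, `notch`
#'   (`enabled`, `f0`, `q`), `wpd` (`wavelet`, `level`), `aggregation`
#'   (`"per-recording"` or `"per-epoch"`), `split` (`train_fraction`,
#'   `stratified`), `svm` (`kernel`, `cost`), `rf` (`n_trees`),
#'   `cv_folds`, `seed`.
#' @export
apnea_config <- function(...) {
  config <- list(
    paths = list(input_dir = NULL, labels = NULL, output_dir = NULL),
    channel = "C3-A2",
    epoch_seconds = 30,
    notch = list(enabled = TRUE, f0 = 50, q = 30),
    wpd = list(wavelet = "db8", level = "auto"),
    aggregation = "per-recording",
    split = list(train_fraction = 0.9, stratified = TRUE),
    svm = list(kernel = "poly2", cost = 1),
    rf = list(n_trees = 150),
    cv_folds = 10,
    seed = 1L
  )
  merge_config(config, list(...))
}

merge_config <- function(base, overrides) {
  for (key in names(overrides)) {
    if (is.list(base[[key]]) && is.list(overrides[[key]])) {
      base[[key]] <- merge_config(base[[key]], overrides[[key]])
    } else {
      base[[key]] <- overrides[[key]]
    }
  }
  base
}

#' Read a pipeline configuration from a YAML file
#'
#' Unspecified keys keep their [apnea_config()] defaults.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  overrides <- yaml::read_yaml(path)
  do.call(apnea_config, overrides)
}

write_manifest <- function(config, path, ...) {
  manifest <- list(
    tool = "apneawave",
    version = as.character(utils::packageVersion("apneawave")),
    config = config,
    ...
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(manifest)
}

#' Run the feature-extraction stage
#'
#' Loads every labeled recording (`<subject_id>.edf` under
#' `paths$input_dir`, labels from the sidecar CSV at `paths$labels`),
#' applies the configured notch and wavelet settings, and writes
#' `features.csv` plus `manifest.json` to `paths$output_dir`. If any
#' recording fails (missing file, missing channel), the rows extracted so
#' far are saved under `output_dir/partial/` and the run stops with an
#' error listing the failing subjects.
#'
#' @param config Configuration list from [apnea_config()] /
#'   [read_config()].
#' @return The feature tibble, invisibly; side effect: files under
#'   `paths$output_dir` (omitted when `output_dir` is `NULL`).
#' @export
run_extract <- function(config = apnea_config()) {
  stopifnot(!is.null(config$paths$input_dir), !is.null(config$paths$labels))
  labels <- read_labels(config$paths$labels)
  message(sprintf("extract: %d labeled subjects from %s",
                  nrow(labels), config$paths$input_dir))
  notch <- if (isTRUE(config$notch$enabled)) {
    list(f0 = config$notch$f0, q = config$notch$q)
  }
  rows <- list()
  failures <- character(0)
  for (i in seq_len(nrow(labels))) {
    sid <- labels$subject_id[i]
    path <- file.path(config$paths$input_dir, paste0(sid, ".edf"))
    res <- tryCatch({
      rec <- read_recording(path, config$channel, subject_id = sid,
                            label = labels$label[i])
      extract_features(rec,
                       epoch_seconds = config$epoch_seconds,
                       notch = notch,
                       wavelet = config$wpd$wavelet,
                       level = config$wpd$level,
                       per_epoch = identical(config$aggregation, "per-epoch"))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", sid, conditionMessage(res)))
    } else {
      rows[[sid]] <- res
    }
  }
  features <- dplyr::bind_rows(rows)
  out <- config$paths$output_dir
  if (length(failures)) {
    if (!is.null(out)) {
      partial <- file.path(out, "partial")
      dir.create(partial, showWarnings = FALSE, recursive = TRUE)
      if (nrow(features) > 0) {
        readr::write_csv(features, file.path(partial, "features.csv"))
      }
    }
    stop(sprintf("extraction failed for %d subject(s):\n  %s",
                 length(failures), paste(failures, collapse = "\n  ")),
         call. = FALSE)
  }
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(features, file.path(out, "features.csv"))
    write_manifest(config, file.path(out, "manifest.json"),
                   n_subjects = nrow(labels), n_rows = nrow(features))
    message(sprintf("extract: wrote %d feature rows to %s",
                    nrow(features), file.path(out, "features.csv")))
  }
  invisible(features)
}

#' Run the classification stage
#'
#' Trains and evaluates both classifiers on a feature table: SVM (the
#' configured kernel) and random forest (with OOB error), each under the
#' configured hold-out split and stratified k-fold cross-validation. The
#' metrics are returned and, when an output directory is configured,
#' written to `metrics.json`.
#'
#' @param config Configuration list.
#' @param features Feature table; read from
#'   `paths$output_dir/features.csv` when omitted.
#' @return List with `svm` and `rf`, each carrying `split` (hold-out
#'   metrics tibble) and `cv` (an `apnea_cv`); `rf` also carries
#'   `oob_error`.
#' @export
run_classify <- function(config = apnea_config(), features = NULL) {
  if (is.null(features)) {
    stopifnot(!is.null(config$paths$output_dir))
    features <- readr::read_csv(file.path(config$paths$output_dir, "features.csv"),
                                col_types = readr::cols())
  }
  check_feature_table(features)
  seed <- as.integer(config$seed)
  split <- split_dataset(features,
                         train_fraction = config$split$train_fraction,
                         stratified = isTRUE(config$split$stratified),
                         seed = seed)
  message(sprintf("classify: %d train / %d test subjects",
                  nrow(split$train), nrow(split$test)))

  svm_fit <- train_svm(split$train, kernel = config$svm$kernel,
                       cost = config$svm$cost, seed = seed)
  svm_split <- evaluate_model(svm_fit, split$test)
  svm_cv <- cross_validate(features, "svm", k = config$cv_folds, seed = seed,
                           kernel = config$svm$kernel, cost = config$svm$cost)

  rf_fit <- train_rf(split$train, n_trees = config$rf$n_trees, seed = seed)
  rf_split <- evaluate_model(rf_fit, split$test)
  rf_cv <- cross_validate(features, "rf", k = config$cv_folds, seed = seed,
                          n_trees = config$rf$n_trees)

  results <- list(
    svm = list(kernel = config$svm$kernel, split = svm_split, cv = svm_cv),
    rf = list(n_trees = config$rf$n_trees, oob_error = rf_fit$oob_error,
              split = rf_split, cv = rf_cv)
  )
  out <- config$paths$output_dir
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(metrics_payload(results), file.path(out, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    message(sprintf("classify: wrote %s", file.path(out, "metrics.json")))
  }
  invisible(results)
}

metrics_payload <- function(results) {
  block <- function(r) {
    out <- list(
      holdout = as.list(r$split[c("accuracy", "sensitivity", "specificity")]),
      cv = c(as.list(r$cv$summary),
             list(per_fold = r$cv$per_fold[c("fold", "accuracy",
                                             "sensitivity", "specificity")]))
    )
    if (!is.null(r$oob_error)) out$oob_error <- r$oob_error
    out
  }
  list(svm = c(list(kernel = results$svm$kernel), block(results$svm)),
       rf = c(list(n_trees = results$rf$n_trees), block(results$rf)))
}

#' Run extraction and classification in one call
#'
#' @param config Configuration list.
#' @return The [run_classify()] result, invisibly.
#' @export
run_pipeline <- function(config = apnea_config()) {
  features <- run_extract(config)
  run_classify(config, features)
}
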
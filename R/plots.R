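#' Box plots of feature distributions by class
#'
#' The standard at-a-glance view of a feature table: one panel per
#' feature, box-and-whisker per class, optionally restricted to a feature
#' family. Log scale is useful for the energy features, which span orders
#' of magnitude.
#'
#' @param features Feature table with a `label` column.
#' @param which `"all"`, `"entropy"`, `"energy"`, or `"ratio"`.
#' @param log_y Use a log10 y axis; default `TRUE` for `"energy"`.
#' @return A ggplot object.
#' @export
plot_feature_distributions <- function(features,
                                       which = c("all", "entropy", "energy",
                                                 "ratio"),
                                       log_y = NULL) {
  check_feature_table(features)
  which <- match.arg(which)
  cols <- switch(which,
    all = feature_names(),
    entropy = grep("^entropy_", feature_names(), value = TRUE),
    energy = grep("^energy_", feature_names(), value = TRUE),
    ratio = grep("_ratio$", feature_names(), value = TRUE)
  )
  if (is.null(log_y)) log_y <- identical(which, "energy")
  long <- tidyr::pivot_longer(features[c("label", cols)],
                              dplyr::all_of(cols),
                              names_to = "feature", values_to = "value")
  long$feature <- factor(long$feature, levels = cols)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$value,
                                          fill = .data$label)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Out-of-bag error versus forest size
#'
#' @param object An `apnea_rf`.
#' @param ... Unused.
#' @return A ggplot object tracing the OOB error as trees accumulate.
#' @method autoplot apnea_rf
#' @export
autoplot.apnea_rf <- function(object, ...) {
  d <- tidy.apnea_rf(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trees, y = .data$oob_error)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "trees", y = "OOB error") +
    ggplot2::theme_minimal()
}

#' Per-fold cross-validation metrics
#'
#' @param object An `apnea_cv`.
#' @param ... Unused.
#' @return A ggplot object with one point per fold and metric.
#' @method autoplot apnea_cv
#' @export
autoplot.apnea_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_fold[c("fold", "accuracy", "sensitivity", "specificity")],
    c("accuracy", "sensitivity", "specificity"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fold, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_x_continuous(breaks = unique(long$fold)) +
    ggplot2::labs(x = "fold", y = NULL) +
    ggplot2::theme_minimal()
}
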
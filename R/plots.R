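#' Plot a precision-recall curve
#'
#' @param object A `pr_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pr_curve
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$recall, .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  subtitle = sprintf("AUC-PR = %.3f", auc_pr(object))) +
    ggplot2::theme_minimal()
}

#' Plot TP/FP rank ECDFs
#'
#' An accumulation whose TP curve rises above the FP curve at low ranks
#' shows that true-positive edges concentrate on strongly non-normal
#' (low combined p-value) gene pairs.
#'
#' @param object A `rank_accumulation`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rank_accumulation
#' @export
autoplot.rank_accumulation <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(ecdf_points(object$r_tp), set = "TP"),
    dplyr::mutate(ecdf_points(object$r_fp), set = "FP"))
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$cum_fraction,
                                   colour = .data$set)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Rank of combined pair p-value",
                  y = "Cumulative fraction", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Benchmark summary figures
#'
#' `plot_auc_by_discretization` shows median AUC-PR per estimator and
#' discretization (one panel per edge density); `plot_auc_by_sample_size`
#' shows the sample-size trend; `plot_class_tpr` compares chain-like
#' (Class I) and hub-attached (Class II) edge TPR distributions.
#'
#' @param records,class_tpr Outputs of [run_benchmark()].
#' @return A ggplot.
#' @export
plot_auc_by_discretization <- function(records) {
  s <- summarize_benchmark(records)
  ggplot2::ggplot(s, ggplot2::aes(.data$discretization, .data$auc_pr_median,
                                  fill = .data$estimator)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(density ~ n_samples, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "Median AUC-PR", fill = "Estimator") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname plot_auc_by_discretization
#' @export
plot_auc_by_sample_size <- function(records) {
  s <- summarize_benchmark(records)
  ggplot2::ggplot(s, ggplot2::aes(.data$n_samples, .data$auc_pr_median,
                                  colour = .data$estimator)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_grid(density ~ discretization,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Sample size", y = "Median AUC-PR",
                  colour = "Estimator") +
    ggplot2::theme_minimal()
}

#' @rdname plot_auc_by_discretization
#' @export
plot_class_tpr <- function(class_tpr) {
  ggplot2::ggplot(class_tpr, ggplot2::aes(.data$estimator, .data$tpr,
                                          fill = .data$edge_class)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_grid(density ~ n_samples, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "Per-edge TPR", fill = "Edge class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
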
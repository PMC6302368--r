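#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the scale-free fit against the hard threshold
#'
#' Line plot of the degree-based (and score-based) fit score over the
#' threshold grid, with the acceptance level marked; the data behind the
#' threshold choice.
#'
#' @param object a `similarity_network` (the curve is computed on the
#'   default grid when not already recorded).
#' @param r2_min horizontal reference level (default 0.8).
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.similarity_network <- function(object, r2_min = 0.8, ...) {
  curve <- object$r2_by_threshold
  if (is.null(curve)) curve <- threshold_curve(object)
  long <- tidyr::pivot_longer(curve, c("r2_degree", "r2_score"),
                              names_to = "mode", values_to = "r2",
                              names_prefix = "r2_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$r2,
                                     colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_hline(yintercept = r2_min, linetype = "dashed") +
    (if (!is.null(object$threshold))
      ggplot2::geom_vline(xintercept = object$threshold, linetype = "dotted")) +
    ggplot2::labs(x = "hard threshold", y = expression(R^2~"fit score"),
                  colour = "binned quantity") +
    ggplot2::theme_minimal()
}

#' Plot module sizes of a partition
#'
#' @param object a `module_partition`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.module_partition <- function(object, ...) {
  df <- tidy(object) |> dplyr::count(.data$module, name = "n_mirnas")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$module), y = .data$n_mirnas)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "module", y = "miRNAs") +
    ggplot2::theme_minimal()
}

#' Plot the largest SGL coefficients by module
#'
#' @param object an `sgl_model`.
#' @param top_n number of features shown (default 25).
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sgl_model <- function(object, top_n = 25, ...) {
  df <- tidy(object) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(estimate = max(abs(.data$estimate)),
                     group = .data$group[1], .groups = "drop") |>
    dplyr::slice_max(.data$estimate, n = top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$term, .data$estimate),
                                   y = .data$estimate,
                                   fill = factor(.data$group))) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "max |coefficient| across classes",
                  fill = "group") +
    ggplot2::theme_minimal()
}

#' Plot precision and recall of ranked biomarkers
#'
#' @param eval_table tibble from [rank_and_evaluate_biomarkers()].
#' @return a ggplot object.
#' @export
plot_precision_recall <- function(eval_table) {
  long <- tidyr::pivot_longer(eval_table, c("precision", "recall"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$k), y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "top-k candidates", y = NULL, fill = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Heatmap of module consistency across analyses
#'
#' @param consistency symmetric NMI matrix from
#'   [module_consistency_matrix()].
#' @return a ggplot object.
#' @export
plot_module_consistency <- function(consistency) {
  df <- tibble::as_tibble(consistency, rownames = "analysis_a") |>
    tidyr::pivot_longer(-"analysis_a", names_to = "analysis_b",
                        values_to = "nmi")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$analysis_a, y = .data$analysis_b,
                                   fill = .data$nmi)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "NMI") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
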
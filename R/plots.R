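# ggplot2 views of the main result types. These return plot objects; the
# pipeline itself exports data tables only.

#' Bar plot of per-sample identification counts
#' @param am An [abundance_matrix()].
#' @return A ggplot object.
#' @export
plot_identification_counts <- function(am) {
  identification_counts(am) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$sample_id, y = .data$n_identified)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "proteins identified") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar plot of per-sample missing-value percentages
#' @inheritParams plot_identification_counts
#' @return A ggplot object.
#' @export
plot_missing_values <- function(am) {
  missing_value_percentages(am) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$sample_id, y = .data$missing_pct)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = NULL, y = "missing values (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Histogram of protein identification coverage
#' @inheritParams plot_identification_counts
#' @return A ggplot object.
#' @export
plot_coverage <- function(am) {
  protein_coverage(am)$histogram |>
    ggplot2::ggplot(ggplot2::aes(x = .data$k, y = .data$n_proteins)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "identified in k samples", y = "proteins") +
    ggplot2::theme_minimal()
}

#' Violin plot of per-group coefficients of variation
#' @inheritParams plot_identification_counts
#' @param samples Sample table covering the matrix columns.
#' @return A ggplot object.
#' @export
plot_group_cv <- function(am, samples) {
  group_cv(am, samples) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$sample_group, y = .data$cv)) +
    ggplot2::geom_violin(fill = "seagreen", alpha = 0.6) +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA) +
    ggplot2::labs(x = NULL, y = "coefficient of variation") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-abundance result
#' @param results A [classify_volcano()] tibble.
#' @return A ggplot object, faceted by comparison.
#' @export
plot_volcano <- function(results) {
  if (is.null(results$volcano_class)) results <- classify_volcano(results)
  ggplot2::ggplot(results, ggplot2::aes(x = .data$log2fc, y = -log10(.data$p_adj),
                                        colour = .data$volcano_class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(down = "royalblue",
                                            not_significant = "grey70",
                                            up = "indianred")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$comparison)) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' PCA score plot
#' @param object A [pca_samples()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.protflow_pca <- function(object, ...) {
  ve <- object$var_explained
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                              label = .data$sample_id)) +
    ggplot2::geom_point(size = 2, colour = "steelblue") +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1L]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ve[2L])) +
    ggplot2::theme_minimal()
}

#' MS-microscopy heatmap
#' @param profile An [ms_microscopy_profile()] tibble.
#' @return A ggplot object.
#' @export
plot_ms_microscopy <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$localization, y = .data$bait,
                                        fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred", limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Run-series metric plot
#' @param series A [time_series_table()] tibble.
#' @param metric One of `"auc"`, `"mean_intensity"`, `"max_intensity"`.
#' @return A ggplot object.
#' @export
plot_run_series <- function(series, metric = c("auc", "mean_intensity", "max_intensity")) {
  metric <- match.arg(metric)
  ggplot2::ggplot(series, ggplot2::aes(x = .data$acquisition_time, y = .data[[metric]])) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "acquisition time", y = metric) +
    ggplot2::theme_minimal()
}
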
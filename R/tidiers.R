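# broom-style accessors for the fitted/derived result objects.

#' Tidy a PCA result
#' @param x A [pca_samples()] object.
#' @param ... Unused.
#' @return Tibble of per-sample scores.
#' @export
tidy.protflow_pca <- function(x, ...) x$scores

#' One-row summary of a PCA result
#' @inheritParams tidy.protflow_pca
#' @return Tibble with sample count and leading variance fractions.
#' @export
glance.protflow_pca <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$scores),
                 n_components = length(x$var_explained),
                 pc1_var = x$var_explained[1L],
                 pc2_var = x$var_explained[min(2L, length(x$var_explained))])
}

#' Tidy a sample clustering
#' @param x A [cluster_samples()] object.
#' @param ... Unused.
#' @return Tibble of merge steps and heights.
#' @export
tidy.protflow_hclust <- function(x, ...) x$merges

#' One-row summary of a sample clustering
#' @inheritParams tidy.protflow_hclust
#' @return Tibble with sample count, linkage and height range.
#' @export
glance.protflow_hclust <- function(x, ...) {
  tibble::tibble(n_samples = length(x$hclust$labels), linkage = x$linkage,
                 min_height = min(x$hclust$height), max_height = max(x$hclust$height))
}

#' One-row summary of a differential-abundance result
#' @param x A [differential_abundance()] tibble (ideally after
#'   [classify_volcano()]).
#' @param ... Unused.
#' @return Tibble with test and class counts per comparison.
#' @export
glance.protflow_da <- function(x, ...) {
  x |>
    dplyr::group_by(.data$comparison) |>
    dplyr::summarise(
      n_proteins = dplyr::n(),
      n_up = if ("volcano_class" %in% names(x)) sum(.data$volcano_class == "up") else NA_integer_,
      n_down = if ("volcano_class" %in% names(x)) sum(.data$volcano_class == "down") else NA_integer_,
      min_p_adj = min(.data$p_adj),
      .groups = "drop"
    )
}
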
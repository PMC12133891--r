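#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_text geom_tile
#'   geom_col labs theme_minimal scale_fill_gradient2 facet_wrap
#' @export
ggplot2::autoplot

#' Scatter plot of an embedding
#'
#' @param object A `wbm_embedding` (PCA or t-SNE).
#' @param label Draw sample labels.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wbm_embedding
#' @export
autoplot.wbm_embedding <- function(object, label = TRUE, ...) {
  co <- object$coordinates
  dims <- names(co)[-1][1:2]
  p <- ggplot(co, aes(x = .data[[dims[1]]], y = .data[[dims[2]]])) +
    geom_point(size = 2) +
    theme_minimal()
  if (object$method == "pca" && !is.null(object$variance_explained)) {
    p <- p + labs(
      x = sprintf("%s (%.1f%%)", dims[1], 100 * object$variance_explained[1]),
      y = sprintf("%s (%.1f%%)", dims[2], 100 * object$variance_explained[2]))
  }
  if (label) {
    p <- p + geom_text(aes(label = .data$sample), vjust = -0.7, size = 3)
  }
  p
}

#' Heatmap of an organ-by-diet exchange flux table
#'
#' Secretion (positive, red) and uptake (negative, blue) of the tracked
#' metabolite per organ and diet.
#'
#' @param object An [organ_contribution_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot organ_flux_table
#' @export
autoplot.organ_flux_table <- function(object, ...) {
  long <- tidy.organ_flux_table(object)
  ggplot(long, aes(x = .data$diet, y = .data$organ, fill = .data$flux)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         midpoint = 0) +
    labs(x = NULL, y = NULL, fill = "flux\n(mmol/day)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar charts of biomarker readouts across diets
#'
#' @param result An [run_intervention()] result.
#' @param metrics Metrics to show (defaults to all in the result).
#' @return A ggplot, faceted by metric and sex.
#' @export
plot_biomarkers <- function(result, metrics = NULL) {
  d <- result$biomarkers
  if (!is.null(metrics)) d <- d[d$metric %in% metrics, ]
  ggplot(d, aes(x = .data$diet, y = .data$value)) +
    geom_col() +
    facet_wrap(~ metric + sex, scales = "free_y") +
    labs(x = NULL, y = "flux readout (mmol/day/person)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
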
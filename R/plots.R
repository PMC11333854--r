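#' Violin plot of per-slice score distributions
#'
#' @param scores [score_cells()] output.
#' @param min_score Optional horizontal rejection line.
#' @return A ggplot.
#' @export
plot_slice_scores <- function(scores, min_score = 5) {
  p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$slice_id, y = .data$total,
                                            fill = .data$slice_id)) +
    ggplot2::geom_violin(scale = "width", show.legend = FALSE) +
    ggplot2::labs(x = "slice", y = "total score") +
    ggplot2::theme_minimal()
  if (!is.null(min_score)) {
    p <- p + ggplot2::geom_hline(yintercept = min_score, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' Spatial scatter coloured by a score or metric
#'
#' @param ds A [spatial_dataset()].
#' @param values Per-cell values aligned with `ds` cells (or a tibble with
#'   `cell_id` and `value`).
#' @param label Colour-bar label.
#' @return A ggplot, faceted by slice.
#' @export
plot_spatial <- function(ds, values, label = "value") {
  cells <- ds$cells
  if (is.data.frame(values)) {
    values <- values$value[match(cells$cell_id, values$cell_id)]
  }
  df <- cells %>% mutate(value = values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$value)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::facet_wrap(~slice_id) +
    ggplot2::scale_colour_viridis_c(name = label) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Density plot of a per-cell metric
#'
#' @param metrics [compute_metrics()] output.
#' @param metric Column to plot (`"n_genes"` or `"n_counts"`).
#' @return A ggplot of the Gaussian KDE.
#' @export
plot_metric_density <- function(metrics, metric = "n_genes") {
  dens <- kde_density(metrics[[metric]])
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line(colour = "#2c3e50") +
    ggplot2::labs(x = metric, y = "density") +
    ggplot2::theme_minimal()
}

#' Scatter of total counts vs genes detected, coloured by mito fraction
#'
#' @param metrics [compute_metrics()] output.
#' @return A ggplot.
#' @export
plot_counts_vs_genes <- function(metrics) {
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$n_genes, y = .data$n_counts,
                                        colour = .data$pct_mito)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::scale_colour_viridis_c(name = "pct_mito") +
    ggplot2::theme_minimal()
}

#' Plot a threshold sweep's retention curves
#'
#' @param object A `qc_sweep`.
#' @param ... Unused.
#' @return A ggplot; per-slice lines for `min_genes` sweeps, the marker
#'   retention curve for `min_cells` sweeps, with target and recommendation
#'   guides when present.
#' @method autoplot qc_sweep
#' @export
autoplot.qc_sweep <- function(object, ...) {
  if (object$type == "min_genes") {
    p <- ggplot2::ggplot(object$curve,
                         ggplot2::aes(x = .data$threshold, y = .data$retention,
                                      colour = .data$slice_id)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "min_genes", y = "fraction of cells retained")
  } else {
    p <- ggplot2::ggplot(object$curve,
                         ggplot2::aes(x = .data$threshold, y = .data$marker_retention)) +
      ggplot2::geom_line(colour = "#2c3e50") +
      ggplot2::geom_point() +
      ggplot2::labs(x = "min_cells", y = "fraction of markers retained")
  }
  if (!is.null(object$recommended)) {
    p <- p + ggplot2::geom_vline(xintercept = object$recommended,
                                 linetype = "dashed", colour = "forestgreen")
  }
  p + ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot before/after score distributions for a run
#'
#' @param object A `qc_run`.
#' @param ... Unused.
#' @return A ggplot comparing the before- and after-filtering score
#'   distributions.
#' @method autoplot qc_run
#' @export
autoplot.qc_run <- function(object, ...) {
  df <- bind_rows(
    object$scores_before %>% mutate(stage = "before"),
    object$scores_after %>% mutate(stage = "after")
  ) %>% mutate(stage = factor(.data$stage, levels = c("before", "after")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$total, fill = .data$stage)) +
    ggplot2::geom_violin(scale = "width", show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "total score") +
    ggplot2::theme_minimal()
}
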
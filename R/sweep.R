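#' Default threshold grid for a min_genes sweep
#'
#' Forty evenly spaced quantiles of the observed `n_genes` distribution
#' (probabilities 1/41 ... 40/41), rounded to integers and deduplicated, so
#' the grid adapts to any platform's depth scale.
#'
#' @param n_genes_values Per-cell `n_genes` vector.
#' @return Strictly ascending integer grid.
#' @export
default_min_genes_grid <- function(n_genes_values) {
  g <- round(stats::quantile(n_genes_values, probs = (1:40) / 41, names = FALSE))
  sort(unique(as.integer(g)))
}

#' Default grid for a min_cells sweep
#' @export
default_min_cells_grid <- c(1L, 2L, 3L, 5L, 10L, 15L, 20L, 30L, 50L)

#' Sweep cell retention against min_genes thresholds
#'
#' For every slice and threshold `t`, records the fraction of that slice's
#' cells with `n_genes >= t` — exact counting, no sampling. Run on the
#' dataset after slice filtering so invalid slices do not distort the
#' recommendation.
#'
#' @param ds Dataset (after slice filtering).
#' @param metrics Per-cell metrics covering at least the cells of `ds`.
#' @param grid Strictly ascending non-negative thresholds; defaults to
#'   [default_min_genes_grid()] of the dataset's cells.
#' @return A `qc_sweep` object with `type = "min_genes"` and a `curve`
#'   tibble (`slice_id`, `threshold`, `retention`).
#' @export
sweep_min_genes <- function(ds, metrics, grid = NULL) {
  m <- metrics[match(ds$cells$cell_id, metrics$cell_id), , drop = FALSE]
  grid <- grid %||% default_min_genes_grid(m$n_genes)
  check_grid(grid)
  curve <- tidyr::expand_grid(slice_id = unique(m$slice_id), threshold = grid) %>%
    left_join(m %>% select("slice_id", "n_genes"), by = "slice_id",
              relationship = "many-to-many") %>%
    group_by(.data$slice_id, .data$threshold) %>%
    summarise(retention = mean(.data$n_genes >= .data$threshold), .groups = "drop")
  structure(list(type = "min_genes", grid = grid, curve = curve),
            class = "qc_sweep")
}

check_grid <- function(grid) {
  if (!length(grid)) stop_config("threshold grid is empty")
  if (any(grid < 0) || is.unsorted(grid, strictly = TRUE)) {
    stop_config("threshold grid must be strictly ascending and non-negative")
  }
  invisible(grid)
}

#' Recommend min_genes from a retention sweep
#'
#' Returns the largest grid value at which more than `target` of each
#' slice's cells survive in at least `slice_fraction` of slices (strict
#' inequalities). When no grid value qualifies, falls back to the smallest
#' grid value with `warning = TRUE`.
#'
#' @param sweep A `qc_sweep` from [sweep_min_genes()].
#' @param target Per-slice retention target (default 0.70).
#' @param slice_fraction Fraction of slices that must hit the target
#'   (default 0.90, i.e. "most" slices).
#' @return The `qc_sweep` with fields `recommended`, `rule`, `warning`.
#' @export
recommend_min_genes <- function(sweep, target = 0.70, slice_fraction = 0.90) {
  ok <- sweep$curve %>%
    group_by(.data$threshold) %>%
    summarise(frac_ok = mean(.data$retention > target), .groups = "drop") %>%
    filter(.data$frac_ok >= slice_fraction)
  if (nrow(ok)) {
    sweep$recommended <- max(ok$threshold)
    sweep$warning <- FALSE
  } else {
    sweep$recommended <- min(sweep$grid)
    sweep$warning <- TRUE
    warn(sprintf(
      "no grid value keeps >%.0f%% of cells in %.0f%% of slices; falling back to min_genes=%s",
      100 * target, 100 * slice_fraction, format(sweep$recommended)))
  }
  sweep$rule <- sprintf("largest t with retention > %.2f in >= %.2f of slices",
                        target, slice_fraction)
  sweep
}

#' Sweep marker retention against min_cells thresholds
#'
#' For every threshold `t`, records the fraction of the marker set detected
#' in at least `t` cells (denominator: the full marker set) and the total
#' genes that would be retained. Run on the dataset after cell filtering,
#' where gene detection is finally counted.
#'
#' @param ds Dataset (after cell filtering).
#' @param markers Marker symbols; required.
#' @param grid Ascending thresholds (default [default_min_cells_grid]).
#' @return A `qc_sweep` with `type = "min_cells"` and a `curve` tibble
#'   (`threshold`, `marker_retention`, `genes_retained`).
#' @export
sweep_min_cells <- function(ds, markers, grid = default_min_cells_grid) {
  if (is.null(markers) || !length(markers)) {
    stop_config(paste0(
      "markers are disabled: marker retention cannot be swept; ",
      "set min_cells manually"))
  }
  check_grid(grid)
  det <- Matrix::colSums(ds$counts > 0)
  marker_det <- det[intersect(markers, colnames(ds$counts))]
  curve <- tibble(
    threshold = as.numeric(grid),
    marker_retention = vapply(grid, function(t) sum(marker_det >= t) / length(markers),
                              numeric(1)),
    genes_retained = vapply(grid, function(t) sum(det >= t), numeric(1))
  )
  structure(list(type = "min_cells", grid = grid, curve = curve,
                 n_markers = length(markers)),
            class = "qc_sweep")
}

#' Recommend min_cells from a marker-retention sweep
#'
#' Largest grid value retaining more than `target` of the marker set
#' (strict `>`); fallback to the smallest grid value with a warning.
#'
#' @param sweep A `qc_sweep` from [sweep_min_cells()].
#' @param target Marker retention target (default 0.99).
#' @return The `qc_sweep` with `recommended`, `rule`, `warning` fields.
#' @export
recommend_min_cells <- function(sweep, target = 0.99) {
  ok <- sweep$curve %>% filter(.data$marker_retention > target)
  if (nrow(ok)) {
    sweep$recommended <- max(ok$threshold)
    sweep$warning <- FALSE
  } else {
    sweep$recommended <- min(sweep$grid)
    sweep$warning <- TRUE
    warn(sprintf(
      "no grid value retains >%.0f%% of markers; falling back to min_cells=%s",
      100 * target, format(sweep$recommended)))
  }
  sweep$rule <- sprintf("largest t with marker retention > %.2f", target)
  sweep
}

#' @export
print.qc_sweep <- function(x, ...) {
  cat(sprintf("<qc_sweep> %s over %d thresholds", x$type, length(x$grid)))
  if (!is.null(x$recommended)) {
    cat(sprintf("; recommended %s%s", format(x$recommended),
                if (isTRUE(x$warning)) " (fallback)" else ""))
  }
  cat("\n")
  invisible(x)
}
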
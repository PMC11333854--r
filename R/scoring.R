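#' Build the default scoring rubric from a metrics table
#'
#' Each of the five metrics maps to a sub-score in \{0, 1, 2\}; the total is
#' their sum, 0-10, with 5 (half the maximum) the default slice rejection
#' boundary. Depth-like metrics (`n_genes`, `n_counts`, `marker_ratio`) are
#' scored against quantiles pooled over the whole pre-filter dataset —
#' pooling keeps slice medians comparable across slices: at or above the
#' median scores 2, at or above the lower quartile 1, else 0 (inclusive
#' boundaries). `pct_mito` uses fixed thresholds: `<= 0.05` scores 2,
#' `<= 0.10` scores 1, above that 0, so a cell at exactly the 10% removal
#' boundary is not failing. The doublet sub-score is 0 for called doublets,
#' 2 for clean cells with score below half the call threshold, 1 otherwise.
#' A disabled metric contributes a constant 2, keeping the 0-10 scale and
#' the meaning of the median-5 boundary.
#'
#' @param metrics [compute_metrics()] output on the full pre-filter dataset.
#' @param markers_enabled,doublets_enabled Which optional metrics are active.
#' @param doublet_threshold Call threshold from [score_doublets()]
#'   (default 0.25 when scoring was skipped).
#' @param mito_cuts Two increasing fixed cutoffs for `pct_mito`.
#' @return A `qc_rubric` object (serialisable with [rubric_to_json()]).
#' @export
default_rubric <- function(metrics, markers_enabled = "marker_ratio" %in% names(metrics),
                           doublets_enabled = TRUE, doublet_threshold = 0.25,
                           mito_cuts = c(0.05, 0.10)) {
  qcut <- function(v) unname(stats::quantile(v, c(0.25, 0.5)))
  rubric <- list(
    n_genes = qcut(metrics$n_genes),
    n_counts = qcut(metrics$n_counts),
    mito = mito_cuts,
    marker_ratio = if (markers_enabled) qcut(metrics$marker_ratio) else NULL,
    doublet_threshold = doublet_threshold,
    markers_enabled = markers_enabled,
    doublets_enabled = doublets_enabled,
    max_total = 10
  )
  structure(rubric, class = "qc_rubric")
}

#' @export
print.qc_rubric <- function(x, ...) {
  cat("<qc_rubric> sub-scores 0-2 per metric, total 0-10\n")
  cat(sprintf("  n_genes cuts: >=%.6g -> 1, >=%.6g -> 2\n", x$n_genes[1], x$n_genes[2]))
  cat(sprintf("  n_counts cuts: >=%.6g -> 1, >=%.6g -> 2\n", x$n_counts[1], x$n_counts[2]))
  cat(sprintf("  pct_mito: <=%.3g -> 2, <=%.3g -> 1, else 0\n", x$mito[1], x$mito[2]))
  if (x$markers_enabled)
    cat(sprintf("  marker_ratio cuts: >=%.6g -> 1, >=%.6g -> 2\n",
                x$marker_ratio[1], x$marker_ratio[2]))
  else cat("  marker_ratio: disabled (constant 2)\n")
  if (x$doublets_enabled)
    cat(sprintf("  doublet: called -> 0; score < %.3g -> 2; else 1\n",
                x$doublet_threshold / 2))
  else cat("  doublet: disabled (constant 2)\n")
  invisible(x)
}

score_quantile_metric <- function(v, cuts) {
  ifelse(v >= cuts[2], 2L, ifelse(v >= cuts[1], 1L, 0L))
}

#' Score every cell against a rubric
#'
#' @param metrics Per-cell metrics (with doublet columns filled if doublet
#'   scoring is enabled).
#' @param rubric A `qc_rubric` built on this dataset by [default_rubric()].
#' @return A tibble with one row per cell: the five sub-scores
#'   (`s_n_genes`, `s_n_counts`, `s_pct_mito`, `s_marker`, `s_doublet`) and
#'   `total`, plus `cell_id` and `slice_id`.
#' @export
score_cells <- function(metrics, rubric) {
  s_mito <- ifelse(metrics$pct_mito <= rubric$mito[1], 2L,
                   ifelse(metrics$pct_mito <= rubric$mito[2], 1L, 0L))
  s_marker <- if (rubric$markers_enabled) {
    score_quantile_metric(metrics$marker_ratio, rubric$marker_ratio)
  } else rep(2L, nrow(metrics))
  s_doublet <- if (rubric$doublets_enabled) {
    ifelse(metrics$is_doublet, 0L,
           ifelse(metrics$doublet_score < rubric$doublet_threshold / 2, 2L, 1L))
  } else rep(2L, nrow(metrics))
  out <- tibble(
    cell_id = metrics$cell_id,
    slice_id = metrics$slice_id,
    s_n_genes = score_quantile_metric(metrics$n_genes, rubric$n_genes),
    s_n_counts = score_quantile_metric(metrics$n_counts, rubric$n_counts),
    s_pct_mito = as.integer(s_mito),
    s_marker = as.integer(s_marker),
    s_doublet = as.integer(s_doublet)
  )
  out$total <- out$s_n_genes + out$s_n_counts + out$s_pct_mito +
    out$s_marker + out$s_doublet
  out
}

#' Per-slice score summary
#'
#' Exact medians (mean of the central pair for even slice sizes); these are
#' what the slice-level filter compares against `min_score`.
#'
#' @param scores Output of [score_cells()].
#' @return A tibble with `slice_id`, `n_cells`, `median_total`.
#' @export
slice_score_summary <- function(scores) {
  if (nrow(scores) == 0) stop_data("no cells to summarise")
  scores %>%
    group_by(.data$slice_id) %>%
    summarise(n_cells = n(), median_total = stats::median(.data$total),
              .groups = "drop")
}

#' Serialise a rubric to JSON
#'
#' @param rubric A `qc_rubric`.
#' @param path Optional file to write to.
#' @return The JSON string, invisibly when written to a file.
#' @export
rubric_to_json <- function(rubric, path = NULL) {
  js <- jsonlite::toJSON(unclass(rubric), auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
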
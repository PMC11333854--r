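#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a pipeline run into a per-step tibble
#'
#' @param x A `qc_run`.
#' @param ... Unused.
#' @return A tibble with one row per filtering step: `step`, `unit`,
#'   `examined`, `removed`, `retained`.
#' @method tidy qc_run
#' @export
tidy.qc_run <- function(x, ...) {
  r <- x$report
  tibble(
    step = c("slice", "cell", "gene"),
    unit = c("slices", "cells", "genes"),
    examined = c(nrow(r$slice), r$cell$examined, r$gene$examined),
    removed = c(sum(r$slice$removed), r$cell$removed, r$gene$removed),
    retained = c(sum(!r$slice$removed), r$cell$retained, r$gene$retained)
  )
}

#' One-row summary of a pipeline run
#'
#' @param x A `qc_run`.
#' @param ... Unused.
#' @return A one-row tibble: input/output sizes, thresholds used, marker
#'   retention and the Welch before/after p-value.
#' @method glance qc_run
#' @export
glance.qc_run <- function(x, ...) {
  tibble(
    cells_in = x$report$input$cells, cells_out = x$report$output$cells,
    genes_in = x$report$input$genes, genes_out = x$report$output$genes,
    slices_in = x$report$input$slices, slices_out = x$report$output$slices,
    min_score = x$cfg$min_score, min_genes = x$cfg$min_genes,
    max_mito = x$cfg$max_mito, min_cells = x$cfg$min_cells,
    marker_retention = x$report$gene$marker_retention,
    median_score_before = x$comparison$median_before,
    median_score_after = x$comparison$median_after,
    p_value = x$comparison$p_value
  )
}

#' Tidy a threshold sweep
#'
#' @param x A `qc_sweep`.
#' @param ... Unused.
#' @return The sweep's retention curve as a tibble.
#' @method tidy qc_sweep
#' @export
tidy.qc_sweep <- function(x, ...) as_tibble(x$curve)

#' One-row summary of a sweep recommendation
#'
#' @param x A `qc_sweep` after `recommend_*()`.
#' @param ... Unused.
#' @return A one-row tibble: `type`, `recommended`, `rule`, `fallback`.
#' @method glance qc_sweep
#' @export
glance.qc_sweep <- function(x, ...) {
  tibble(type = x$type,
         recommended = x$recommended %||% NA_real_,
         rule = x$rule %||% NA_character_,
         fallback = isTRUE(x$warning))
}

#' Tidy a doublet result into per-cell scores
#'
#' @param x A `doublet_result`.
#' @param ... Unused.
#' @return The per-cell score tibble.
#' @method tidy doublet_result
#' @export
tidy.doublet_result <- function(x, ...) x$scores

#' One-row summary of a doublet result
#'
#' @param x A `doublet_result`.
#' @param ... Unused.
#' @return A one-row tibble: cells, calls, threshold, mean score, k used.
#' @method glance doublet_result
#' @export
glance.doublet_result <- function(x, ...) {
  tibble(n_cells = nrow(x$scores), n_called = sum(x$scores$is_doublet),
         threshold = x$threshold, mean_score = mean(x$scores$doublet_score),
         k = x$k, expected_rate = x$expected_rate)
}
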
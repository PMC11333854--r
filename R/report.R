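#' Summarise a dataset for the report header
#'
#' @param ds A [spatial_dataset()].
#' @param metrics [compute_metrics()] output for `ds`.
#' @param markers Marker symbols, or `NULL` (marker fields are then omitted).
#' @param platform Platform name to echo.
#' @return A list: totals (`cells`, `genes`, `slices`, optionally
#'   `markers`, `platform`) plus `per_slice`, a tibble of per-slice cell
#'   counts and metric medians.
#' @export
summarize_dataset <- function(ds, metrics, markers = NULL, platform = NULL) {
  per_slice <- metrics %>%
    group_by(.data$slice_id) %>%
    summarise(n_cells = n(),
              median_n_genes = stats::median(.data$n_genes),
              median_n_counts = stats::median(.data$n_counts),
              median_pct_mito = stats::median(.data$pct_mito),
              .groups = "drop")
  out <- list(cells = n_cells(ds), genes = n_genes(ds),
              slices = length(slice_levels(ds)))
  if (!is.null(markers)) out$markers <- length(markers)
  if (!is.null(platform)) out$platform <- platform
  out$per_slice <- per_slice
  out
}

#' Welch two-sample comparison of cell scores
#'
#' Unequal-variance (Welch) two-sided t-test on the before- vs
#' after-filtering total-score vectors:
#' \eqn{t = (\bar x_1 - \bar x_2)/\sqrt{s_1^2/n_1 + s_2^2/n_2}} with
#' Welch-Satterthwaite degrees of freedom. Identical groups (zero pooled
#' standard error, equal means) return `t = 0`, `p = 1`.
#'
#' @param before,after Numeric score vectors, each of length >= 2.
#' @return A one-row tibble: `t_statistic`, `df`, `p_value`,
#'   `mean_before`, `mean_after`, `median_before`, `median_after`.
#' @export
compare_scores <- function(before, after) {
  if (length(before) < 2 || length(after) < 2) {
    stop_data("score comparison needs at least 2 values per group")
  }
  n1 <- length(before); n2 <- length(after)
  m1 <- mean(before); m2 <- mean(after)
  v1 <- stats::var(before); v2 <- stats::var(after)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    t_stat <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    df <- NA_real_
    p <- if (m1 == m2) 1 else 0
  } else {
    t_stat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  tibble(t_statistic = t_stat, df = df, p_value = p,
         mean_before = m1, mean_after = m2,
         median_before = stats::median(before), median_after = stats::median(after))
}

# ---- report bundle ---------------------------------------------------------

subsample_idx <- function(n, cap = 50000L) {
  if (n <= cap) seq_len(n) else round(seq(1, n, length.out = cap))
}

per_slice_xyv <- function(cells, values, cap = 50000L) {
  split_idx <- split(seq_len(nrow(cells)), cells$slice_id)
  lapply(split_idx, function(idx) {
    pick <- idx[subsample_idx(length(idx), cap)]
    out <- list(x = cells$x[pick], y = cells$y[pick])
    if (is.data.frame(values)) {
      out <- c(out, lapply(values, function(v) v[pick]))
    } else {
      out$value <- values[pick]
    }
    out$subsampled <- length(pick) < length(idx)
    out
  })
}

#' Assemble the report bundle for a pipeline run
#'
#' Collects the 14 report sections (data summary, quality visualisations,
#' parameter assessment, before/after comparison, configuration echo and
#' per-slice drill-down) as plain data, ready to embed as JSON islands.
#' Spatial scatters are capped at 50 000 points per slice for
#' responsiveness (flagged when subsampled).
#'
#' @param run A `qc_run` from [run_pipeline()].
#' @param ds The input dataset the run was computed on.
#' @param markers Marker symbols used (or `NULL`).
#' @return A `report_bundle`: list with `summary`, `sections` (named list of
#'   14 sections, each `list(id, title, type, data)`), `slices`.
#' @export
build_report_bundle <- function(run, ds, markers = NULL) {
  metrics <- run$metrics
  scores <- run$scores_before
  cells <- ds$cells
  ord <- match(cells$cell_id, metrics$cell_id)
  metrics <- metrics[ord, , drop = FALSE]
  scores <- scores[match(cells$cell_id, scores$cell_id), , drop = FALSE]

  summary <- summarize_dataset(ds, metrics, markers = markers,
                               platform = run$cfg$platform)
  sections <- list()
  add <- function(id, title, type, data) {
    sections[[id]] <<- list(id = id, title = title, type = type, data = data)
  }

  add("summary", "Data summary", "table", list(
    rows = list(
      c("Cells/spots (input)", format(summary$cells)),
      c("Genes (input)", format(summary$genes)),
      c("Slices", format(summary$slices)),
      c("Markers", if (is.null(markers)) "disabled" else format(length(markers))),
      c("Platform", run$cfg$platform),
      c("Cells/spots (output)", format(run$report$output$cells)),
      c("Genes (output)", format(run$report$output$genes)))))

  add("slice_scores", "Slice score distributions", "violin", list(
    groups = lapply(split(scores$total, scores$slice_id), as.numeric),
    min_score = run$cfg$min_score,
    ylab = "total score"))

  add("spatial_total", "Spatial total score", "spatial", list(
    slices = per_slice_xyv(cells, scores$total),
    value_label = "total score"))

  sub_tbl <- scores %>% select("s_n_genes", "s_n_counts", "s_pct_mito",
                               "s_marker", "s_doublet")
  add("spatial_subscores", "Spatial sub-scores", "spatial_multi", list(
    slices = per_slice_xyv(cells, sub_tbl),
    channels = names(sub_tbl)))

  kde_section <- function(vals_before, vals_after, lab) {
    before <- tryCatch(kde_density(vals_before), error = function(e) NULL)
    after <- tryCatch(kde_density(vals_after), error = function(e) NULL)
    list(
      series = Filter(Negate(is.null), list(
        before = if (!is.null(before)) list(x = before$x, y = before$density),
        after = if (!is.null(after)) list(x = after$x, y = after$density))),
      xlab = lab, ylab = "density")
  }
  add("kde_n_genes", "Density of genes detected", "kde",
      kde_section(metrics$n_genes, run$metrics_after$n_genes, "n_genes"))
  add("kde_n_counts", "Density of total counts", "kde",
      kde_section(metrics$n_counts, run$metrics_after$n_counts, "n_counts"))

  pick <- subsample_idx(nrow(metrics))
  add("counts_vs_genes", "Total counts vs genes detected", "scatter", list(
    x = metrics$n_genes[pick], y = metrics$n_counts[pick],
    color = metrics$pct_mito[pick],
    xlab = "n_genes", ylab = "n_counts", color_label = "pct_mito"))

  if (run$cfg$doublets_enabled && !is.null(run$doublets)) {
    add("doublets", "Doublet scores", "hist", list(
      values = metrics$doublet_score,
      threshold = run$doublets$threshold,
      called = sum(metrics$is_doublet), xlab = "doublet score"))
  } else {
    add("doublets", "Doublet scores", "disabled", list(
      note = "doublet calling disabled for this platform"))
  }

  mg <- run$sweeps$min_genes %||%
    recommend_min_genes(sweep_min_genes(ds, run$metrics),
                        target = run$cfg$cell_retention_target,
                        slice_fraction = run$cfg$slice_majority_fraction)
  add("sweep_min_genes", "Cell retention vs min_genes", "sweep_lines", list(
    series = lapply(split(mg$curve, mg$curve$slice_id), function(d) {
      list(x = d$threshold, y = d$retention)
    }),
    recommended = mg$recommended, target = run$cfg$cell_retention_target,
    xlab = "min_genes", ylab = "fraction of cells retained"))

  if (!is.null(markers) && run$cfg$markers_enabled) {
    mc <- run$sweeps$min_cells %||%
      recommend_min_cells(sweep_min_cells(run$dataset, markers),
                          target = run$cfg$marker_retention_target)
    add("sweep_min_cells", "Marker retention vs min_cells", "sweep_lines", list(
      series = list(markers = list(x = mc$curve$threshold,
                                   y = mc$curve$marker_retention)),
      recommended = mc$recommended, target = run$cfg$marker_retention_target,
      xlab = "min_cells", ylab = "fraction of markers retained"))
  } else {
    add("sweep_min_cells", "Marker retention vs min_cells", "disabled", list(
      note = "markers disabled; min_cells was set manually"))
  }

  rep <- run$report
  add("waterfall", "Filtering waterfall", "waterfall", list(
    steps = list(
      list(label = "input cells", value = rep$input$cells),
      list(label = "after slice filter", value = rep$cell$examined),
      list(label = "after cell filter", value = rep$cell$retained),
      list(label = "input genes", value = rep$input$genes),
      list(label = "after gene filter", value = rep$gene$retained)),
    causes = rep$cell$causes))

  cmp <- run$comparison
  add("comparison", "Cell scores before vs after filtering", "comparison", list(
    before = as.numeric(run$scores_before$total),
    after = as.numeric(run$scores_after$total),
    t_statistic = cmp$t_statistic, p_value = cmp$p_value,
    median_before = cmp$median_before, median_after = cmp$median_after))

  cfg_show <- run$cfg[c("platform", "min_score", "min_genes", "max_mito",
                        "min_cells", "cell_retention_target",
                        "marker_retention_target", "markers_enabled",
                        "doublets_enabled", "mito_enabled")]
  add("config", "Configuration", "table", list(
    rows = lapply(names(cfg_show), function(k) c(k, format(cfg_show[[k]] %||% "auto")))))

  add("slice_detail", "Per-slice details", "table", list(
    header = c("slice", "cells", "median n_genes", "median n_counts",
               "median pct_mito", "median score", "removed"),
    rows = {
      ps <- summary$per_slice
      sl <- run$report$slice
      lapply(seq_len(nrow(ps)), function(i) {
        j <- match(ps$slice_id[i], sl$slice_id)
        c(ps$slice_id[i], format(ps$n_cells[i]),
          format(ps$median_n_genes[i]), format(ps$median_n_counts[i]),
          format(signif(ps$median_pct_mito[i], 3)),
          format(sl$median_total[j]),
          ifelse(isTRUE(sl$removed[j]), "yes", "no"))
      })
    }))

  structure(list(summary = summary, sections = sections,
                 slices = unique(cells$slice_id)),
            class = "report_bundle")
}

# ---- HTML rendering --------------------------------------------------------

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render the interactive HTML QC report
#'
#' Writes a single self-contained HTML document: a navigation bar with one
#' button per section (14 sections), a slice drop-down for the spatial
#' panels, and per-section figures rendered client-side to SVG from JSON
#' data islands embedded in the document. No external network resource is
#' referenced; identical inputs produce byte-identical output except for
#' the generation timestamp.
#'
#' @param bundle A `report_bundle` from [build_report_bundle()].
#' @param path Output `.html` path.
#' @return `path`, invisibly.
#' @export
build_report <- function(bundle, path) {
  if (!dir.exists(dirname(path))) {
    stop_data(sprintf("cannot write report to '%s': directory does not exist", path))
  }
  secs <- bundle$sections
  stopifnot(length(secs) == 14)
  buttons <- paste0(vapply(secs, function(s) sprintf(
    '<button class="nav-btn" role="button" data-target="sec-%s">%s</button>',
    s$id, html_escape(s$title)), character(1)), collapse = "\n")
  panels <- paste0(vapply(secs, function(s) {
    json <- jsonlite::toJSON(s$data, auto_unbox = TRUE, digits = NA,
                             null = "null", na = "null")
    sprintf(paste0(
      '<section class="panel" id="sec-%s"><h2>%s</h2>',
      '<script type="application/json" id="data-sec-%s">%s</script>',
      '<div class="fig" data-type="%s" data-source="data-sec-%s"></div></section>'),
      s$id, html_escape(s$title), s$id, json, s$type, s$id)
  }, character(1)), collapse = "\n")
  slice_options <- paste0(
    '<option value="__all__">all slices</option>',
    paste0(sprintf('<option value="%s">%s</option>',
                   html_escape(bundle$slices), html_escape(bundle$slices)),
           collapse = ""))
  stamp <- format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")
  html <- paste0(
    "<!DOCTYPE html>\n<html lang=\"en\"><head><meta charset=\"utf-8\">",
    "<title>Spatial QC report</title>\n<style>\n", report_css(), "\n</style></head>\n",
    "<body>\n<header><h1>Spatial QC report</h1>",
    "<p class=\"timestamp\">Generated: ", stamp, "</p></header>\n",
    "<nav id=\"nav\">", buttons,
    "\n<label for=\"slice-select\">slice:</label>",
    "<select id=\"slice-select\">", slice_options, "</select></nav>\n",
    "<main>\n", panels, "\n</main>\n",
    "<script>\n", report_js(), "\n</script>\n</body></html>\n")
  writeLines(html, path, useBytes = TRUE)
  invisible(path)
}

report_css <- function() {
  paste(
    "body{font-family:sans-serif;margin:0;background:#fafafa;color:#222}",
    "header{background:#2c3e50;color:#fff;padding:8px 16px}",
    "header h1{margin:0;font-size:20px} .timestamp{margin:2px 0;font-size:11px;color:#bcd}",
    "#nav{display:flex;flex-wrap:wrap;gap:4px;padding:8px;background:#ecf0f1;align-items:center}",
    ".nav-btn{border:1px solid #7f8c8d;background:#fff;border-radius:4px;padding:4px 8px;cursor:pointer;font-size:12px}",
    ".nav-btn.active{background:#2c3e50;color:#fff}",
    ".panel{display:none;padding:12px 16px} .panel.visible{display:block}",
    ".panel h2{font-size:16px} .fig svg{background:#fff;border:1px solid #ddd}",
    "table.rpt{border-collapse:collapse} table.rpt td,table.rpt th{border:1px solid #ccc;padding:3px 8px;font-size:13px}",
    sep = "\n")
}

report_js <- function() {
  # minimal dependency-free SVG renderer for the section types
  paste(readLines(system.file("report", "report.js", package = "spotcheck")),
        collapse = "\n")
}
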
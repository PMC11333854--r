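#' Platform presets
#'
#' Per-platform defaults for the filtering configuration. `stereo-seq`
#' targets 70% cell retention per slice when recommending `min_genes` and
#' keeps doublet calling on; `slide-seq` ships the permissive depth defaults
#' appropriate for shallow bead arrays (min_genes 340, max_mito 0.2);
#' `visium` spots are multi-cell so doublet calling is off; `merfish` probe
#' panels rarely include mitochondrial genes so mito scoring is disabled;
#' `generic` uses the base defaults. Every preset value is overridable.
#' @export
platform_presets <- list(
  "stereo-seq" = list(cell_retention_target = 0.70, doublets_enabled = TRUE),
  "slide-seq"  = list(min_genes = 340L, max_mito = 0.2, doublets_enabled = TRUE),
  "visium"     = list(doublets_enabled = FALSE, max_mito = 0.10),
  "merfish"    = list(mito_enabled = FALSE, doublets_enabled = TRUE),
  "generic"    = list()
)

#' Build a filtering configuration
#'
#' Collects every threshold the three-step filter uses. `min_genes = NULL`
#' or `min_cells = NULL` means "recommend from a retention sweep at run
#' time" ([recommend_min_genes()], [recommend_min_cells()]); recommending
#' `min_cells` needs markers, so markers disabled together with an unset
#' `min_cells` is a configuration error.
#'
#' @param platform One of `r paste(names(platform_presets), collapse=", ")`.
#' @param min_score Slice filter: a slice is removed when the median cell
#'   score falls below this (strict `<`; default 5 = half the maximum).
#' @param min_genes Cell filter: minimum genes detected per cell
#'   (`NULL` = recommend).
#' @param max_mito Cell filter: maximum mitochondrial fraction (default 0.10,
#'   inclusive: exactly 0.10 survives).
#' @param min_cells Gene filter: minimum cells a gene must be detected in
#'   (`NULL` = recommend from marker retention).
#' @param cell_retention_target Fraction of each slice's cells the
#'   recommended `min_genes` must preserve (default 0.70, strict `>`).
#' @param slice_majority_fraction Fraction of valid slices that must hit the
#'   retention target (default 0.90).
#' @param marker_retention_target Fraction of the marker set the recommended
#'   `min_cells` must preserve (default 0.99, strict `>`).
#' @param markers_enabled,doublets_enabled,mito_enabled Toggle optional
#'   metrics; a disabled metric scores a constant 2 and its filter is skipped.
#' @param mito_prefixes,mito_genes Mitochondrial gene detection rule, as in
#'   [compute_metrics()].
#' @param sim_ratio,expected_rate Doublet-scorer parameters.
#' @return A `filter_config` list.
#' @export
filter_config <- function(platform = "generic",
                          min_score = 5,
                          min_genes = NULL,
                          max_mito = 0.10,
                          min_cells = NULL,
                          cell_retention_target = 0.70,
                          slice_majority_fraction = 0.90,
                          marker_retention_target = 0.99,
                          markers_enabled = TRUE,
                          doublets_enabled = TRUE,
                          mito_enabled = TRUE,
                          mito_prefixes = default_mito_prefixes,
                          mito_genes = NULL,
                          sim_ratio = 2,
                          expected_rate = 0.06) {
  platform <- match.arg(platform, names(platform_presets))
  cfg <- list(platform = platform, min_score = min_score, min_genes = min_genes,
              max_mito = max_mito, min_cells = min_cells,
              cell_retention_target = cell_retention_target,
              slice_majority_fraction = slice_majority_fraction,
              marker_retention_target = marker_retention_target,
              markers_enabled = markers_enabled,
              doublets_enabled = doublets_enabled,
              mito_enabled = mito_enabled,
              mito_prefixes = mito_prefixes, mito_genes = mito_genes,
              sim_ratio = sim_ratio, expected_rate = expected_rate)
  preset <- platform_presets[[platform]]
  explicit <- names(as.list(match.call()))
  for (k in names(preset)) {
    if (!k %in% explicit) cfg[[k]] <- preset[[k]]
  }
  for (f in c("max_mito", "cell_retention_target", "slice_majority_fraction",
              "marker_retention_target")) {
    if (cfg[[f]] <= 0 || cfg[[f]] > 1) {
      stop_config(sprintf("%s must lie in (0, 1]", f))
    }
  }
  if (!is.null(cfg$min_genes) && cfg$min_genes < 0) stop_config("min_genes must be >= 0")
  if (!is.null(cfg$min_cells) && cfg$min_cells < 0) stop_config("min_cells must be >= 0")
  structure(cfg, class = "filter_config")
}

validate_config <- function(cfg, markers) {
  if ((is.null(markers) || !cfg$markers_enabled) && is.null(cfg$min_cells)) {
    stop_config(paste0(
      "markers are disabled, so min_cells cannot be recommended from marker ",
      "retention: the 'min_cells' parameter must be specified"))
  }
  invisible(cfg)
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>", x$platform, "\n")
  cat(sprintf("  min_score=%s min_genes=%s max_mito=%s min_cells=%s\n",
              x$min_score, x$min_genes %||% "auto", x$max_mito,
              x$min_cells %||% "auto"))
  cat(sprintf("  markers=%s doublets=%s mito=%s\n", x$markers_enabled,
              x$doublets_enabled, x$mito_enabled))
  invisible(x)
}

# ---- Step 1: slice filter --------------------------------------------------

#' Slice-level filter
#'
#' Removes every slice whose median cell score is strictly below
#' `min_score`; all cells of surviving slices are kept for the later steps.
#'
#' @param ds A [spatial_dataset()].
#' @param scores [score_cells()] output covering all cells of `ds`.
#' @param min_score Rejection boundary (default 5).
#' @return A list with `dataset` (filtered), `report` (tibble of slices with
#'   `median_total`, `n_cells`, `removed`).
#' @export
filter_slices <- function(ds, scores, min_score = 5) {
  med <- slice_score_summary(scores %>% filter(.data$cell_id %in% ds$cells$cell_id))
  med$removed <- med$median_total < min_score
  if (all(med$removed)) {
    stop_data(sprintf(
      "all %d slices fall below min_score=%s; reduce min_score and re-run",
      nrow(med), format(min_score)))
  }
  bad <- med$slice_id[med$removed]
  keep <- !(ds$cells$slice_id %in% bad)
  list(dataset = subset_dataset(ds, cells = keep), report = med)
}

# ---- Step 2: cell filter ---------------------------------------------------

#' Cell-level filter
#'
#' A cell survives iff `n_genes >= min_genes`, `pct_mito <= max_mito` (when
#' mito scoring is enabled) and it is not a called doublet (when doublet
#' calling is enabled). Removal causes are tallied non-exclusively: a cell
#' failing two rules counts in both tallies.
#'
#' @param ds Dataset after slice filtering.
#' @param metrics Per-cell metrics covering `ds`.
#' @param cfg A [filter_config()] with `min_genes` resolved (non-NULL).
#' @return A list with `dataset` and `report` (examined/removed/retained and
#'   per-cause counts).
#' @export
filter_cells <- function(ds, metrics, cfg) {
  m <- metrics[match(ds$cells$cell_id, metrics$cell_id), , drop = FALSE]
  if (is.null(cfg$min_genes)) stop_config("min_genes is unset; recommend or specify it")
  fail_genes <- m$n_genes < cfg$min_genes
  fail_mito <- if (cfg$mito_enabled) m$pct_mito > cfg$max_mito else rep(FALSE, nrow(m))
  fail_doublet <- if (cfg$doublets_enabled) m$is_doublet else rep(FALSE, nrow(m))
  keep <- !(fail_genes | fail_mito | fail_doublet)
  causes <- c(low_n_genes = sum(fail_genes), high_pct_mito = sum(fail_mito),
              doublet = sum(fail_doublet))
  if (!any(keep)) {
    stop_data(paste0(
      "no cells survive the cell filter (",
      paste(names(causes), causes, sep = "=", collapse = ", "),
      "); relax min_genes/max_mito"))
  }
  list(dataset = subset_dataset(ds, cells = keep),
       report = list(examined = nrow(m), removed = sum(!keep),
                     retained = sum(keep), causes = as.list(causes),
                     min_genes = cfg$min_genes, max_mito = cfg$max_mito))
}

# ---- Step 3: gene filter ---------------------------------------------------

#' Gene-level filter
#'
#' Keeps genes detected (count > 0) in at least `min_cells` cells, counted
#' on the post-cell-filter matrix. Records the fraction of the marker set
#' retained. An empty surviving gene set is reported, not raised, so
#' parameter sweeps can explore freely.
#'
#' @param ds Dataset after cell filtering.
#' @param markers Marker symbols or `NULL`.
#' @param min_cells Detection threshold (inclusive `>=`).
#' @return A list with `dataset` and `report` (gene tallies and
#'   `marker_retention`).
#' @export
filter_genes <- function(ds, markers = NULL, min_cells) {
  det <- Matrix::colSums(ds$counts > 0)
  keep <- det >= min_cells
  marker_retention <- NA_real_
  if (!is.null(markers) && length(markers)) {
    kept_genes <- colnames(ds$counts)[keep]
    marker_retention <- sum(markers %in% kept_genes) / length(markers)
  }
  list(dataset = subset_dataset(ds, genes = keep),
       report = list(examined = length(det), removed = sum(!keep),
                     retained = sum(keep), min_cells = min_cells,
                     marker_retention = marker_retention))
}

# ---- Orchestration ---------------------------------------------------------

#' Run the full three-step QC pipeline
#'
#' Computes metrics and (optionally) doublet scores on the input, fits the
#' scoring rubric on the full pre-filter dataset, then applies the three
#' sequential filters: slice (median score), cell (min_genes / max_mito /
#' doublets), gene (min_cells). Unset `min_genes`/`min_cells` are
#' recommended from retention sweeps. Post-filter cells are re-measured on
#' the cleaned matrix and scored with the *pre-filter* rubric so the
#' before/after comparison reflects the filtering, not re-centred quantiles.
#'
#' @param ds A [spatial_dataset()].
#' @param markers Marker symbols (or `NULL`; then `markers_enabled` is
#'   forced off).
#' @param cfg A [filter_config()].
#' @param seed Integer seed for the doublet simulator.
#' @param doublet_result Optional precomputed [score_doublets()] result; pass
#'   it to hold the stochastic step fixed across runs.
#' @return A `qc_run` object: `dataset` (cleaned), `report` (per-step
#'   tallies), `scores_before`/`scores_after`, `metrics`, `rubric`,
#'   `sweeps`, `comparison` (Welch test on totals), `cfg`.
#' @export
run_pipeline <- function(ds, markers = NULL, cfg = filter_config(), seed = 0,
                         doublet_result = NULL) {
  if (is.null(markers)) cfg$markers_enabled <- FALSE
  validate_config(cfg, markers)
  mk <- if (cfg$markers_enabled) markers else NULL

  metrics <- compute_metrics(ds, markers = mk, mito_prefixes = cfg$mito_prefixes,
                             mito_genes = cfg$mito_genes)
  dres <- NULL
  if (cfg$doublets_enabled) {
    dres <- doublet_result %||%
      score_doublets(ds$counts, sim_ratio = cfg$sim_ratio,
                     expected_rate = cfg$expected_rate, seed = seed)
    metrics <- add_doublet_scores(metrics, dres)
  }
  rubric <- default_rubric(metrics,
                           markers_enabled = cfg$markers_enabled,
                           doublets_enabled = cfg$doublets_enabled,
                           doublet_threshold = if (is.null(dres)) 0.25 else dres$threshold,
                           mito_cuts = if (cfg$mito_enabled) c(0.05, 0.10) else c(Inf, Inf))
  scores_before <- score_cells(metrics, rubric)

  step1 <- filter_slices(ds, scores_before, min_score = cfg$min_score)

  sweeps <- list()
  if (is.null(cfg$min_genes)) {
    sw <- sweep_min_genes(step1$dataset, metrics)
    rec <- recommend_min_genes(sw, target = cfg$cell_retention_target,
                               slice_fraction = cfg$slice_majority_fraction)
    sweeps$min_genes <- rec
    cfg$min_genes <- rec$recommended
  }
  step2 <- filter_cells(step1$dataset, metrics, cfg)

  if (is.null(cfg$min_cells)) {
    sw <- sweep_min_cells(step2$dataset, mk)
    rec <- recommend_min_cells(sw, target = cfg$marker_retention_target)
    sweeps$min_cells <- rec
    cfg$min_cells <- rec$recommended
  }
  step3 <- filter_genes(step2$dataset, mk, min_cells = cfg$min_cells)

  clean <- step3$dataset
  metrics_after <- compute_metrics(clean, markers = mk,
                                   mito_prefixes = cfg$mito_prefixes,
                                   mito_genes = cfg$mito_genes)
  if (cfg$doublets_enabled) {
    metrics_after <- add_doublet_scores(metrics_after, dres)
  }
  scores_after <- score_cells(metrics_after, rubric)
  comparison <- compare_scores(scores_before$total, scores_after$total)

  report <- list(
    slice = step1$report, cell = step2$report, gene = step3$report,
    input = list(cells = n_cells(ds), genes = n_genes(ds),
                 slices = length(slice_levels(ds))),
    output = list(cells = n_cells(clean), genes = n_genes(clean),
                  slices = length(slice_levels(clean)))
  )
  structure(list(dataset = clean, report = report,
                 scores_before = scores_before, scores_after = scores_after,
                 metrics = metrics, metrics_after = metrics_after,
                 rubric = rubric, sweeps = sweeps, doublets = dres,
                 comparison = comparison, cfg = cfg),
            class = "qc_run")
}

#' @export
print.qc_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("<qc_run> %d/%d cells, %d/%d genes, %d/%d slices retained\n",
              r$output$cells, r$input$cells, r$output$genes, r$input$genes,
              r$output$slices, r$input$slices))
  cat(sprintf("  min_score=%s min_genes=%s max_mito=%s min_cells=%s\n",
              x$cfg$min_score, x$cfg$min_genes, x$cfg$max_mito, x$cfg$min_cells))
  cat(sprintf("  before/after median score: %.1f -> %.1f (Welch p=%.3g)\n",
              x$comparison$median_before, x$comparison$median_after,
              x$comparison$p_value))
  invisible(x)
}

#' Serialise a filter report as JSON
#'
#' @param run A `qc_run` object.
#' @param path Optional output path.
#' @return JSON string (invisibly when written).
#' @export
filter_report_json <- function(run, path = NULL) {
  rep <- run$report
  rep$slice <- as.list(rep$slice)
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
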
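#' Default mitochondrial gene-name prefixes
#'
#' Covers human/mouse (`MT-`, `mt-`, `Mt-`) and Drosophila (`mt:`)
#' nomenclature. Matching is case-sensitive; pass an explicit `mito_genes`
#' list to override prefix detection entirely.
#' @export
default_mito_prefixes <- c("MT-", "mt-", "mt:", "Mt-")

mito_gene_index <- function(gene_names, mito_prefixes, mito_genes = NULL) {
  if (!is.null(mito_genes)) {
    return(which(gene_names %in% mito_genes))
  }
  pat <- paste0("^(", paste(escape_regex(mito_prefixes), collapse = "|"), ")")
  which(stringr::str_detect(gene_names, pat))
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Compute per-cell QC metrics
#'
#' One row per cell: `n_genes` (genes with nonzero count), `n_counts` (total
#' molecules), `pct_mito` (fraction of counts from mitochondrial genes; 0 for
#' all-zero cells), and, when a marker set is supplied, `marker_ratio` (the
#' fraction of the marker set detected in the cell). `doublet_score` and
#' `is_doublet` are initialised to 0/`FALSE` and filled in by
#' [score_doublets()] / [add_doublet_scores()].
#'
#' @param ds A [spatial_dataset()].
#' @param markers Character vector of marker symbols, or `NULL` to disable
#'   marker scoring.
#' @param mito_prefixes Gene-name prefixes marking mitochondrial genes
#'   (case-sensitive).
#' @param mito_genes Optional explicit mitochondrial gene list overriding the
#'   prefixes.
#' @return A tibble with columns `cell_id`, `slice_id`, `n_genes`,
#'   `n_counts`, `pct_mito`, (`marker_ratio`,) `doublet_score`, `is_doublet`.
#' @export
#' @examples
#' sim <- generate_dataset(synthetic_config(n_slices = 2, cells_per_slice = 50,
#'                                          n_genes = 200, n_markers = 20, seed = 1))
#' head(compute_metrics(sim$dataset, markers = sim$truth_markers))
compute_metrics <- function(ds, markers = NULL,
                            mito_prefixes = default_mito_prefixes,
                            mito_genes = NULL) {
  counts <- ds$counts
  nc <- Matrix::rowSums(counts)
  ng <- Matrix::rowSums(counts > 0)
  mi <- mito_gene_index(colnames(counts), mito_prefixes, mito_genes)
  mito_counts <- if (length(mi)) Matrix::rowSums(counts[, mi, drop = FALSE]) else rep(0, nrow(counts))
  pct_mito <- ifelse(nc > 0, mito_counts / nc, 0)

  out <- tibble(
    cell_id = ds$cells$cell_id,
    slice_id = ds$cells$slice_id,
    n_genes = as.integer(ng),
    n_counts = as.numeric(nc),
    pct_mito = as.numeric(pct_mito)
  )
  if (!is.null(markers)) {
    present <- intersect(markers, colnames(counts))
    if (!length(present)) {
      stop_data(sprintf(
        "none of the %d marker genes are present in the dataset (overlap 0); check symbol case/species",
        length(markers)))
    }
    det <- Matrix::rowSums(counts[, present, drop = FALSE] > 0)
    out$marker_ratio <- as.numeric(det) / length(markers)
  }
  out$doublet_score <- 0
  out$is_doublet <- FALSE
  out
}

#' Gaussian kernel density estimate
#'
#' Gaussian kernel with Silverman's rule-of-thumb bandwidth, evaluated on an
#' explicit grid (default: 512 points spanning the data range padded by three
#' bandwidths). Used for the report's depth/complexity density panels, where
#' a second mode flags a background (non-tissue) population.
#'
#' @param values Numeric vector, at least two distinct finite values.
#' @param grid Evaluation points; computed from the data when `NULL`.
#' @param n_grid Grid size when `grid` is `NULL`.
#' @return A tibble with columns `x` (grid) and `density`.
#' @export
kde_density <- function(values, grid = NULL, n_grid = 512) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    stop_data("kernel density needs at least 2 finite values")
  }
  bw <- if (stats::sd(values) > 0) stats::bw.nrd0(values) else 0
  if (!is.finite(bw) || bw <= 0) {
    abort("constant input: degenerate bandwidth; plot a spike instead",
          class = c("spotcheck_degenerate_density", "spotcheck_data_error"))
  }
  if (is.null(grid)) {
    grid <- seq(min(values) - 3 * bw, max(values) + 3 * bw, length.out = n_grid)
  }
  # mean of N(value, bw) kernels at each grid point
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, mean = values, sd = bw)),
                 numeric(1))
  tibble(x = as.numeric(grid), density = dens)
}

#' Count modes of a gridded density
#'
#' A mode is a strict interior local maximum whose height is at least
#' `min_height_frac` of the global maximum; the floor suppresses numerical
#' ripples in the tail.
#'
#' @param density_tbl Output of [kde_density()] (columns `x`, `density`).
#' @param min_height_frac Minimum relative height of a countable mode.
#' @return Integer number of modes.
#' @export
count_modes <- function(density_tbl, min_height_frac = 0.05) {
  d <- density_tbl$density
  if (length(d) < 3) return(as.integer(length(d) > 0))
  interior <- 2:(length(d) - 1)
  is_max <- d[interior] > d[interior - 1] & d[interior] > d[interior + 1]
  tall <- d[interior] >= min_height_frac * max(d)
  sum(is_max & tall)
}
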
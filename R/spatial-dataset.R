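#' Construct a spatial dataset
#'
#' The container every pipeline stage consumes and produces: a sparse
#' cells-by-genes matrix of raw counts plus per-cell spatial coordinates and a
#' slice (tissue-section) label. Counts are never transformed by the pipeline;
#' filtering only selects rows and columns.
#'
#' @param counts A non-negative integer matrix or `Matrix::dgCMatrix`,
#'   cells in rows, genes in columns.
#' @param cell_ids Character vector of unique cell/spot identifiers.
#' @param x,y Numeric spatial coordinates per cell (platform units).
#' @param slice_id Character (or factor) slice label per cell.
#' @param gene_names Character vector of unique gene symbols.
#' @param metadata Named list of free-form strings (platform, source path).
#'
#' @return An object of class `spatial_dataset`: a list with elements
#'   `counts` (dgCMatrix with dimnames), `cells` (tibble with columns
#'   `cell_id`, `x`, `y`, `slice_id`) and `metadata`.
#' @export
#' @examples
#' m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 3), x = c(5, 1), dims = c(2, 3))
#' ds <- spatial_dataset(m, c("c1", "c2"), x = c(0, 1), y = c(0, 1),
#'                       slice_id = c("s1", "s1"), gene_names = c("g1", "g2", "g3"))
#' n_cells(ds)
spatial_dataset <- function(counts, cell_ids, x, y, slice_id, gene_names,
                            metadata = list()) {
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  cell_ids <- as.character(cell_ids)
  gene_names <- as.character(gene_names)
  slice_id <- as.character(slice_id)
  dimnames(counts) <- list(cell_ids, gene_names)
  ds <- structure(
    list(
      counts = counts,
      cells = tibble(cell_id = cell_ids, x = as.numeric(x), y = as.numeric(y),
                     slice_id = slice_id),
      metadata = metadata
    ),
    class = "spatial_dataset"
  )
  validate_spatial_dataset(ds)
}

#' Validate a spatial dataset's invariants
#'
#' Checks matrix/annotation shape agreement, uniqueness of cell and gene
#' identifiers, non-negative integral counts, and finite coordinates.
#'
#' @param ds A `spatial_dataset`.
#' @return `ds`, invisibly unchanged, or an error describing the violation.
#' @export
validate_spatial_dataset <- function(ds) {
  counts <- ds$counts
  cells <- ds$cells
  if (nrow(counts) != nrow(cells)) {
    stop_structural(sprintf(
      "count matrix has %d rows but %d cells are annotated",
      nrow(counts), nrow(cells)))
  }
  if (anyDuplicated(cells$cell_id)) {
    dup <- cells$cell_id[duplicated(cells$cell_id)][1]
    stop_structural(sprintf("duplicate cell id: '%s'", dup))
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- colnames(counts)[duplicated(colnames(counts))][1]
    stop_structural(sprintf("duplicate gene name: '%s'", dup))
  }
  if (length(counts@x) && (min(counts@x) < 0 || any(counts@x != round(counts@x)))) {
    stop_data("counts must be non-negative integers (raw counts)")
  }
  bad_coord <- !is.finite(cells$x) | !is.finite(cells$y)
  if (any(bad_coord)) {
    stop_structural(sprintf(
      "%d cell(s) have missing/non-finite coordinates (first: '%s')",
      sum(bad_coord), cells$cell_id[which(bad_coord)[1]]))
  }
  if (any(is.na(cells$slice_id))) {
    stop_structural("missing slice label")
  }
  ds
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("<spatial_dataset> %d cells x %d genes, %d slice(s)\n",
              n_cells(x), n_genes(x), length(unique(x$cells$slice_id))))
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of cells/spots in a dataset
#' @param ds A `spatial_dataset`.
#' @return Integer count.
#' @export
n_cells <- function(ds) nrow(ds$counts)

#' Number of genes in a dataset
#' @param ds A `spatial_dataset`.
#' @return Integer count.
#' @export
n_genes <- function(ds) ncol(ds$counts)

#' Slice labels present in a dataset
#' @param ds A `spatial_dataset`.
#' @return Character vector of unique slice labels, in order of appearance.
#' @export
slice_levels <- function(ds) unique(ds$cells$slice_id)

#' Subset a dataset by cells or genes
#'
#' Pure row/column selection: counts are untouched otherwise.
#'
#' @param ds A `spatial_dataset`.
#' @param cells Logical, integer, or character index over cells (default all).
#' @param genes Logical, integer, or character index over genes (default all).
#' @return The subsetted `spatial_dataset`.
#' @export
subset_dataset <- function(ds, cells = NULL, genes = NULL) {
  ci <- if (is.null(cells)) seq_len(n_cells(ds)) else cells
  gi <- if (is.null(genes)) seq_len(n_genes(ds)) else genes
  counts <- ds$counts[ci, gi, drop = FALSE]
  keep <- ds$cells[ci, , drop = FALSE]
  structure(list(counts = counts, cells = keep, metadata = ds$metadata),
            class = "spatial_dataset")
}

#' Per-cell annotation table
#' @param ds A `spatial_dataset`.
#' @return A tibble with columns `cell_id`, `x`, `y`, `slice_id`.
#' @export
cell_info <- function(ds) ds$cells
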
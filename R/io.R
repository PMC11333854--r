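#' Read a spatial dataset from disk
#'
#' Dispatches on format: `h5ad` (HDF5 annotated matrix with counts in `X`,
#' coordinates under `obsm/spatial`, slice label as an `obs` column), `mtx`
#' (MatrixMarket triplet, genes in rows and cells in columns per the
#' CellRanger convention, with sibling barcode/feature/coordinate tables), or
#' `gem` (Stereo-seq tab-delimited records; see [read_gem()]).
#'
#' @param path Path to the main file (`.h5ad`, `.mtx`, or GEM text).
#' @param format One of `"h5ad"`, `"mtx"`, `"gem"`; inferred from the file
#'   extension when omitted.
#' @param ... Passed to the format-specific reader.
#' @return A [spatial_dataset()].
#' @export
read_dataset <- function(path, format = NULL, ...) {
  if (!file.exists(path)) {
    stop_data(sprintf("cannot read input file: '%s' does not exist", path))
  }
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, h5ad = "h5ad", mtx = "mtx", gem = "gem",
                     stop_config(sprintf(
                       "cannot infer format from extension '.%s'; pass format=", ext)))
  }
  format <- match.arg(format, c("h5ad", "mtx", "gem"))
  switch(format,
         h5ad = read_h5ad(path),
         mtx  = read_mtx(path, ...),
         gem  = read_gem(path))
}

# ---- h5ad ------------------------------------------------------------------

h5_write_string_array <- function(x, file, name) {
  rhdf5::h5write(enc2utf8(as.character(x)), file, name,
                 variableLengthString = TRUE, encoding = "UTF-8")
  h5_set_attrs(file, name, c("encoding-type" = "string-array",
                             "encoding-version" = "0.2.0"))
}

h5_set_attrs <- function(file, name, attrs) {
  fid <- rhdf5::H5Fopen(file)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  oid <- rhdf5::H5Oopen(fid, name)
  on.exit(rhdf5::H5Oclose(oid), add = TRUE)
  force_array <- "column-order" # AnnData requires an array even when length 1
  for (a in names(attrs)) {
    if (!length(attrs[[a]])) { # zero-length string array, via the low-level API
      sid <- rhdf5::H5Screate_simple(0)
      tid <- rhdf5::H5Tcopy("H5T_C_S1")
      aid <- rhdf5::H5Acreate(oid, a, tid, sid)
      rhdf5::H5Aclose(aid)
      rhdf5::H5Sclose(sid)
      next
    }
    rhdf5::h5writeAttribute(attrs[[a]], oid, a,
                            asScalar = length(attrs[[a]]) == 1 && !a %in% force_array,
                            variableLengthString = is.character(attrs[[a]]),
                            encoding = if (is.character(attrs[[a]])) "UTF-8" else NULL)
  }
}

#' Write a spatial dataset as h5ad
#'
#' Emits an AnnData-compatible HDF5 file: `X` as a CSR sparse group over
#' cells-by-genes, `obs/_index` (cell ids) and `obs/slice_id`, `var/_index`
#' (gene names), spatial coordinates under `obsm/spatial`, and free-form
#' metadata strings under `uns`. [read_dataset()] on the result reproduces
#' counts, coordinates and slice labels exactly.
#'
#' @param ds A [spatial_dataset()]; must contain at least one cell.
#' @param path Output path (`.h5ad`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  validate_spatial_dataset(ds)
  if (n_cells(ds) == 0) {
    stop_data(paste0(
      "refusing to write a dataset with 0 cells; ",
      "relax the filtering thresholds (min_score/min_genes/max_mito) and re-run"))
  }
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop_data(sprintf("cannot write to '%s': directory does not exist", path))
  if (file.exists(path)) file.remove(path)

  csr <- as(Matrix::t(ds$counts), "CsparseMatrix") # CSC of genes x cells == CSR of cells x genes
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)

  rhdf5::h5createGroup(path, "X")
  h5_write_vec <- function(v, name, mode) {
    rhdf5::h5createDataset(path, name, dims = length(v), storage.mode = mode,
                           chunk = max(1L, min(length(v), 262144L)), level = 4)
    rhdf5::h5write(v, path, name)
  }
  h5_write_vec(csr@x, "X/data", "double")
  h5_write_vec(csr@i, "X/indices", "integer")
  h5_write_vec(csr@p, "X/indptr", "integer")
  h5_set_attrs(path, "X", list("encoding-type" = "csr_matrix",
                               "encoding-version" = "0.1.0",
                               "shape" = as.integer(dim(ds$counts))))

  rhdf5::h5createGroup(path, "obs")
  h5_write_string_array(ds$cells$cell_id, path, "obs/_index")
  h5_write_string_array(ds$cells$slice_id, path, "obs/slice_id")
  h5_set_attrs(path, "obs", list("encoding-type" = "dataframe",
                                 "encoding-version" = "0.2.0",
                                 "_index" = "_index",
                                 "column-order" = "slice_id"))

  rhdf5::h5createGroup(path, "var")
  h5_write_string_array(ds$gene_names %||% colnames(ds$counts), path, "var/_index")
  h5_set_attrs(path, "var", list("encoding-type" = "dataframe",
                                 "encoding-version" = "0.2.0",
                                 "_index" = "_index",
                                 "column-order" = character(0)))

  rhdf5::h5createGroup(path, "obsm")
  rhdf5::h5write(cbind(ds$cells$x, ds$cells$y), path, "obsm/spatial",
                 native = TRUE) # C-order so h5py sees cells x 2
  h5_set_attrs(path, "obsm/spatial", list("encoding-type" = "array",
                                          "encoding-version" = "0.2.0"))

  rhdf5::h5createGroup(path, "uns")
  meta <- ds$metadata
  if (length(meta)) {
    for (k in names(meta)) {
      h5_write_string_array(as.character(meta[[k]]), path, paste0("uns/", k))
    }
  }
  h5_set_attrs(path, "/", list("encoding-type" = "anndata",
                               "encoding-version" = "0.1.0"))
  rhdf5::h5closeAll()
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

h5_read_strings <- function(path, name) {
  as.character(rhdf5::h5read(path, name))
}

read_h5ad <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  paths <- gsub("^/+", "", paste(contents$group, contents$name, sep = "/"))

  cell_ids <- h5_read_strings(path, "obs/_index")
  gene_names <- h5_read_strings(path, "var/_index")
  nc <- length(cell_ids); ng <- length(gene_names)
  if (anyDuplicated(gene_names)) {
    stop_structural(sprintf("duplicate gene name in var: '%s'",
                            gene_names[duplicated(gene_names)][1]))
  }

  x_attrs <- rhdf5::h5readAttributes(path, "X")
  if ("X/indptr" %in% paths) {
    dat <- as.numeric(rhdf5::h5read(path, "X/data"))
    idx <- as.integer(rhdf5::h5read(path, "X/indices"))
    ptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    enc <- x_attrs[["encoding-type"]] %||% "csr_matrix"
    if (identical(as.character(enc), "csc_matrix")) {
      counts <- methods::new("dgCMatrix", x = dat, i = idx, p = ptr,
                             Dim = c(nc, ng))
    } else {
      gt <- methods::new("dgCMatrix", x = dat, i = idx, p = ptr,
                         Dim = c(ng, nc))
      counts <- Matrix::t(gt)
    }
  } else {
    dense <- rhdf5::h5read(path, "X")
    if (nrow(dense) == nc) counts <- Matrix::Matrix(dense, sparse = TRUE)
    else counts <- Matrix::Matrix(base::t(dense), sparse = TRUE)
  }
  if (nrow(counts) != nc) {
    stop_structural(sprintf("X has %d rows but obs lists %d cells",
                            nrow(counts), nc))
  }

  if (!"obsm/spatial" %in% paths) {
    stop_structural("no obsm/spatial coordinates found; cells without coordinates are rejected")
  }
  sp <- rhdf5::h5read(path, "obsm/spatial", native = TRUE)
  if (is.null(dim(sp))) sp <- matrix(sp, ncol = 2)
  if (nrow(sp) != nc && ncol(sp) == nc) sp <- base::t(sp)
  if (nrow(sp) != nc) {
    stop_structural(sprintf("coordinate table has %d rows for %d cells",
                            nrow(sp), nc))
  }

  slice <- if ("obs/slice_id" %in% paths) {
    obj <- rhdf5::h5read(path, "obs/slice_id")
    if (is.list(obj) && !is.null(obj$categories)) {
      as.character(obj$categories)[as.integer(obj$codes) + 1L]
    } else as.character(obj)
  } else rep("s1", nc)

  spatial_dataset(counts, cell_ids, x = sp[, 1], y = sp[, 2],
                  slice_id = slice, gene_names = gene_names,
                  metadata = list(source = path))
}

# ---- MTX triplet -----------------------------------------------------------

find_sibling <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Read an MTX triplet with coordinate table
#'
#' Expects a MatrixMarket coordinate file (genes in rows, cells in columns)
#' with sibling text tables: barcodes (one cell id per line), features (gene
#' symbol in the first column), and a tab-delimited coordinate table with
#' header columns `x`, `y`, optionally `cell_id` (else row order follows the
#' barcodes file) and `slice_id` (else a single slice `"s1"`).
#'
#' @param path Path to the `.mtx` file.
#' @param barcodes,features,coordinates Override the sibling-file paths.
#' @return A [spatial_dataset()].
#' @export
read_mtx <- function(path, barcodes = NULL, features = NULL, coordinates = NULL) {
  dir <- dirname(path)
  barcodes <- barcodes %||% find_sibling(dir, c("barcodes.tsv", "barcodes.txt"))
  features <- features %||% find_sibling(dir, c("features.tsv", "genes.tsv"))
  coordinates <- coordinates %||%
    find_sibling(dir, c("coordinates.tsv", "coords.tsv", "positions.tsv"))
  for (f in list(barcodes = barcodes, features = features, coordinates = coordinates)) {
    if (is.null(f)) {
      stop_data(sprintf("MTX companion file missing next to '%s'", path))
    }
  }
  m <- Matrix::readMM(path)
  cell_ids <- trimws(readLines(barcodes))
  feats <- readr::read_tsv(features, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE)
  gene_names <- as.character(feats[[1]])
  if (ncol(m) != length(cell_ids)) {
    stop_structural(sprintf("matrix has %d columns but %d barcodes listed",
                            ncol(m), length(cell_ids)))
  }
  if (nrow(m) != length(gene_names)) {
    stop_structural(sprintf("matrix has %d rows but %d features listed",
                            nrow(m), length(gene_names)))
  }
  if (anyDuplicated(gene_names)) {
    stop_structural(sprintf("duplicate gene name: '%s'",
                            gene_names[duplicated(gene_names)][1]))
  }
  co <- readr::read_tsv(coordinates, show_col_types = FALSE, progress = FALSE)
  for (col in c("x", "y")) {
    if (!col %in% names(co)) stop_structural(sprintf("coordinate table lacks column '%s'", col))
  }
  if ("cell_id" %in% names(co)) {
    idx <- match(cell_ids, co$cell_id)
    if (anyNA(idx)) {
      stop_structural(sprintf(
        "coordinate table covers %d of %d cells; cells without coordinates are rejected",
        sum(!is.na(idx)), length(cell_ids)))
    }
    co <- co[idx, , drop = FALSE]
  } else if (nrow(co) != length(cell_ids)) {
    stop_structural(sprintf("coordinate table has %d rows for %d cells",
                            nrow(co), length(cell_ids)))
  }
  slice <- if ("slice_id" %in% names(co)) as.character(co$slice_id) else rep("s1", length(cell_ids))
  spatial_dataset(Matrix::t(m), cell_ids, x = co$x, y = co$y, slice_id = slice,
                  gene_names = gene_names, metadata = list(source = path))
}

# ---- Stereo-seq GEM --------------------------------------------------------

#' Read a Stereo-seq GEM text file
#'
#' Tab-delimited records with header columns `geneID`, `x`, `y`, `MIDCount`
#' and optionally a cell label column (one of `cell`, `cell_id`, `CellID`,
#' `label`). With a label column, one cell is emitted per label with
#' coordinates at the centroid of its records; without one, records are
#' binned by exact `(x, y)` position (the raw GEM spot semantics). Counts are
#' the per-(cell, gene) sum of `MIDCount`.
#'
#' @param path Path to the GEM file.
#' @return A [spatial_dataset()] with a single slice `"s1"`.
#' @export
read_gem <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("cannot read input file: '%s' does not exist", path))
  rec <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         comment = "#")
  for (col in c("geneID", "x", "y", "MIDCount")) {
    if (!col %in% names(rec)) {
      stop_structural(sprintf("GEM file lacks mandatory column '%s'", col))
    }
  }
  if (nrow(rec) == 0) {
    stop_structural("GEM file contains a header but no records")
  }
  neg <- which(rec$MIDCount < 0)
  if (length(neg)) {
    stop_data(sprintf("negative MIDCount at line %d", neg[1] + 1L))
  }
  label_col <- intersect(c("cell", "cell_id", "CellID", "label"), names(rec))[1]
  if (!is.na(label_col)) {
    rec$..cell <- as.character(rec[[label_col]])
  } else {
    rec$..cell <- paste0("bin_", rec$x, "_", rec$y)
  }
  cells <- rec %>%
    group_by(cell_id = .data$..cell) %>%
    summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop")
  # preserve first-appearance order of both cells and genes
  cells <- cells[match(unique(rec$..cell), cells$cell_id), , drop = FALSE]
  genes <- unique(rec$geneID)
  agg <- rec %>%
    group_by(cell_id = .data$..cell, gene = .data$geneID) %>%
    summarise(count = sum(.data$MIDCount), .groups = "drop")
  counts <- Matrix::sparseMatrix(
    i = match(agg$cell_id, cells$cell_id),
    j = match(agg$gene, genes),
    x = agg$count,
    dims = c(nrow(cells), length(genes)))
  spatial_dataset(counts, cells$cell_id, x = cells$x, y = cells$y,
                  slice_id = rep("s1", nrow(cells)), gene_names = genes,
                  metadata = list(source = path, platform = "stereo-seq"))
}

# ---- marker lists ----------------------------------------------------------

#' Read a marker-gene list
#'
#' One gene symbol per line; whitespace (including Windows line endings) is
#' stripped, blanks dropped, duplicates removed preserving first-appearance
#' order. Matching against dataset genes is case-sensitive.
#'
#' @param path Path to the text file.
#' @return A character vector of unique symbols with attribute `source`.
#' @export
read_marker_list <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("cannot read marker file: '%s' does not exist", path))
  lines <- trimws(readLines(path, warn = FALSE))
  genes <- unique(lines[nzchar(lines)])
  if (!length(genes)) {
    stop_data(paste0("marker file '", path, "' is empty; ",
                     "disable markers instead (markers_enabled = FALSE)"))
  }
  attr(genes, "source") <- path
  genes
}

#' Export a per-cell table as TSV
#'
#' @param tbl A tibble (metrics, scores, ground truth, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(tbl, path) {
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}
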
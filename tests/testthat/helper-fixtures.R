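# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files these helpers write to tempdirs.

tiny_dataset <- function() {
  m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 3), x = c(5, 1),
                            dims = c(2, 3))
  spatial_dataset(m, c("c1", "c2"), x = c(0, 1), y = c(0, 2),
                  slice_id = c("s1", "s1"), gene_names = c("g1", "g2", "g3"))
}

# random sparse fixture with known density, seeded
random_dataset <- function(n_cells = 50, n_genes = 40, n_slices = 2,
                           seed = 1, density = 0.2, max_count = 10) {
  withr::with_seed(seed, {
    m <- matrix(0L, n_cells, n_genes)
    nz <- round(density * n_cells * n_genes)
    idx <- sample.int(n_cells * n_genes, nz)
    m[idx] <- sample.int(max_count, nz, replace = TRUE)
    spatial_dataset(
      Matrix::Matrix(m, sparse = TRUE),
      cell_ids = sprintf("c%03d", seq_len(n_cells)),
      x = runif(n_cells), y = runif(n_cells),
      slice_id = sample(sprintf("s%d", seq_len(n_slices)), n_cells, replace = TRUE),
      gene_names = sprintf("g%03d", seq_len(n_genes)))
  })
}

write_gem_file <- function(records, envir = parent.frame()) {
  # records: data.frame with geneID, x, y, MIDCount and optional cell column;
  # the file lives until the *calling* test finishes
  path <- withr::local_tempfile(fileext = ".gem", .local_envir = envir)
  readr::write_tsv(records, path, progress = FALSE)
  path
}

write_mtx_fixture <- function(dir, counts_genes_by_cells, cell_ids, gene_names,
                              coords) {
  Matrix::writeMM(Matrix::Matrix(counts_genes_by_cells, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(cell_ids, file.path(dir, "barcodes.tsv"))
  writeLines(gene_names, file.path(dir, "features.tsv"))
  readr::write_tsv(coords, file.path(dir, "coordinates.tsv"), progress = FALSE)
  file.path(dir, "matrix.mtx")
}

# small two-program dataset for doublet tests
doublet_fixture <- function(seed = 1, n = 400) {
  generate_dataset(synthetic_config(n_slices = 2, cells_per_slice = n / 2,
                                    bad_slices = integer(0), seed = seed))
}
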
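metrics_of <- function(ds) compute_metrics(ds)

test_that("min_genes retention curves count exactly", {
  ds <- random_dataset(n_cells = 3, n_genes = 400, n_slices = 1, seed = 1)
  met <- tibble::tibble(cell_id = ds$cells$cell_id, slice_id = "s1",
                        n_genes = c(100L, 200L, 300L), n_counts = 1,
                        pct_mito = 0, doublet_score = 0, is_doublet = FALSE)
  sw <- sweep_min_genes(ds, met, grid = c(150, 250))
  expect_equal(sw$curve$retention, c(2 / 3, 1 / 3))
  sw0 <- sweep_min_genes(ds, met, grid = 0)
  expect_equal(sw0$curve$retention, 1)
  expect_error(sweep_min_genes(ds, met, grid = numeric(0)),
               class = "spotcheck_config_error")
  expect_error(sweep_min_genes(ds, met, grid = c(5, 5)),
               class = "spotcheck_config_error")
})

test_that("retention curves equal a brute-force recount and never increase", {
  for (seed in 1:5) {
    sim <- generate_dataset(synthetic_config(n_slices = 3, cells_per_slice = 50,
                                             n_genes = 200, n_markers = 30,
                                             seed = seed))
    met <- compute_metrics(sim$dataset)
    sw <- sweep_min_genes(sim$dataset, met)
    for (s in unique(sw$curve$slice_id)) {
      cur <- sw$curve[sw$curve$slice_id == s, ]
      expect_true(all(diff(cur$retention) <= 0))
      ng <- met$n_genes[met$slice_id == s]
      for (j in seq_len(nrow(cur))) {
        expect_equal(cur$retention[j], mean(ng >= cur$threshold[j]))
      }
    }
  }
})

test_that("recommend_min_genes picks the largest threshold meeting the target", {
  sw <- structure(list(
    type = "min_genes", grid = c(100, 500, 600),
    curve = tibble::tibble(slice_id = "s1",
                           threshold = c(100, 500, 600),
                           retention = c(0.95, 0.71, 0.60))),
    class = "qc_sweep")
  expect_equal(recommend_min_genes(sw, target = 0.70)$recommended, 500)
  # all below target: smallest grid value with a warning flag
  sw$curve$retention <- c(0.5, 0.4, 0.3)
  expect_warning(rec <- recommend_min_genes(sw, target = 0.70))
  expect_equal(rec$recommended, 100)
  expect_true(rec$warning)
  # strict inequality: exactly 0.70 does not count
  sw$curve$retention <- c(0.95, 0.70, 0.60)
  expect_equal(suppressWarnings(recommend_min_genes(sw, target = 0.70)$recommended), 100)
})

test_that("min_cells sweeps measure marker retention over the full set", {
  m <- matrix(0, 5, 3)
  m[1:2, 1] <- 1 # marker g1 in exactly 2 cells
  m[1:5, 2] <- 1 # marker g2 in 5 cells
  ds <- spatial_dataset(Matrix::Matrix(m, sparse = TRUE), paste0("c", 1:5),
                        x = 1:5, y = 1:5, slice_id = rep("s1", 5),
                        gene_names = c("g1", "g2", "g3"))
  sw <- sweep_min_cells(ds, markers = c("g1", "g2"), grid = c(1, 3))
  expect_equal(sw$curve$marker_retention, c(1, 0.5)) # g1 lost at 3
  expect_equal(sw$curve$genes_retained, c(2, 1))
  expect_error(sweep_min_cells(ds, markers = NULL),
               "set min_cells manually", class = "spotcheck_config_error")
})

test_that("min_cells retention equals a brute-force recount on random fixtures", {
  for (seed in 1:5) {
    ds <- random_dataset(n_cells = 40, n_genes = 50, seed = seed)
    markers <- colnames(ds$counts)[seq(1, 50, by = 3)]
    sw <- sweep_min_cells(ds, markers, grid = c(1, 2, 3, 5, 8))
    det <- colSums(as.matrix(ds$counts) > 0)
    for (j in seq_along(sw$grid)) {
      expect_equal(sw$curve$marker_retention[j],
                   sum(det[markers] >= sw$grid[j]) / length(markers))
    }
    expect_true(all(diff(sw$curve$marker_retention) <= 0))
  }
})

test_that("recommend_min_cells follows the >99% marker retention rule", {
  sw <- structure(list(
    type = "min_cells", grid = c(1, 3, 15, 30),
    curve = tibble::tibble(threshold = c(1, 3, 15, 30),
                           marker_retention = c(1, 1, 1, 0.97),
                           genes_retained = c(100, 90, 60, 40))),
    class = "qc_sweep")
  expect_equal(recommend_min_cells(sw, target = 0.99)$recommended, 15)
  expect_equal(recommend_min_cells(sw, target = 0)$recommended, 30)
  sw$curve$marker_retention <- c(0.9, 0.8, 0.7, 0.6)
  expect_warning(rec <- recommend_min_cells(sw, target = 0.99))
  expect_equal(rec$recommended, 1)
})

test_that("recommendations reproduce their sweep retention when re-applied", {
  sim <- generate_dataset(synthetic_config(n_slices = 3, cells_per_slice = 80,
                                           n_genes = 400, n_markers = 60, seed = 4))
  ds <- sim$dataset
  met <- compute_metrics(ds, markers = sim$truth_markers)
  rec <- recommend_min_genes(sweep_min_genes(ds, met))
  cfg <- filter_config(min_genes = rec$recommended, min_cells = 1,
                       doublets_enabled = FALSE, mito_enabled = FALSE)
  kept <- filter_cells(ds, met, cfg)$dataset
  for (s in unique(ds$cells$slice_id)) {
    expected <- rec$curve$retention[rec$curve$slice_id == s &
                                      rec$curve$threshold == rec$recommended]
    got <- sum(kept$cells$slice_id == s) / sum(ds$cells$slice_id == s)
    expect_equal(got, expected)
  }
  rec2 <- recommend_min_cells(sweep_min_cells(kept, sim$truth_markers))
  out <- filter_genes(kept, sim$truth_markers, min_cells = rec2$recommended)
  expect_equal(out$report$marker_retention,
               rec2$curve$marker_retention[rec2$curve$threshold == rec2$recommended])
})
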
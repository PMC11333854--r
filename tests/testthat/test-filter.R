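scores_for <- function(ds, slice_totals) {
  # constant total per slice so medians are exact
  tibble::tibble(cell_id = ds$cells$cell_id, slice_id = ds$cells$slice_id,
                 total = slice_totals[ds$cells$slice_id])
}

test_that("slice filter removes exactly the below-median slices, strictly", {
  ds <- random_dataset(n_cells = 40, n_slices = 2, seed = 1)
  out <- filter_slices(ds, scores_for(ds, c(s1 = 7, s2 = 4.5)), min_score = 5)
  expect_setequal(unique(out$dataset$cells$slice_id), "s1")
  expect_true(out$report$removed[out$report$slice_id == "s2"])
  # a median of exactly 5 is kept (strict <)
  out2 <- filter_slices(ds, scores_for(ds, c(s1 = 7, s2 = 5)), min_score = 5)
  expect_setequal(unique(out2$dataset$cells$slice_id), c("s1", "s2"))
  # single slice above threshold: identity
  one <- subset_dataset(ds, cells = ds$cells$slice_id == "s1")
  out3 <- filter_slices(one, scores_for(one, c(s1 = 7)), min_score = 5)
  expect_identical(as.matrix(out3$dataset$counts), as.matrix(one$counts))
  expect_error(filter_slices(ds, scores_for(ds, c(s1 = 2, s2 = 3))),
               "reduce min_score", class = "spotcheck_data_error")
})

test_that("cell filter applies min_genes, max_mito and doublet calls with tallies", {
  ds <- random_dataset(n_cells = 6, n_genes = 600, seed = 2)
  met <- tibble::tibble(
    cell_id = ds$cells$cell_id, slice_id = ds$cells$slice_id,
    n_genes = c(489L, 490L, 600L, 600L, 600L, 600L),
    n_counts = rep(1000, 6),
    pct_mito = c(0, 0, 0.12, 0.10, 0, 0),
    doublet_score = 0, is_doublet = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  cfg <- filter_config(min_genes = 490, max_mito = 0.10, min_cells = 1)
  out <- filter_cells(ds, met, cfg)
  kept <- out$dataset$cells$cell_id
  expect_setequal(kept, ds$cells$cell_id[c(2, 4, 6)]) # 489<490 out, 0.12>0.1 out, doublet out
  expect_equal(out$report$causes$low_n_genes, 1)
  expect_equal(out$report$causes$high_pct_mito, 1)
  expect_equal(out$report$causes$doublet, 1)
  # counts of retained cells unchanged
  expect_identical(as.matrix(out$dataset$counts),
                   as.matrix(ds$counts)[c(2, 4, 6), ])
  met$n_genes <- 0L
  expect_error(filter_cells(ds, met, cfg), "low_n_genes=6",
               class = "spotcheck_data_error")
})

test_that("gene filter keeps genes detected in >= min_cells cells and tracks markers", {
  m <- matrix(0, 4, 3)
  m[1:2, 1] <- 1   # g1 in 2 cells
  m[1:3, 2] <- 2   # g2 in 3 cells
  ds <- spatial_dataset(Matrix::Matrix(m, sparse = TRUE), paste0("c", 1:4),
                        x = 1:4, y = 1:4, slice_id = rep("s1", 4),
                        gene_names = c("g1", "g2", "g3"))
  out <- filter_genes(ds, markers = c("g1", "g2"), min_cells = 3)
  expect_identical(colnames(out$dataset$counts), "g2")
  expect_equal(out$report$marker_retention, 0.5)
  out1 <- filter_genes(ds, min_cells = 1) # only all-zero genes removed
  expect_setequal(colnames(out1$dataset$counts), c("g1", "g2"))
  # empty surviving gene set reports, never raises
  out0 <- filter_genes(ds, min_cells = 10)
  expect_identical(ncol(out0$dataset$counts), 0L)
})

test_that("gene detection counts equal a brute-force column oracle", {
  for (seed in 1:5) {
    ds <- random_dataset(n_cells = 30, n_genes = 40, seed = seed)
    for (mc in c(1, 3, 5)) {
      kept <- colnames(filter_genes(ds, min_cells = mc)$dataset$counts)
      oracle <- colnames(ds$counts)[colSums(as.matrix(ds$counts) > 0) >= mc]
      expect_setequal(kept, oracle)
    }
  }
})

test_that("the pipeline removes exactly the planted bad slice and dying cells", {
  sim <- generate_dataset(synthetic_config(n_slices = 4, cells_per_slice = 100,
                                           n_genes = 500, n_markers = 60,
                                           bad_slices = 3, seed = 11))
  cfg <- filter_config(doublets_enabled = FALSE)
  run <- suppressWarnings(run_pipeline(sim$dataset, markers = sim$truth_markers, cfg = cfg))
  removed_slices <- run$report$slice$slice_id[run$report$slice$removed]
  expect_identical(removed_slices, "s3")
  truth <- sim$truth
  dying <- truth$cell_id[truth$is_dying & truth$slice_id != "s3"]
  expect_gt(mean(!dying %in% run$dataset$cells$cell_id), 0.7)
})

test_that("markers disabled without min_cells is a configuration error", {
  sim <- generate_dataset(synthetic_config(n_slices = 2, cells_per_slice = 40,
                                           n_genes = 200, n_markers = 30, seed = 1))
  cfg <- filter_config(markers_enabled = FALSE, doublets_enabled = FALSE)
  expect_error(run_pipeline(sim$dataset, markers = sim$truth_markers, cfg = cfg),
               "min_cells", class = "spotcheck_config_error")
  expect_error(run_pipeline(sim$dataset, markers = NULL,
                            cfg = filter_config(doublets_enabled = FALSE)),
               "min_cells", class = "spotcheck_config_error")
})

test_that("a fully permissive configuration is the identity", {
  sim <- generate_dataset(synthetic_config(n_slices = 2, cells_per_slice = 50,
                                           n_genes = 300, n_markers = 30, seed = 6))
  cfg <- filter_config(min_score = 0, min_genes = 0, min_cells = 0,
                       max_mito = 1, doublets_enabled = FALSE)
  run <- run_pipeline(sim$dataset, markers = sim$truth_markers, cfg = cfg)
  expect_identical(as.matrix(run$dataset$counts), as.matrix(sim$dataset$counts))
})

test_that("output counts are an exact submatrix of the input (conservation)", {
  sim <- generate_dataset(synthetic_config(n_slices = 3, cells_per_slice = 60,
                                           n_genes = 300, n_markers = 40, seed = 8))
  run <- suppressWarnings(run_pipeline(sim$dataset, markers = sim$truth_markers,
                                       cfg = filter_config(doublets_enabled = FALSE)))
  sub <- sim$dataset$counts[run$dataset$cells$cell_id,
                            colnames(run$dataset$counts), drop = FALSE]
  expect_identical(as.matrix(run$dataset$counts), as.matrix(sub))
})

test_that("retention is monotone in min_genes, min_score and min_cells", {
  sim <- generate_dataset(synthetic_config(n_slices = 2, cells_per_slice = 60,
                                           n_genes = 300, n_markers = 40, seed = 9))
  met <- compute_metrics(sim$dataset, markers = sim$truth_markers)
  rub <- default_rubric(met, doublets_enabled = FALSE)
  sc <- score_cells(met, rub)
  cells_at <- function(mg) {
    cfg <- filter_config(min_genes = mg, min_cells = 1, doublets_enabled = FALSE)
    out <- tryCatch(filter_cells(sim$dataset, met, cfg)$dataset,
                    spotcheck_data_error = function(e) NULL)
    if (is.null(out)) 0 else n_cells(out)
  }
  mg_grid <- c(0, 50, 100, 200, 400)
  expect_true(all(diff(vapply(mg_grid, cells_at, numeric(1))) <= 0))
  genes_at <- function(mc) filter_genes(sim$dataset, min_cells = mc)$report$retained
  expect_true(all(diff(vapply(c(1, 2, 5, 10, 30), genes_at, numeric(1))) <= 0))
  slices_at <- function(ms) {
    kept <- try(length(unique(filter_slices(sim$dataset, sc, ms)$dataset$cells$slice_id)),
                silent = TRUE)
    if (inherits(kept, "try-error")) 0 else kept
  }
  expect_true(all(diff(vapply(c(0, 3, 5, 8, 10), slices_at, numeric(1))) <= 0))
})

test_that("gene detection is counted after cell filtering (order matters)", {
  # g1 detected in 3 cells overall but only 1 surviving cell
  m <- matrix(0, 4, 2)
  m[, 1] <- c(1, 1, 1, 0); m[, 2] <- c(5, 5, 5, 5)
  ds <- spatial_dataset(Matrix::Matrix(m, sparse = TRUE), paste0("c", 1:4),
                        x = 1:4, y = 1:4, slice_id = rep("s1", 4),
                        gene_names = c("g1", "g2"))
  met <- tibble::tibble(cell_id = paste0("c", 1:4), slice_id = "s1",
                        n_genes = c(2L, 1L, 1L, 1L), n_counts = c(6, 6, 6, 5),
                        pct_mito = 0, doublet_score = 0, is_doublet = FALSE)
  cfg <- filter_config(min_genes = 2, min_cells = 2, doublets_enabled = FALSE)
  after_cells <- filter_cells(ds, met, cfg)$dataset
  out <- filter_genes(after_cells, min_cells = 2)
  expect_false("g1" %in% colnames(out$dataset$counts)) # would survive pre-filter counting
})

test_that("re-running the pipeline on its own output removes nothing further", {
  sim <- generate_dataset(synthetic_config(n_slices = 3, cells_per_slice = 60,
                                           n_genes = 300, n_markers = 40, seed = 10))
  cfg <- filter_config(min_genes = 30, min_cells = 2, doublets_enabled = FALSE)
  run1 <- suppressWarnings(run_pipeline(sim$dataset, markers = sim$truth_markers, cfg = cfg))
  run2 <- suppressWarnings(run_pipeline(run1$dataset, markers = sim$truth_markers, cfg = cfg))
  expect_identical(as.matrix(run2$dataset$counts), as.matrix(run1$dataset$counts))
})

test_that("platform presets fill defaults without clobbering explicit values", {
  sl <- filter_config(platform = "slide-seq")
  expect_equal(sl$min_genes, 340L)
  expect_equal(sl$max_mito, 0.2)
  sl2 <- filter_config(platform = "slide-seq", max_mito = 0.05)
  expect_equal(sl2$max_mito, 0.05)
  vis <- filter_config(platform = "visium")
  expect_false(vis$doublets_enabled)
  mer <- filter_config(platform = "merfish")
  expect_false(mer$mito_enabled)
  expect_error(filter_config(max_mito = 1.5), class = "spotcheck_config_error")
})
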
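small_run <- function(seed = 5) {
  sim <- generate_dataset(synthetic_config(n_slices = 3, cells_per_slice = 70,
                                           n_genes = 400, n_markers = 60,
                                           bad_slices = 2, seed = seed))
  run <- suppressWarnings(run_pipeline(
    sim$dataset, markers = sim$truth_markers,
    cfg = filter_config(min_genes = 30, min_cells = 2), seed = seed))
  list(sim = sim, run = run)
}

test_that("dataset summaries report exact totals and per-slice medians", {
  ds <- random_dataset(n_cells = 25, n_genes = 100, n_slices = 1, seed = 2)
  ds$cells$slice_id <- rep(c("s1", "s2"), c(10, 15))
  met <- compute_metrics(ds)
  s <- summarize_dataset(ds, met)
  expect_equal(s$cells, 25)
  expect_equal(s$genes, 100)
  expect_equal(s$slices, 2)
  expect_null(s$markers) # markers disabled: field omitted
  expect_equal(s$per_slice$n_cells, c(10, 15))
  expect_equal(s$per_slice$median_n_genes[1],
               median(met$n_genes[ds$cells$slice_id == "s1"]))
  s2 <- summarize_dataset(ds, met, markers = c("g001", "g002"))
  expect_equal(s2$markers, 2)
})

test_that("the Welch comparison matches its closed form and the stats oracle", {
  # identical groups: t = 0, p = 1 by definition
  same <- compare_scores(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  # hand vectors against the textbook formula, evaluated independently
  x <- c(1, 2, 3); y <- c(1, 2, 3, 4)
  got <- compare_scores(x, y)
  se <- sqrt(var(x) / 3 + var(y) / 4)
  expect_equal(got$t_statistic, (mean(x) - mean(y)) / se)
  oracle <- t.test(x, y) # Welch by default
  expect_equal(got$t_statistic, unname(oracle$statistic))
  expect_equal(got$df, unname(oracle$parameter))
  expect_equal(got$p_value, oracle$p.value)

  # clearly separated groups are overwhelmingly significant
  withr::with_seed(0, {
    a <- rnorm(500, 5, 1); b <- rnorm(400, 7, 1)
  })
  expect_lt(compare_scores(a, b)$p_value, 1e-10)

  expect_error(compare_scores(1, c(1, 2)), class = "spotcheck_data_error")
})

test_that("the report is self-contained HTML with 14 sections and a slice selector", {
  sr <- small_run()
  bundle <- build_report_bundle(sr$run, sr$sim$dataset, markers = sr$sim$truth_markers)
  expect_length(bundle$sections, 14)
  path <- withr::local_tempfile(fileext = ".html")
  build_report(bundle, path)
  html <- xml2::read_html(path)
  buttons <- xml2::xml_find_all(html, "//button[@class='nav-btn'][@role='button']")
  expect_length(buttons, 14)
  expect_length(xml2::xml_find_all(html, "//select[@id='slice-select']"), 1)
  expect_length(xml2::xml_find_all(html, "//section[@class='panel']"), 14)
  # self-contained: nothing is loaded from the network (XML namespace URIs
  # are identifiers, not fetched resources)
  raw <- readLines(path, warn = FALSE)
  expect_false(any(grepl("(src|href)\\s*=\\s*[\"']https?://", raw)))
  expect_length(xml2::xml_find_all(html, "//script[@src]"), 0)
  expect_length(xml2::xml_find_all(html, "//link[@href]"), 0)
})

test_that("embedded JSON islands round-trip the bundle's figure arrays", {
  sr <- small_run()
  bundle <- build_report_bundle(sr$run, sr$sim$dataset, markers = sr$sim$truth_markers)
  path <- withr::local_tempfile(fileext = ".html")
  build_report(bundle, path)
  html <- xml2::read_html(path)
  extract <- function(id) {
    node <- xml2::xml_find_first(html, sprintf("//script[@id='data-sec-%s']", id))
    jsonlite::fromJSON(xml2::xml_text(node), simplifyVector = TRUE)
  }
  cvg <- extract("counts_vs_genes")
  expect_equal(cvg$x, bundle$sections$counts_vs_genes$data$x)
  expect_equal(cvg$y, bundle$sections$counts_vs_genes$data$y)
  expect_equal(cvg$color, bundle$sections$counts_vs_genes$data$color)
  kde <- extract("kde_n_genes")
  expect_equal(kde$series$before$y, bundle$sections$kde_n_genes$data$series$before$y)
  sg <- extract("sweep_min_genes")
  expect_equal(sg$recommended, bundle$sections$sweep_min_genes$data$recommended)
  db <- extract("doublets")
  expect_equal(db$threshold, bundle$sections$doublets$data$threshold)
})

test_that("reports are byte-stable across reruns apart from the timestamp", {
  sr <- small_run()
  bundle <- build_report_bundle(sr$run, sr$sim$dataset, markers = sr$sim$truth_markers)
  p1 <- withr::local_tempfile(fileext = ".html")
  p2 <- withr::local_tempfile(fileext = ".html")
  build_report(bundle, p1)
  Sys.sleep(1.1) # force a different timestamp
  build_report(bundle, p2)
  strip <- function(p) sub("Generated: [^<]*", "Generated: X", readLines(p, warn = FALSE))
  expect_identical(strip(p1), strip(p2))
  expect_false(identical(readLines(p1, warn = FALSE), readLines(p2, warn = FALSE)))
})

test_that("a doublets-disabled run still renders all 14 sections", {
  sim <- generate_dataset(synthetic_config(n_slices = 2, cells_per_slice = 60,
                                           n_genes = 300, n_markers = 40, seed = 3))
  run <- suppressWarnings(run_pipeline(
    sim$dataset, markers = sim$truth_markers,
    cfg = filter_config(min_genes = 30, min_cells = 2, doublets_enabled = FALSE)))
  bundle <- build_report_bundle(run, sim$dataset, markers = sim$truth_markers)
  expect_length(bundle$sections, 14)
  expect_identical(bundle$sections$doublets$type, "disabled")
  path <- withr::local_tempfile(fileext = ".html")
  build_report(bundle, path)
  html <- xml2::read_html(path)
  expect_length(xml2::xml_find_all(html, "//button[@class='nav-btn'][@role='button']"), 14)
})

test_that("tidy and glance summarise runs, sweeps and doublet results", {
  sr <- small_run()
  td <- tidy(sr$run)
  expect_equal(td$examined - td$removed, td$retained)
  expect_equal(td$step, c("slice", "cell", "gene"))
  gl <- glance(sr$run)
  expect_equal(gl$cells_in, 3 * 70)
  expect_lte(gl$cells_out, gl$cells_in)
  sw <- recommend_min_genes(sweep_min_genes(sr$sim$dataset,
                                            compute_metrics(sr$sim$dataset)))
  expect_s3_class(tidy(sw), "tbl_df")
  expect_false(glance(sw)$fallback)
  dres <- sr$run$doublets
  expect_equal(nrow(tidy(dres)), n_cells(sr$sim$dataset))
  expect_equal(glance(dres)$n_called, sum(tidy(dres)$is_doublet))
})

test_that("plot functions return ggplot objects", {
  sr <- small_run()
  expect_s3_class(plot_slice_scores(sr$run$scores_before), "ggplot")
  expect_s3_class(plot_spatial(sr$sim$dataset, sr$run$scores_before$total), "ggplot")
  expect_s3_class(plot_metric_density(sr$run$metrics), "ggplot")
  expect_s3_class(plot_counts_vs_genes(sr$run$metrics), "ggplot")
  sw <- recommend_min_genes(sweep_min_genes(sr$sim$dataset, sr$run$metrics))
  expect_s3_class(autoplot(sw), "ggplot")
  expect_s3_class(autoplot(sr$run), "ggplot")
})
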
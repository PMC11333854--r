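#' Configuration for the synthetic multi-slice generator
#'
#' Defines the study conditions the generator emulates: several tissue
#' slices with gamma-Poisson (negative binomial) per-cell depths, one
#' planted low-depth ("bad") slice, optionally a spatially localised
#' low-quality region inside a slice, a small population of dying cells
#' with high mitochondrial load, planted cross-program doublets, and a
#' marker-gene program so marker-based recommendations can be exercised.
#'
#' @param n_slices Number of slices (default 8).
#' @param cells_per_slice Cells per slice (default 400).
#' @param n_genes Non-mitochondrial genes (default 2000).
#' @param n_markers Planted marker genes (default 451).
#' @param base_depth Mean molecules per cell (default 2000).
#' @param depth_dispersion Gamma shape of the per-cell depth (default 2).
#' @param bad_slices Indices (1-based) of planted low-depth slices; the
#'   default plants one bad slice, the 7th (or the last slice when fewer
#'   than 7 exist). Pass `integer(0)` for none.
#' @param bad_slice_depth_factor Depth multiplier of bad slices (default 0.2).
#' @param bad_region `NULL`, or `list(slice, center = c(x, y), radius,
#'   depth_factor)` planting a localised low-quality disc inside a slice.
#' @param doublet_rate Fraction of cells that are cross-program doublets
#'   (default 0.06).
#' @param dying_cell_rate Fraction of dying cells (default 0.05); their
#'   mitochondrial fraction is drawn Beta(8, 2) versus Beta(1, 30) for
#'   healthy cells.
#' @param dying_depth_range Range of the per-cell depth multiplier for dying
#'   cells (default `c(0.2, 1)`, drawn uniformly): apoptosis progressively
#'   degrades cytoplasmic RNA, so dying cells smear toward low counts and
#'   high mito fraction rather than forming a coherent subpopulation.
#' @param n_programs Expression programs (default 2); markers are split
#'   into program-specific blocks up-weighted 10x in their program.
#' @param n_mito_genes Mitochondrial genes, named with the `MT-` prefix
#'   (default 13).
#' @param profile_alpha Dirichlet concentration of the non-marker gene
#'   weights (default 0.3, giving the heavy-tailed profiles of real
#'   transcriptomes where the top ~100 genes carry about half the counts;
#'   marker weights use concentration 1 since differential-expression-derived
#'   markers are robustly expressed in their program).
#' @param seed Integer seed; generation is fully reproducible per seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_slices = 8, cells_per_slice = 400,
                             n_genes = 2000, n_markers = 451,
                             base_depth = 2000, depth_dispersion = 2,
                             bad_slices = NULL, bad_slice_depth_factor = 0.2,
                             bad_region = NULL,
                             doublet_rate = 0.06, dying_cell_rate = 0.05,
                             dying_depth_range = c(0.2, 1),
                             n_programs = 2, n_mito_genes = 13,
                             profile_alpha = 0.3, seed = 0) {
  if (is.null(bad_slices)) bad_slices <- if (n_slices >= 7L) 7L else integer(0)
  cfg <- as.list(environment())
  if (n_markers > n_genes) stop_config("n_markers cannot exceed n_genes")
  if (doublet_rate < 0 || doublet_rate > 1) stop_config("doublet_rate must lie in [0, 1]")
  if (dying_cell_rate < 0 || dying_cell_rate > 1) stop_config("dying_cell_rate must lie in [0, 1]")
  if (bad_slice_depth_factor <= 0 || bad_slice_depth_factor > 1) {
    stop_config("bad_slice_depth_factor must lie in (0, 1]")
  }
  if (length(bad_slices) && any(bad_slices < 1 | bad_slices > n_slices)) {
    stop_config("bad_slices indices out of range")
  }
  structure(cfg, class = "synthetic_config")
}

make_programs <- function(cfg) {
  gene_names <- c(sprintf("MT-g%d", seq_len(cfg$n_mito_genes)),
                  sprintf("g%04d", seq_len(cfg$n_genes)))
  mito_idx <- seq_len(cfg$n_mito_genes)
  body_idx <- cfg$n_mito_genes + seq_len(cfg$n_genes)
  markers <- gene_names[body_idx][seq_len(cfg$n_markers)]
  marker_program <- rep(seq_len(cfg$n_programs), length.out = cfg$n_markers)
  weights <- matrix(0, nrow = cfg$n_programs, ncol = cfg$n_genes)
  for (p in seq_len(cfg$n_programs)) {
    # heavy-tailed background profile (top ~100 genes carry about half the
    # counts, as in real transcriptomes); markers are DE-derived so they are
    # robustly expressed in their program, never near-zero
    w <- rgamma(cfg$n_genes, shape = cfg$profile_alpha)
    w[seq_len(cfg$n_markers)] <- rgamma(cfg$n_markers, shape = 1)
    block <- which(marker_program == p)
    w[block] <- w[block] * 10
    weights[p, ] <- w / sum(w)
  }
  list(gene_names = gene_names, mito_idx = mito_idx, body_idx = body_idx,
       markers = markers, weights = weights)
}

draw_cell_counts <- function(depth, mito_frac, program_w, n_mito) {
  p <- c(rep(mito_frac / n_mito, n_mito), (1 - mito_frac) * program_w)
  size <- rpois(1, depth)
  if (size == 0) return(integer(length(p)))
  as.integer(rmultinom(1, size, p))
}

#' Generate a synthetic multi-slice spatial dataset with planted defects
#'
#' Draws per-cell depths gamma-Poisson (`Gamma(shape, scale =
#' base_depth/shape)` times slice and region factors), allocates the cell's
#' mitochondrial fraction of depth to the mito genes, and the rest
#' multinomially across its program's Dirichlet gene weights (markers
#' up-weighted 10x in their own program). Doublets are the sum of two
#' cross-program draws placed at the midpoint coordinate; coordinates are
#' uniform on a per-slice unit square.
#'
#' @param cfg A [synthetic_config()].
#' @return A list: `dataset` (a [spatial_dataset()]), `truth` (per-cell
#'   tibble: `is_doublet`, `is_dying`, `in_bad_region`, `program`),
#'   `truth_slices` (per-slice tibble with `is_bad`), `truth_markers`
#'   (planted marker symbols).
#' @export
#' @examples
#' sim <- generate_dataset(synthetic_config(n_slices = 2, cells_per_slice = 40,
#'                                          n_genes = 100, n_markers = 10, seed = 1))
#' sim$dataset
generate_dataset <- function(cfg = synthetic_config()) {
  withr::with_seed(cfg$seed, generate_dataset_impl(cfg))
}

generate_dataset_impl <- function(cfg) {
  pr <- make_programs(cfg)
  n_total <- cfg$n_slices * cfg$cells_per_slice
  counts <- matrix(0L, nrow = n_total, ncol = length(pr$gene_names))
  cell_rows <- vector("list", cfg$n_slices)
  row <- 0L
  for (s in seq_len(cfg$n_slices)) {
    slice_name <- sprintf("s%d", s)
    slice_factor <- if (s %in% cfg$bad_slices) cfg$bad_slice_depth_factor else 1
    n <- cfg$cells_per_slice
    xs <- runif(n); ys <- runif(n)
    in_region <- rep(FALSE, n)
    region_factor <- rep(1, n)
    br <- cfg$bad_region
    if (!is.null(br) && br$slice == s) {
      in_region <- sqrt((xs - br$center[1])^2 + (ys - br$center[2])^2) <= br$radius
      region_factor[in_region] <- br$depth_factor
    }
    n_dbl <- round(cfg$doublet_rate * n)
    is_doublet <- rep(FALSE, n)
    if (n_dbl > 0 && cfg$n_programs >= 2) is_doublet[sample.int(n, n_dbl)] <- TRUE
    is_dying <- runif(n) < cfg$dying_cell_rate
    program <- sample.int(cfg$n_programs, n, replace = TRUE)
    mito_frac <- ifelse(is_dying, rbeta(n, 8, 2), rbeta(n, 1, 30))
    depth_mean <- cfg$base_depth * slice_factor * region_factor *
      ifelse(is_dying, runif(n, cfg$dying_depth_range[1], cfg$dying_depth_range[2]), 1)
    for (i in seq_len(n)) {
      row <- row + 1L
      if (is_doublet[i]) {
        p1 <- program[i]
        p2 <- sample(setdiff(seq_len(cfg$n_programs), p1), 1)
        # both members share the spot's capture depth (total ~2x a singlet);
        # their split reflects biological RNA-content variation
        d <- rgamma(1, shape = cfg$depth_dispersion,
                    scale = depth_mean[i] / cfg$depth_dispersion)
        f <- rbeta(1, 6, 6)
        mf <- rbeta(1, 1, 30)
        counts[row, ] <- draw_cell_counts(2 * d * f, mf, pr$weights[p1, ], cfg$n_mito_genes) +
          draw_cell_counts(2 * d * (1 - f), mf, pr$weights[p2, ], cfg$n_mito_genes)
        # midpoint of two independent positions
        x2 <- runif(1); y2 <- runif(1)
        xs[i] <- (xs[i] + x2) / 2; ys[i] <- (ys[i] + y2) / 2
        is_dying[i] <- FALSE
      } else {
        d <- rgamma(1, shape = cfg$depth_dispersion,
                    scale = depth_mean[i] / cfg$depth_dispersion)
        counts[row, ] <- draw_cell_counts(d, mito_frac[i], pr$weights[program[i], ],
                                          cfg$n_mito_genes)
      }
    }
    cell_rows[[s]] <- tibble(
      cell_id = sprintf("%s_c%04d", slice_name, seq_len(n)),
      x = xs, y = ys, slice_id = slice_name,
      program = program, is_doublet = is_doublet, is_dying = is_dying,
      in_bad_region = in_region)
  }
  cells <- bind_rows(cell_rows)
  ds <- spatial_dataset(Matrix::Matrix(counts, sparse = TRUE),
                        cells$cell_id, x = cells$x, y = cells$y,
                        slice_id = cells$slice_id, gene_names = pr$gene_names,
                        metadata = list(platform = "synthetic"))
  list(
    dataset = ds,
    truth = cells %>% select("cell_id", "slice_id", "program", "is_doublet",
                             "is_dying", "in_bad_region"),
    truth_slices = tibble(
      slice_id = sprintf("s%d", seq_len(cfg$n_slices)),
      is_bad = seq_len(cfg$n_slices) %in% cfg$bad_slices),
    truth_markers = pr$markers
  )
}

#' Generate a bead-array dataset with non-tissue background
#'
#' Emulates a bead platform where the tissue occupies part of the array:
#' tissue cells are drawn as in [generate_dataset()] and mixed with
#' background beads whose depth is Gamma with mean `bead_depth` over a flat
#' gene profile, at `bead_fraction` beads : (1 - `bead_fraction`) tissue.
#' The mixture makes the per-cell `n_genes` and `n_counts` densities
#' bimodal; removing low-complexity beads collapses them to one mode.
#'
#' @param cfg A [synthetic_config()] describing the tissue component. Slice
#'   and region depth defects are ignored here: the planted defect of this
#'   preset is the non-tissue background itself.
#' @param bead_fraction Fraction of all units that are background beads
#'   (default 0.6).
#' @param bead_depth Mean background-bead depth (default 60).
#' @return As [generate_dataset()], with an extra per-cell truth column
#'   `is_background`.
#' @export
generate_bead_background <- function(cfg = synthetic_config(),
                                     bead_fraction = 0.6, bead_depth = 60) {
  if (bead_fraction < 0 || bead_fraction >= 1) {
    stop_config("bead_fraction must lie in [0, 1)")
  }
  cfg$bad_slices <- integer(0)
  cfg$bad_region <- NULL
  cfg$doublet_rate <- 0 # beads are smaller than cells; no droplet-style doublets
  sim <- generate_dataset(cfg)
  sim$truth$is_background <- FALSE
  if (bead_fraction == 0) return(sim)
  withr::with_seed(cfg$seed + 104729L, {
    n_tissue <- n_cells(sim$dataset)
    n_beads <- round(n_tissue * bead_fraction / (1 - bead_fraction))
    ng <- n_genes(sim$dataset)
    flat <- rep(1 / ng, ng)
    bead_counts <- matrix(0L, nrow = n_beads, ncol = ng)
    depth <- rgamma(n_beads, shape = cfg$depth_dispersion,
                    scale = bead_depth / cfg$depth_dispersion)
    for (i in seq_len(n_beads)) {
      size <- rpois(1, depth[i])
      if (size > 0) bead_counts[i, ] <- as.integer(rmultinom(1, size, flat))
    }
    slices <- slice_levels(sim$dataset)
    bead_slice <- sample(slices, n_beads, replace = TRUE)
    bead_cells <- tibble(
      cell_id = sprintf("bead_%05d", seq_len(n_beads)),
      x = runif(n_beads), y = runif(n_beads), slice_id = bead_slice)
    all_counts <- rbind(sim$dataset$counts,
                        Matrix::Matrix(bead_counts, sparse = TRUE))
    cells <- bind_rows(sim$dataset$cells, bead_cells)
    ds <- spatial_dataset(all_counts, cells$cell_id, x = cells$x, y = cells$y,
                          slice_id = cells$slice_id,
                          gene_names = colnames(sim$dataset$counts),
                          metadata = list(platform = "synthetic-bead"))
    truth <- bind_rows(
      sim$truth,
      tibble(cell_id = bead_cells$cell_id, slice_id = bead_cells$slice_id,
             program = NA_integer_, is_doublet = FALSE, is_dying = FALSE,
             in_bad_region = FALSE, is_background = TRUE))
    list(dataset = ds, truth = truth, truth_slices = sim$truth_slices,
         truth_markers = sim$truth_markers)
  })
}
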
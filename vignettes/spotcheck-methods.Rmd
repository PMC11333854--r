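---
title: "Quality control for multi-slice spatial transcriptomics: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control for multi-slice spatial transcriptomics: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotcheck)
```

# The problem

Spatial transcriptomics datasets are assembled from physically sectioned
slices, each sequenced separately. Quality therefore varies at three scales:
whole slices can be shallowly sequenced; individual cells or spots can be
empty, dying, or doublets; and genes can be so sparsely detected that they
only add noise. `spotcheck` scores every cell on five metrics, aggregates
the scores per slice, and filters sequentially at slice, cell, and gene
level. This vignette records the models, the defaults and why they were
chosen, and the places where the design was genuinely open.

# The scoring rubric

Per-cell metrics: `n_genes` (genes with nonzero count), `n_counts` (total
molecules), `pct_mito` (fraction of counts from mitochondrial genes, with
0/0 defined as 0 so all-empty cells do not propagate NaN), `marker_ratio`
(fraction of a user-supplied marker set detected in the cell), and a
simulated-doublet score (next section).

Each metric contributes a sub-score in {0, 1, 2}; the cell score is the
sum, 0–10. Depth-like metrics (`n_genes`, `n_counts`, `marker_ratio`) are
cut at the dataset's pooled lower quartile and median — at or above the
median scores 2, at or above Q25 scores 1, boundaries inclusive. Pooling
across slices (rather than per-slice quantiles) is deliberate: slice-level
filtering compares slice medians with one another, which is only meaningful
if every slice is scored against the same yardstick. `pct_mito` uses fixed
cuts (≤ 0.05 → 2, ≤ 0.10 → 1): mitochondrial load has an absolute
biological interpretation that quantiles would dilute. Because removal
applies to cells *exceeding* 10%, a cell at exactly 0.10 scores 1, not 0.
The doublet sub-score is 0 for called doublets, 2 for cells scoring below
half the call threshold, 1 in between.

A disabled metric (no markers supplied; doublets off for spot platforms;
mito scoring off for probe panels without mitochondrial genes) contributes
a constant 2. This keeps the scale at 0–10, so the slice-rejection
boundary of 5 — half the maximum — retains its meaning regardless of which
metrics are active. The rubric is an explicit object
(`default_rubric()`, serialisable via `rubric_to_json()`), so a user with
an externally calibrated rubric can substitute it.

The exact sub-score table is a design decision of this package: a
five-metric × {0,1,2} rubric is the simplest scheme in which the
conventional "median below 5" slice boundary equals half the maximum
score.

`marker_ratio` is defined as the fraction of the marker *set* detected in
the cell (not the share of the cell's counts attributable to markers). The
set-coverage reading makes the metric a library-complexity measure on the
genes that should be present in the tissue, independent of expression
magnitude, and is the reading under which pooled quantile cuts behave
sensibly for shallow platforms.

# Filtering

Three sequential steps, each a pure row/column selection (counts are never
altered — an invariant the tests assert as exact submatrix equality):

1. **Slice**: drop slices with median cell score strictly below
   `min_score` (default 5). Medians are exact (mean of the central pair for
   even sizes). All cells of surviving slices continue.
2. **Cell**: keep cells with `n_genes ≥ min_genes`, `pct_mito ≤ max_mito`
   (default 0.10, inclusive), and no doublet call. Removal causes are
   tallied non-exclusively so report percentages are interpretable.
3. **Gene**: keep genes detected in at least `min_cells` cells, counted on
   the post-filter cells — the ordering matters and is tested with a
   fixture where pre-filter counting would keep a different gene set.

`min_genes` and `min_cells` default to sweep recommendations:
`recommend_min_genes()` returns the largest grid value at which more than
70% of cells survive in at least 90% of slices ("most" slices quantified
as 0.90, adjustable); `recommend_min_cells()` the largest value retaining
more than 99% of the marker set. Both inequalities are strict, and both
fall back to the smallest grid value with a warning when no value
qualifies. The `min_genes` grid is 40 evenly spaced quantiles of the
observed `n_genes` distribution; the `min_cells` grid is
{1, 2, 3, 5, 10, 15, 20, 30, 50}. Since recommending `min_cells` requires
markers, disabling markers while leaving `min_cells` unset is a
configuration error rather than a silent default.

Platform presets bundle defaults: stereo-seq keeps doublet calling on;
slide-seq ships permissive depth defaults (`min_genes` 340, `max_mito`
0.2) appropriate for shallow bead arrays; Visium disables doublet calling
(multi-cell spots make "doublet" meaningless); MERFISH disables mito
scoring (probe panels rarely include mitochondrial genes). Presets are
data and every field is overridable.

The before/after comparison re-measures the cleaned matrix but scores it
with the rubric fitted on the *pre-filter* dataset. Refitting quantiles on
the cleaned data would re-centre the scores and mask exactly the effect
the comparison is meant to show. The comparison itself is a Welch
(unequal-variance) two-sample t-test implemented from the closed form,
with the degenerate case of two identical constant groups defined as
t = 0, p = 1; `stats::t.test` serves as the independent oracle in the
tests.

# The doublet scorer

The pipeline: synthetic doublets are element-wise sums of uniformly
sampled pairs of distinct observed cells, at twice the number of observed
cells (`sim_ratio = 2`); observed and synthetic profiles are total-count
normalised to the observed median depth, log1p-transformed, restricted to
the top 1 000 genes by binned normalised dispersion, z-scored with
observed-cell statistics, and projected onto 30 principal components
fitted on observed cells only. For each point, the fraction of synthetic
doublets among its neighbours in the joint embedding is converted to a
posterior-style score with prior `expected_rate` (default 0.06).

Neighbourhood semantics follow the published reference implementation of
this strategy exactly: the base neighbourhood is `k = round(0.5·√N)`,
expanded to `k_adj = round(k·(1 + sim_ratio))` in the joint library so the
effective number of observed neighbours stays near `k`; after dropping
self, `k_adj − 1` neighbours are counted and the fraction is
Laplace-smoothed, `q = (n_sim + 1)/(k_adj + 2)`. The smoothing matters: a
raw fraction saturates at exactly 0 and 1 at finite `k`, and the saturated
mass at 1 distorts the score distribution on which the call threshold is
computed.

The call threshold is the density minimum between the two modes of the
synthetic doublets' own score distribution (synthetic doublets made of two
same-population cells score low; genuine cross-population constructs score
high). Because `q` takes at most `k_adj + 1` discrete values, the minimum
is located on that discrete support — an equal-width histogram shows
spurious valleys in the empty gaps between the widely spaced high-score
support points — smoothing the mass function with a moving-average filter
until at most two maxima remain, with the same 5%-of-maximum height floor
used by the KDE mode counter. Two guards handle degenerate shapes: a
unimodal distribution falls back to a fixed threshold of 0.25, and a
threshold that would call more than five times the expected rate is
rejected in favour of the same fallback (a valley inside the bulk of an
unstructured distribution is a sampling artefact, not evidence of
doublets). Datasets under 20 cells skip scoring with a warning and zero
scores. Scoring is disabled entirely for spot-based platform presets.

Pair sampling operates on indices taken after sorting cell identifiers,
so permuting the input rows permutes the scores identically — a property
the tests check.

# Kernel density estimation and mode counting

`kde_density()` is a plain Gaussian KDE with Silverman's rule-of-thumb
bandwidth, evaluated on an explicit grid (default 512 points over the data
range padded by three bandwidths). Constant input raises a
degenerate-bandwidth error; the caller is expected to plot a spike.
A mode (`count_modes()`) is a strict interior local maximum with height at
least 5% of the global maximum; the floor suppresses numerical ripples in
long tails. This is the instrument behind the report's complexity/depth
density panels, where a second mode flags a background (non-tissue)
population and its disappearance after a `min_genes` cut confirms the cut
removed that population and not tissue.

# The synthetic generator

`generate_dataset()` draws gamma–Poisson (negative binomial) counts: cell
depth is Gamma(shape = 2, mean = 2 000 counts) times a slice factor, times
a region factor, with the cell's gene distribution given by its expression
program. Defaults: 8 slices × 400 cells × 2 000 genes (plus 13 `MT-`
prefixed mitochondrial genes), 451 planted markers split between 2
programs, one planted low-depth slice (the 7th, at 0.2× depth), 6%
doublets, 5% dying cells.

Choices worth recording:

* **Program profiles** are Dirichlet-drawn with concentration 0.3 for
  non-marker genes — heavy-tailed, so the top ~100 genes carry about half
  the counts, as in real transcriptomes — and concentration 1 for markers,
  up-weighted ×10 in their own program. Markers are modelled as
  differential-expression-derived, hence robustly expressed in their
  program and never near-zero; this is what makes the ">99% marker
  retention at `min_cells` = 3" recommendation logic exercisable.
* **Doublets** share the spot's capture depth: both member cells are
  captured at the same efficiency, so their expected contributions are
  equal, with a Beta(6, 6) split for biological RNA-content variation and
  a total of about twice a singlet. Summing two *independently*-deep
  parents instead leaves roughly a third of pairs at >3:1 imbalance —
  indistinguishable from singlets for any neighbour-based scorer, which
  turns planted-doublet recovery into a test of the generator rather than
  the scorer.
* **Dying cells** draw mitochondrial fraction from Beta(8, 2) (versus
  Beta(1, 30) for healthy cells) and a per-cell depth multiplier from
  Uniform(0.2, 1): apoptosis progressively degrades cytoplasmic RNA, so
  dying cells form the classic low-count/high-mito smear rather than a
  coherent subpopulation that would add a spurious density mode.
* **`generate_bead_background()`** mixes tissue (as above, without slice
  or region defects and without doublets — a bead array's planted defect
  is its non-tissue background, and beads are smaller than cells) with
  background beads at 60:40 bead:tissue, bead depth Gamma with mean 60
  over a flat gene profile. The mixture makes the `n_genes` and
  `n_counts` densities bimodal; cutting at `n_genes ≥ 200` removes ≥99%
  of beads and collapses the density to one mode.

What the generator does **not** emulate: tissue morphology and spatial
expression gradients (coordinates are uniform per-slice unit squares,
doublets placed at pair midpoints), ambient RNA, segmentation errors,
platform-specific spatial noise, and batch chemistry effects. Tests
passing on this generator therefore demonstrate that the pipeline's rules
and recommendations behave as specified under controlled defects — not
that any particular real tissue will be cleaned optimally.

# Numerical conventions and problem sizes

Quantiles use R's default type-7 definition; all "at or above a quantile"
comparisons are inclusive; medians are exact. Sweeps count exactly — no
sampling. The HTML report embeds every figure's data as JSON islands and
renders client-side to SVG with inlined script; spatial scatters are
subsampled to at most 50 000 points per slice for responsiveness (flagged
in the panel; the JSON island keeps what was plotted). Reports are
byte-identical across reruns except the timestamp.

The validation suite runs the full stack at the generator's default size
(3 200 cells × 2 013 genes, ten seeds) for slice recovery and
threshold-rule rechecks, 800-cell two-program fixtures for doublet
behaviour, an 8 000-unit bead mixture for the bimodality collapse, and
twenty 200 × 300 random fixtures for exact brute-force equivalence of
metrics, medians, sweep curves, and detection counts.

# Known limitations

* Doublet recovery is threshold-limited: the automatic valley threshold is
  the method's weakest component, and planted-doublet recall on the
  800-cell fixtures ranges roughly 0.65–0.85 across generator seeds. On
  the same fixtures, the published reference implementation of the
  simulated-doublet scorer varies more widely still (recall 0.06–0.69
  across its internal random states), so this is a property of the
  strategy at shallow depth, not of this implementation.
* The rubric's sub-score table is a package design decision, not an
  externally calibrated standard; it is pluggable for exactly that reason.
* GEM files without a cell-label column are binned by exact (x, y)
  coordinate — the raw spot semantics; no coarser binning is offered.
* Gene-name matching (markers, mitochondrial prefixes) is case-sensitive
  by design: silent case-folding hides annotation mismatches.
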
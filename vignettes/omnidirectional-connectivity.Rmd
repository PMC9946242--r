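---
title: "Omnidirectional circuit-theory connectivity: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Omnidirectional circuit-theory connectivity: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omnicurrent)
```

This vignette is the package's own account of the science it implements:
the model, its assumptions, the parameters that matter, what the synthetic
generators do and do not emulate, and the design choices made where more
than one defensible option existed.

## The circuit model

A movement-cost raster assigns every cell a strictly positive cost
encoding how difficult it is for terrestrial, non-volant fauna to cross.
The raster becomes a resistor network: one node per cell, an edge between
neighbouring cells (8-connected by default; 4-connected by flag) with
resistance

$$r_{ij} = d_{ij}\,\frac{c_i + c_j}{2}, \qquad g_{ij} = 1/r_{ij},$$

where $c_i$ is cell cost and $d_{ij}$ is 1 for orthogonal and $\sqrt 2$
for diagonal neighbours. Injecting current $i$ and solving the Kirchhoff
system $L v = i$ on the graph Laplacian $L$ gives node potentials; the
per-cell *current density* is half the sum of absolute currents on
incident edges plus half the node's own injection or absorption (without
the halving every ampere would be counted entering and leaving). Current
density is proportional to the expected use of a cell by random walkers
moving between sources and grounds — concretely, the expected net number
of crossings of an edge by an absorbed random walker whose step
probabilities are proportional to edge conductance equals the edge current.
`random_walk_visits()` implements that walker as an independent Monte-Carlo
oracle, and the test suite holds the solver to it (Spearman rank
correlation above 0.9; in practice ≈ 0.99 at 2×10⁵ walkers).

Assumptions worth stating: movement is memoryless (a random walk, not
route planning); costs are isotropic and static; and the analysis is
purely terrestrial — masked cells (`NA`) are simply absent from the graph.

## The wall-to-wall omnidirectional protocol

One-pixel source and ground strips span two opposite raster edges; the
solve is repeated in the four cardinal directions and the four maps are
averaged cell-wise. Strip-to-strip boundary conditions remove the strong
dependence of current patterns on chosen source/destination nodes.

Two protocol details were genuinely open and are worth the rationale:

* **Injection normalization.** Each source-strip cell injects 1 A (the
  advanced-mode convention of the established circuit tools). The
  alternative — a fixed 1 A total per run — makes per-cell current scale
  like $1/n$ with raster size, which would (a) prevent the tile-size
  statistics from stabilizing and (b) give tiles of different sizes
  incompatible brightness, so their overlaps could not be averaged into a
  seamless mosaic. Per-cell injection keeps maps comparable across tile
  sizes, which the stitching workflow requires.
* **Ground treatment.** By default the ground strip is a *balanced sink*:
  each ground cell extracts an equal share of the injected total, and the
  singular system is solved with one node pinned per component. Under this
  boundary condition a run and its reverse are exactly identical by
  linearity, so the four-run mean equals the mean of the two distinct
  runs; all four are still computed to mirror the protocol. The classic
  hard ground (strip fixed at 0 V, absorbed current distributed as the
  solve dictates) is available as `ground = "hard"`; with it, opposite
  runs differ slightly — a 2×2 counterexample is easy to construct — which
  is the historical reason the protocol averages all four directions. The
  hard ground is also the boundary condition the walker oracle samples
  (walkers are absorbed wherever they first touch the far strip), so the
  oracle comparison uses `ground = "hard"`.

Numerical choices: sparse Cholesky factorization (CHOLMOD) with two sweeps
of iterative refinement; the residual contract ‖Lv − i‖∞ ≤ 10⁻¹⁰·‖i‖∞ is
checked before potentials are re-referenced (shifting a component by a
constant leaves Lv unchanged mathematically but a recomputed product picks
up O(|v|·ε) cancellation noise). Disconnected components are solved
independently; a source with no ground in its component is an error naming
the component.

## Cost surfaces

Cost schemas are ranked category → cost maps; the default
{1, 10, 100, 1000} spans the plausible range while the scenario machinery
(`scenario_table()`, `scenario_correlations()`) quantifies how little the
*pattern* depends on the absolute values: scenarios sharing rank order
correlate at ρ ≥ 0.86 over 1000 seeded cells on synthetic landscapes,
while broader ranges raise the maxima at pinch points. The lowest cost is
1, not 0, because the solver cannot take null resistance and uncovered
cells must still conduct.

Combination follows highest-cost-wins per cell across layers; cells
covered by no layer get the low cost, so the output has no nodata.
Natural-feature thresholds use the conventional operators exactly:
elevation > 2300 m, slope > 30°, lake area ≥ 10 ha, river flow > 28 m³/s
(all high cost), sea ice medium-low. Polylines are rasterized any-touch so
that thin roads and rivers cannot vanish at coarse resolution; polygons by
center intersection. Grid convention: row 1 is the northern row,
pixel-center registration, half-open cell extents.

## Tiling, stitching, seam repair

Large rasters are split into rectangular tiles, each solved on a window
buffered by 20 % of the mean tile side (clipped at the raster edge) to
push the artificial strips away from the cells of interest; buffers are
cropped before stitching, and overlapping cells take the mean across
covering tiles. On a 300×300 synthetic landscape, 150-cell tiles with a
20 % buffer reproduce the whole-raster map at Pearson r ≈ 0.95–0.98, and
the correlation is non-decreasing in the buffer fraction — tiling is an
approximation whose contract is correlation, not equality. `detect_seams()`
flags internal tile boundaries whose mean absolute cross-boundary
difference exceeds 3× the landscape-wide neighbour difference; this
statistic is an invention of the package (the original workflow judged
seams by eye), and repair tiles remain caller-specified.

The tile-size analysis runs the protocol on 50/50 split landscapes (half
low cost, half high, defaults 1/1000) at a ladder of sizes; because the
ladder is unevenly spaced, stabilization is judged on the discrete rate
|Δmean|/Δsize, which falls monotonically beyond the 100-cell size (mean
current ≈ 1.075 from size 100 on). Sizes up to 300 keep the analysis in
seconds; nothing but time limits larger sizes.

## Telemetry and roadkill validation

The used-vs-available design: per individual, 10 % of fixes are kept as
observed points (reducing serial autocorrelation), the 95 % isopleth of a
Gaussian-kernel utilization distribution on the full track defines the
home range (reference bandwidth `href = 0.5·(sd(x)+sd(y))·n^{-1/6}`), the
maximum displacement distance (greatest straight-line distance from any
fix back to the earliest fix) dilates it, and an equal number of available
points is drawn uniformly from the dilated region. Current density is
extracted at the focal pixel (or averaged within a buffer radius; with
300 m cells a 300 m buffer adds exactly the four orthogonal neighbours).
The case model is a REML random-intercept fit,
`current ~ case + (1|individual)`, with Wald 95 % intervals; the
interaction model adds `case × d_max`. Welch's unequal-variance *t*-test
(one-sided, event mean greater, two-sided by flag) with pooled-SD Cohen's
*d* serves point comparisons, and roadkill counts on 900 m road sections
are correlated with section mean current (section cells plus a one-cell
buffer) by Spearman with mid-ranked ties.

**Calibration caveat, stated plainly.** The random intercept absorbs each
individual's mean current level but not the *spatial mismatch* between its
used and available regions. On landscapes with sizeable patches the
current field is autocorrelated at home-range scale, each individual's
used-minus-available difference acquires variance the model does not see,
and the Wald interval for the case effect is anti-conservative (pilot
coverage 75–88 %). The package therefore demonstrates null calibration in
the regime where the model's assumptions hold — an uncorrelated
category mosaic (`patch_scale` ≪ 1 cell), where used and available sets
average over many independent cells and coverage reaches the nominal
level (18–20 of 20 null replicates). Real current maps are spatially
correlated; for real data this caveat applies to the original design as
much as to this reimplementation.

## The synthetic generators

* `generate_patchy_landscape()` — Gaussian-smoothed white noise quantized
  at equal quantiles; `patch_scale` is the smoothing SD in cells. It
  emulates multi-category patchiness, not real land-cover geometry (no
  linear infrastructure, no hydrology).
* `generate_split_landscape()` — the exact 50/50 two-cost landscape of the
  tile-size analysis.
* `simulate_tracks()` — a lattice walk choosing among the 8 neighbours
  with probability ∝ exp(β·z), z the standardized current map; proposals
  leaving the grid keep the animal in place, which makes the β = 0 kernel
  doubly stochastic and its stationary law exactly uniform (the property
  the null-calibration tests rely on). `displacement_coupling` spreads
  walk lengths over exp(±coupling); `preference_exponent` couples β to the
  length multiplier; `drift` adds per-individual directional persistence
  scaled by the multiplier — needed because a preference-biased walk
  alone concentrates in good habitat instead of ranging, so without drift
  realized displacement decouples from walk length. Study sizes used by
  the tests: 20 individuals × 100 steps (null and signal), 40 × 150 on a
  160×160 mosaic (interaction). Fix schedules are hourly and uniform; no
  attempt is made to mimic any particular collar programme.
* `simulate_roadkill()` — Poisson counts with log-intensity
  `intercept + slope · meanCurrent(section)`.

What passing these tests shows: the pipeline recovers a step-selection
signal it itself generated, stays calibrated under its null in the regime
described above, and reproduces the qualitative displacement interaction.
What it does not show: performance on real collar data with irregular
fixes, habitat-driven home ranges, or observation error.

## Degenerate inputs and tie-breaking

Spearman ties are mid-ranked; modal resampling breaks ties toward the
lowest category code; quartile mover bins are rank-based and classify
everything as middle (with a warning) when all distances coincide; UD
isopleth masks include all cells tied at the threshold density; a
zero-variance mixed-model response yields zero standard errors rather
than a dropped fit; coincident UD points collapse to the single
containing cell with a warning; walkers exceeding the step cap
(100·(nrows+ncols)) are discarded and counted, with a warning above 1 %.

## Known limitations

Single CRS assumed (no reprojection); pairwise/focal-node and
moving-window omnidirectional variants are out of scope; the solver is
direct-factorization only, sized for desk-scale rasters (≈10⁵–10⁶ nodes);
cost schemas are expert-opinion constructs — the package quantifies
sensitivity to them but cannot validate them.
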
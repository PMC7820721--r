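---
title: "Mining running situations: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining running situations: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`runsit` implements a two-stage analysis of running behavior: clustering
runners by their annual activity pattern, then mining temporal and
environmental *situations* that are frequently associated with runs longer
or shorter than a runner's personal average. This vignette is the package's
own account of the method: the models and their assumptions, the parameters
that matter, the conventions adopted where several were defensible, and what
the synthetic-data validation does and does not establish.

## 1. The data model

A *run record* carries an activity and user id, total distance (m), a start
timestamp, planar start coordinates, and four measured weather fields
(temperature °C plus weather/wind/humidity categories). Records are cleaned
before analysis: runs under 100 m (exactly 100 m is kept), missing or
malformed fields, unknown categorical values, and start points without
geographic context are dropped with per-reason accounting; users with fewer
than 10 retained runs over the whole horizon are then removed. Cleaning is
total and idempotent.

Each retained run becomes a **transaction**: 29 categorical (feature, value)
items plus a signed weight.

* **Temporal (3).** Hour of day in eight half-open 3-hour bins
  `[0,3) … [21,24)`; weekday (Monday–Sunday, from the timestamp, fixed
  English names, no locale dependence); month.
* **Weather (4).** Temperature in five width-8 bins over [−10, 30] °C;
  weather (9 categories), wind (5), humidity (3) passed through. Bins are
  left-open right-closed — 11 °C falls in `(6,14]` — with the lowest bin
  closed at −10 and out-of-range values clamped with a warning. Only the bin
  count and range are treated as normative; the closure side is a package
  convention.
* **Topographical (18).** On a 100 m analysis grid: the center-to-center
  Euclidean distance from the start cell to the nearest cell of each of 9
  landuse classes (parks, sports, recreation, forest, water, agriculture,
  traffic, residential, cbd), and the percentage of each class in a 10×10
  cell (1 km²) window. A 10-cell window has no exact center cell; the window
  spans rows `[r−5, r+4]` and columns `[c−5, c+4]`, clipped at raster
  borders with the denominator reduced to the cells actually present. "The
  nearest region" is approximated by the nearest class *cell* at 100 m
  resolution, which is exactly what a precomputed raster supports.
* **Demographic (4).** Population density and three household percentages
  of the neighborhood containing the start point, found by point-in-polygon
  query; a boundary point belongs to the first polygon in table order that
  covers it (an explicit on-edge test backs this tie rule up, since generic
  point-in-polygon tests are agnostic on boundaries).

**Discretization.** Geographic and demographic features get a dedicated
`"0"` category (distance 0 means the class is underfoot; coverage or
density 0 means absence) plus 10 equal-probability bins over the strictly
positive values of the *reference landscape* — all grid cells, computed once
and frozen. Quantiles use the nearest-rank method so edges are data values
and the scheme is deterministic; duplicate edges on discrete distributions
are merged, so a degenerate feature may have fewer than 10 positive bins.
Whether the upstream convention included zero cells in its quantiles is not
decidable from the description; the zero-exclusive convention was chosen
because the zero category is listed separately from the decile bins.

**Weights.** The per-user normalization is

$$w \;=\; \frac{y - \operatorname{mean}(y^{u})}{\max(y^{u}) - \min(y^{u})} \in [-1, 1],$$

computed over **all** of a user's retained runs across the full horizon
(not just the clustering window): the normalization expresses a run against
the user's overall ability. A run at the user's mean maps to exactly 0; if
a user's runs are all identical the weight is 0 by convention (avoiding a
0/0 while preserving the at-the-mean semantics). Weights per user sum to
zero, a conservation law the tests rely on.

**Weekly activity.** Runs are counted per ISO-8601 week (an unambiguous
calendar convention); per user, the 52-consecutive-week window with the
most runs is selected, ties broken by the earliest start, and histories
shorter than 52 weeks are right-padded with zeros. The row sum of this
matrix is the "annual run count" used to profile clusters.

## 2. Runner clustering

Pairwise similarity between 52-week sequences uses classic dynamic time
warping: local cost $|a_i-b_j|$, unit steps (match/insert/delete), anchored
endpoints, no warping window. The implementation is a two-row dynamic
program in C++; tests verify it against an independent full-matrix dynamic
program and, on tiny sequences, against exhaustive enumeration of all
warping paths.

Ward agglomerative clustering then runs on the DTW matrix with the standard
Lance–Williams update on squared distances,

$$d(C_x,C_y)^2=\frac{(n_i{+}n_y)d(C_i,C_y)^2+(n_j{+}n_y)d(C_j,C_y)^2-n_y\,d(C_i,C_j)^2}{n_i+n_j+n_y},$$

which is identical to `hclust(method = "ward.D2")` and is cross-checked
against it to 1e-8. A variant lacking the subtracted term and using
$n(C_x)+n(C_y)$ denominators throughout circulates in the literature; it is
available behind `update = "as_printed"` for comparison, but the standard
recurrence is the default because it is the established Ward form and
enables oracle testing. Exact merge ties are broken by the smallest pair of
cluster indices (clusters indexed by their smallest leaf), making the
linkage deterministic across platforms.

Two caveats are documented rather than "fixed": DTW is not a metric and not
Euclidean, so Ward's variance interpretation is heuristic on this input —
the method is applied regardless, as is common in this literature; and the
dendrogram cut height is a free parameter whose scale depends on the data,
so the pipeline defaults to cutting into `n_clusters = 2` groups (the
threshold is derived as the midpoint of the relevant merge-height gap) with
`cut_threshold` available when a fixed height is preferred.

## 3. Weighted frequent itemset mining

The weighted support of an itemset $X$ is $w(X)=\sum_m w_m$ over
transactions containing $X$; its sign says whether the situation accompanies
above- or below-average distances. Items with $|w(i)|\ge\sigma$ form the
header table, sorted by descending $|w|$ (ties alphabetically — the
insertion order is a free choice and is fixed for determinism), and
transactions are compressed into a prefix tree whose nodes accumulate signed
weight and count; mining proceeds by conditional pattern bases.

Signed weights destroy the anti-monotonicity that classical FP-growth
pruning relies on: a pair can clear $\sigma$ while both singletons cancel to
near zero. The package therefore ships two modes:

* `exhaustive` (default): conditional bases are recursed without
  intermediate $|w|$ pruning (only zero-count paths and the `max_len` cap
  bound the recursion), so the output is *exactly*
  $\{X : |w(X)|\ge\sigma,\ |X|\le \texttt{max\_len}\}$. This declarative
  semantics is what the brute-force oracle checks on hundreds of random
  instances. `max_len` defaults to 4 to bound the combinatorics; the
  situations of interest in this domain are short conjunctions.
* `pruned`: items below $\sigma$ are also dropped inside conditional bases —
  the classic heuristic; faster, possibly incomplete, and provably a subset
  of the exhaustive output at equal $\sigma$ (every reported value is still
  exact).

$\sigma$ has no canonical value; the pipeline's default `sigma = "auto"`
sets it to 5× the Monte-Carlo null standard deviation of single-item
supports, estimated by permuting weights (which severs every
situation–weight association while preserving both margins). Under a null
simulation this yields zero discoveries; planted effects exceed it by an
order of magnitude.

Reports are assembled per feature *category* (temporal, weather,
topographical, demographical): mining runs on each category's features
separately — matching how multi-feature situations are usually presented,
and keeping the exhaustive search tractable — and the top-k positive and
negative situations are tabulated per category. Per-feature **variability**
is the population standard deviation of a feature's value supports over its
*observed* categories (never-occurring categories are excluded; including
structural zeros would deflate comparisons between features with different
vocabulary sizes). Value **histograms** report count and support per
category over the full vocabulary, and conserve totals exactly.

## 4. What the synthetic generator emulates

The generator exists so that every stage can be validated by parameter
recovery. It emulates, per seed and bit-reproducibly:

* **Landscape:** a Voronoi-patch landuse raster (contiguous regions, so
  distance and coverage features have spatial autocorrelation; default
  60×60 cells of 100 m) with a realistic class mix, and rectangular
  neighborhoods tiling the extent whose population density is tied to
  residential coverage (uninhabited zero-density polygons occur, exercising
  the `"0"` bins).
* **Two runner archetypes**, matching the empirically observed clusters: a
  *sporadic* type (~34 runs/year, concentrated in a user-specific ~18-week
  seasonal block repeated at the same phase each year) and a *regular* type
  (~94 runs/year spread over all weeks); 80/20 mix, per-user rates Gamma
  with CV 0.25, per-user baseline distances (5.0±1.2 km and 8.0±1.5 km).
  Within a year, runs are placed quasi-evenly over the active weeks (even
  base load plus randomly placed remainder): with fully independent weekly
  sampling, the *most-active-window* statistic systematically overshoots
  the annual rate (the maximum over ~150 overlapping windows, and over
  hybrid windows straddling two seasonal blocks, inflates by 15–20%),
  whereas the archetypes are defined by the windowed measure; quasi-even
  placement makes that statistic an unbiased read of the rate.
* **Run context:** weekday and 3-hour-slot preferences aligned with the bin
  boundaries (Sunday and late-morning favoured, so planted temporal effects
  sit on real probability mass); a month-conditioned weather model
  (sinusoidal monthly temperature means ~3–18 °C with 3.5 °C noise,
  season-dependent category frequencies); start locations drawn with
  elevated weight in and within ~300 m of residential cells.
* **Distances:** user baseline + matched planted effects × archetype
  sensitivity + Gaussian noise (default sd 500 m; recovery experiments use
  300 m), floored at 50 m. A 2% fraction of "aborted" recordings
  (50–400 m) and 0.5% missing weather records give the cleaning rules real
  work; both are parameters and can be disabled.
* **Planted effects** are additive distance shifts attached to sets of
  temporal/weather items (the features computable inside the generator;
  effects on geographic bins would require the enriched context stack at
  simulation time and are rejected with a clear error). The default plant
  is +800 m on Sunday 9:00–12:00 and −600 m on Wednesday 18:00–21:00, with
  the sporadic archetype twice as sensitive and the regular archetype half
  as sensitive — reproducing the qualitative finding that less regular
  runners react more strongly to circumstances.

It deliberately does **not** emulate: real geography or class frequencies,
spatially or serially correlated weather fronts, GPS measurement error,
user churn or enrollment drift, within-track context (only start points are
modelled), or any dependence of *whether* someone runs on the situation
(effects act on distance given a run — the same selection limitation the
empirical design has). Passing recovery tests therefore shows the pipeline
is *correct* (it finds exactly what is planted, and nothing under the
null); it does not show that real running data contains such effects.

## 5. Numerical conventions and degenerate inputs

* Determinism: every generator routes randomness through a locally scoped,
  fully specified RNG; the pipeline fans one master seed out into per-stage
  child seeds so single stages can be re-run reproducibly. Identical
  configurations give byte-identical artifacts.
* Distance rasters demand the class exists in the raster (the distance is
  undefined otherwise — an error, not NA); an all-one-class raster gives an
  all-zero distance raster and degenerate (single-bin) coverage schemes.
* All-zero reference values collapse a feature to the single `"0"` category
  with a logged warning; binning values above the frozen reference maximum
  clamp into the top bin.
* Merge-height ties in Ward, equal-sum weekly windows, and equal-|w| header
  items all have explicit deterministic tie-breaks (smallest index pair,
  earliest window, alphabetical item).
* Problem sizes used in the packaged experiments — 500 users, 60×60-cell
  landscape, 4 simulated years (~90k runs) for recovery; 200 users for null
  calibration; rasters ≤ 40×40 for the exact brute-force oracles — were
  chosen so each validation exercises realistic volumes while the full
  suite stays fast enough to run routinely.

## 6. Known limitations

Ward-on-DTW lacks a variance interpretation (above); the mining reports
associations, not causal effects, and no significance testing is attached
to supports (by design — the upstream method defines none); the exhaustive
miner's cost grows with the number of *occurring* itemsets, so very low
σ together with large `max_len` on the full 29-feature table can be
expensive — the per-category defaults keep it well-behaved; and the
point-in-polygon edge rule depends on polygon table order, which is part of
the data contract, not geometry.
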
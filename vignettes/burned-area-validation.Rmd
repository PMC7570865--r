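---
title: "Validating burned-area maps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating burned-area maps: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firescar)
```

# The problem

Global burned-area (BA) products map, per year, which pixels burned. Before
such maps feed carbon, vegetation or fire-management models, their error
structure must be quantified against independent reference data — typically
agency fire perimeters digitized from high-resolution imagery. This package
implements that assessment for the common setting of one reference
perimeter set and several candidate products co-registered on a single
projected equal-area grid, and adds the resolution-attribution step: how
much of a product's error is forced by sub-pixel fragmentation at its
native resolution, rather than by its detection algorithm?

# The model and its pieces

## Reference rasterization

Perimeter polygons become a binary map by the **maximum-area rule**: pixel
Burned iff the burned fraction of its footprint is ≥ 0.5. Fractions are
computed by exact polygon–pixel intersection (Sutherland–Hodgman clipping
of each ring to the pixel rectangle, shoelace area, holes subtracted).
Two numerical choices are deliberate:

* **Tie rule.** A pixel exactly half burned is labelled Burned. Any
  deterministic rule works; ties must not depend on floating-point luck,
  so the comparison carries a 1e-9 tolerance. Test oracles exclude pixels
  whose true fraction lies within 0.05 of the threshold.
* **Grid convention.** The origin is the upper-left corner; pixel
  `(row, col)` spans half-open intervals so every point belongs to exactly
  one pixel; row 1 is the top row. This matches common raster practice.

Self-intersecting rings are rejected rather than repaired — topology repair
is out of scope, and silently "fixing" a perimeter would change its area.

## Temporal and spatial accuracy

The annual detected percentage is a ratio of totals,
`P = 100·ΣBAP/ΣBAR` — deliberately blind to location, which is why the
spatial metrics exist. The all-years value is the reference-area-weighted
mean of the annual values, computed as a ratio of multi-year sums. Years
with exactly zero reference area are excluded from these sums (they cannot
occur in a real perimeter record, but synthetic series may produce them and
must not crash).

Spatial accuracy uses the standard two-class confusion matrix, with the
classified map on rows and the reference on columns. One definitional point
deserves a flag: specificity is the rate of correctly identified Non-Burned
pixels, so its denominator is the reference Non-Burned total `n2r`
(printed renderings of this matrix sometimes show `n1r` in that slot, which
contradicts the definition; the definition wins here). Because the
Non-Burned class dominates boreal landscapes, OA and Sp are near 1 for any
map and are reported only for completeness; CE and OE carry the signal.

CE and OE are not directly comparable — CE is a fraction of the *map's*
burned area, OE of the *reference's*. The weighted total error
`TE = CE·P + OE` (equivalently `TE_ha = CE·BAP + OE·BAR`, with
`TE = TE_ha/BAR`) puts them on one scale. TE may exceed 1: a product that
detects a little, all of it wrong, in a year it also misses everything,
earns CE = OE = 1 and TE = 1 + P.

Empty-class conventions: a product that detects nothing has CE := 0 (its
commission is vacuously empty) and OE = 1; an empty reference year sets
OE := 0 with a warning. These keep annual series well defined.

## Pareto boundary and AUPB

Aggregating the 50 m reference map by an integer factor gives per-pixel
burned fractions at 250/300/500 m. A strict binary classification of that
fraction map must call each mixed pixel Burned (committing its unburned
fraction) or Non-Burned (omitting its burned fraction). Sweeping the
minimum-fraction threshold `p` traces the locus of minimal (CE, OE) pairs
— the Pareto boundary. Errors on it are attributable purely to resolution.

Choices pinned here, each surfaced in the docs:

* **Threshold semantics.** `B = {f ≥ p}` for `p > 0`; at `p = 0`,
  `B = {f > 0}`, so fully unburned pixels are never classified Burned and
  the curve is anchored at the maximal-CE/zero-OE end. The `p = 1` end
  always includes the empty classification `(CE, OE) = (0, 1)` — reachable
  whenever no coarse pixel is fully burned — so the equidistant and exact
  sweeps agree.
* **Area-based errors.** CE and OE are computed on pixel-area fractions
  (classifying a mixed pixel as Burned commits `1 − f` of one pixel), not
  on pixel counts; the two agree only for pure pixels.
* **Pareto filtering.** Duplicate and dominated (CE, OE) pairs are removed
  before integration, making OE(CE) single-valued — the trapezoidal rule
  over a non-functional relation would be ill-defined.
* **Steps.** Default 101 equidistant thresholds; `n_steps = "exact"`
  sweeps every distinct pixel fraction (plus 0 and 1) and is the reference
  semantics. For fractions arising from integer aggregation factors
  `f ≤ 31` the distinct values are ≥ 1/961 apart, so a 1001-step sweep
  reproduces the exact curve identically; the tests assert this.

AUPB integrates OE over CE by the trapezoidal rule, giving a value in
`[0, 1]`: 0 iff every coarse pixel is pure. Coarser aggregation can only
merge burned with unburned area, so AUPB is non-decreasing in the
aggregation factor — asserted on synthetic landscapes, and consistent with
published boreal assessments where the 500 m value is about triple the
250 m value. Finally, annual TE is regressed on annual AUPB by ordinary
least squares (via `stats::lm`); the slope measures the product's error
sensitivity to fragmentation.

`distance_to_boundary()` (minimum Euclidean distance to the piecewise
linear curve) is reported as a diagnostic of error *not* explained by
resolution; it is not part of any summary statistic.

# The synthetic generator

The generator emulates the features of a boreal fire record that the
pipeline is sensitive to, and nothing more:

* **Size structure.** Five size categories with half-open boundaries at
  100 / 1,000 / 10,000 / 100,000 ha. Sizes are drawn log-uniformly within a
  category: the real size-frequency law inside categories is not known
  from category shares alone, so the package exposes it as configuration
  (explicit `sizes_ha`) rather than asserting one. Configured counts make
  area shares as skewed as real records (where large and very large fires
  are ~14% of fires but ~82% of area).
* **Scar shape.** Each fire grows as a 4-connected blob by seeded random
  boundary accretion, giving irregular perimeters whose edge layers make
  the perimeter-biased degradation and the fragmentation analysis
  non-trivial. Fires do not overlap; infeasible packings (more than half
  the grid requested, or a blob walled in after 25 restarts) error with
  the achieved-vs-requested sizes.
* **Known error rates.** `perturb_product()` removes
  `round(OE·n_burned)` reference pixels and adds
  `round(CE·kept/(1 − CE))` false pixels, so the measured confusion-matrix
  rates equal the targets to the nearest pixel — within ±0.01 for scars of
  ≥ 5,000 pixels, which the tests assert over a grid of targets and seeds.
  `uniform` mode is the statistically clean default; `perimeter_first`
  erodes whole edge layers first (random within the last partial layer)
  and commits in rings around the scar, mimicking products that miss scar
  margins.
* **Determinism.** Everything is seeded; multi-year series derive per-year
  seeds from a master seed by a 32-bit-safe arithmetic mix, so years are
  decoupled but the series is exactly reproducible.

What the generator does *not* emulate: fire spread physics, burn severity,
day-of-burn timing, land cover, or sensor artefacts (cloud, view angle).
Passing tests therefore demonstrate the correctness of the *accounting* —
rasterization, metrics, boundary construction, regression — on data with
known truth; they do not certify any real product's accuracy, which
depends on real reference data.

# Degenerate inputs and numerical conventions

* Aggregation requires divisible dimensions by default; `pad = TRUE`
  zero-pads partial edge blocks and flags the affected coarse pixels,
  which are then excluded from Pareto statistics (their fractions are
  biased low by construction). The padded and cropped analyses agree
  exactly on the divisible core.
* Area conservation under aggregation (`Σ fractions × coarse pixel area =
  fine burned area`) holds to machine precision and is asserted on 1,000
  random grids.
* An entirely unburned fraction map has no defined OE and errors out; an
  empty reference map makes the annual percentage undefined and errors
  out.
* Percentages are printed at 2 decimals and errors at 3 (AUPB as
  `×10⁻³`), mirroring how such tables are published; all internal
  computation is full precision, and the JSON bundle round-trips the
  full-precision values.

# Problem sizes used in the test-suite

The suites run on deliberately modest sizes chosen to exercise every code
path with comfortable margins: toy fraction maps with hand-enumerable
boundaries; 150×150-pixel landscapes (≈ 5,600 ha) for recovery tests;
200 random coarse grids of ≤ 400 pixels for the sweep-equivalence
property; 100 landscapes of ≈ 350 ha for the AUPB monotonicity property.
These sizes make every statistical property tested here a finite, exact or
tightly-toleranced statement rather than an asymptotic one.

# Known limitations

* No reprojection: all inputs must share one projected equal-area frame.
* Binary annual maps only — no day-of-burn or multi-band support.
* Shapefile input is not supported; perimeters are read from projected
  GeoJSON (and rasters from ESRI ASCII grids).
* The TE-vs-AUPB regression is ordinary least squares on annual pairs;
  with short series (n < ~10) its R² is a descriptive, not inferential,
  quantity.
* `categorize_fires()` trusts recorded areas where present; realized
  (rasterized) areas can put a fire near a category boundary on the other
  side of its recorded area.
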
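---
title: "Scoring location data integrity and estimating planting effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring location data integrity and estimating planting effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(ldiscore)
```

## The problem

Reforestation projects on the voluntary carbon market self-report where they
plant. Any satellite-based check of those claims rests on one fragile input:
the reported site boundary. If the "site" is actually a buffered point, a
whole administrative district, a duplicate of another listing, or an invalid
ring, every downstream NDVI trend computed over it is meaningless.

`ldiscore` audits reported planting-site geometries with ten binary
indicators and aggregates them into the 0–10 Location Data Integrity Score
(LDIS), then quantifies post-planting greening with vegetation-index panels
over each site and its 500 m buffer annulus, a two-period
difference-in-differences (DiD) regression, and a bucket-weighted synthetic
control. A seeded generator emulates every input layer, so the entire
pipeline is testable offline.

## The ten indicators

An indicator *fails* when its rule fires; the score counts passes. The
thresholds and their strictness follow the published rules verbatim:

| indicator | rule (fail when) |
|---|---|
| `road_presence` | road corridor covers **more than** 10% of the site |
| `built_area_presence` | built-up cells cover **more than** 10% |
| `forest_at_planting_glad` | tree cover at planting is **20% or more** |
| `other_landcover_score` | other land cover (incl. permanent water by default) is **20% or more** |
| `stable_cropland_score` | stable cropland is **20% or more** |
| `nesting_polygon` | the site is (near-)contained in another site |
| `intersecting_polygon` | the site partially overlaps another site |
| `exact_admin_area` | >98% mutual area overlap with an administrative region |
| `perfect_circle_indicator` | circularity at or above 0.95 |
| `geometry_validity` | the ring is not a closed simple polygon |

Two rules were described with different numbers in different places in the
source material: the circle flag (95% vs 98%). We default to
`circle_frac = 0.95` — the value used where the score itself is defined —
and expose it in `ldis_config()`. Likewise the assignment of permanent
water (infrastructure rule vs land-cover rule) is a config switch,
defaulting to the land-cover side.

**Missing inputs.** Sites are scored even when some layers are absent.
By default a missing indicator is neither pass nor fail: the score counts
passes among evaluated indicators and `completeness` records how many of
the ten were evaluated. A strict mode treats missing as fail. Both are
reported rather than silently mixed because the choice changes the meaning
of "perfect score" for sparsely covered sites.

## Geometry methodology

All stored coordinates are WGS84 lon/lat; all measurement is metric.

* **Areas** are geodesic on the WGS84 ellipsoid (`geosphere::areaPolygon`),
  so no projection needs choosing and no UTM zone bookkeeping exists.
* **Metric work** (buffering, circularity, overlap ratios, zonal
  statistics) happens in a per-feature azimuthal-equidistant frame built
  from geodesic distance and azimuth about the feature's anchor point.
  Distortion over the few-kilometre extents involved is negligible
  relative to every tolerance used.
* **Circularity** is the Polsby–Popper isoperimetric quotient
  4&pi;A/P&sup2;: exactly 1 for a disc, &pi;/4 for a square. The source
  material names the quantity but not a formula; Polsby–Popper is the
  standard compactness score whose value 1 matches "perfectly circular".
* **Point sites** become discs of radius 100 m discretized at 64 vertices;
  the discretized disc has 99.84% of the true area and circularity
  &asymp; 0.998, comfortably above the circle threshold — which is why a
  point-derived cohort can never score 10/10.
* **Buffering** (the 500 m annulus) offsets edges outward and joins them
  with vertex arcs. This is exact for convex rings and discs; concave
  rings fall back to their convex hull with a warning. A full polygon
  offsetting engine was deliberately out of scope; the fall-back is
  conservative (annulus slightly too far out) and flagged.
* **Validity** means: at least three distinct vertices, no
  self-intersection, and area above a scale-invariant thinness cutoff
  (area/P&sup2; &gt; 1e-10), which also catches collinear rings whose
  shoelace area is only nonzero through round-off.
* **Overlap relations** use the published >95% rule on both ratios
  I/|A| and I/|B| (duplicates), one ratio (nesting), otherwise plain
  intersection. Duplicates are recorded as mutual nesting because the
  published schema has no duplicate column; a log line counts them.
  Candidate pairs come from a bounding-box grid index; a brute-force mode
  exists purely so tests can prove the index changes nothing.
* **Intersection areas** are computed by Sutherland–Hodgman clipping
  whenever either ring is convex (exact for simple subjects against a
  convex clip) and by a deterministic 256&times;256 grid estimate for
  concave–concave pairs.

## Overlay statistics

Cells contribute their **exact intersection area** with the site polygon,
not centre-point membership: the median reported site is far smaller than
1 km², where centre-point counting quantizes badly. Road presence converts
clipped road length into covered area through a configurable corridor
width (default 10 m), matching the published storage of road length
alongside an area rule; corridor self-overlap at crossings is not
de-duplicated. Loss-year windows are [p−5, p−1], {p−1} and [p+1, p+5]
around planting year p; post windows extending past the raster's last
encoded year are truncated *and flagged*, never silently shortened. Slope
uses Horn's 3&times;3 finite differences with replicated edges.

## Vegetation indices and panels

NDVI = (NIR−Red)/(NIR+Red), NDRE the red-edge analogue. SAVI follows the
formula as printed in the source material — red-edge band, soil constant
L = 0.5, multiplier (1+L) — although conventional SAVI uses the red band;
we do not silently "correct" it, and `use_red = TRUE` plus a free `L`
give the conventional variant.

Scenes are rejected when the cloud fraction over the *site* footprint is
20% or more (retention is strictly below the threshold). Within a period
the `greenest_k = 3` scenes by site-level NDVI are composited with the
median (mean by config); fixed regional month lists (e.g. Jan/Apr/May for
Africa) can bypass selection. Panels record zonal area-weighted means per
site &times; zone (site, annulus) &times; period, with periods at
planting-year offsets {−1, 0, +1, +2, +5}. Unbalanced panels are left
unbalanced; balancing is an explicit analysis step.

## Impact analysis

The DiD model is the saturated two-period two-zone regression

Y = intercept + &beta;&#8321;·g + &beta;&#8322;·t + &beta;&#8323;·(g&times;t) + &epsilon;,

with g = 1 on the site (annulus as control) and t = 1 in the comparison
period. OLS on this design equals the four cell-mean contrasts, and
&beta;&#8323; is the DiD estimate. Standard errors are classical
homoskedastic OLS errors, matching how the reference regressions are
reported; site-clustered errors are available but off by default. The
pre-planting specification treats the planting date itself as "after" and
the year before as baseline. `counterfactual_series()` reproduces the
no-interaction predictions whose gap to the observed treated-after mean is
exactly &beta;&#8323;.

Bootstrap confidence intervals resample **sites** (both zones travel
together), percentile method, seeded. The synthetic control buckets the
sites' at-planting NDVI distribution into `n_buckets = 10`
equal-probability quantile buckets (the count is not stated in the source
material; 10 is exposed in the call), assigns sampled control points by
their own at-planting NDVI — outer buckets are unbounded so no control
point is discarded at the tails — and reports per-period means weighted by
the sites' bucket shares, re-normalizing over occupied buckets with a
warning when some are empty.

## The synthetic generator

The generator is the package's study-condition definition, not a tuning
knob. `ldis_scenario()` defaults describe a small equatorial landscape:
sites of 100–250 m nominal radius on a 2.5 km grid (so no 500 m annulus
touches a neighbour), planting year 2018, background NDVI 0.30, site
pre-planting NDVI 0.35, a clearing dip of 0.10 at planting, recovery of
0.02 NDVI/yr, and 30% spillover of the site trend into the annulus — the
qualitative pattern described for real sites (higher pre-planting NDVI,
post-planting recovery, buffer co-movement). Pathology rates default to
20% points, 20% near-perfect circles, 10% admin copies, 10% duplicates,
10% nested children, 10% partial overlaps, 5% invalid rings.

Reflectance is synthesized by inverting the index formulas with
NIR + Red = 1, so painted cells hit target NDVI **exactly** and
zonal-mean tests are sharp. Raster violations are painted at 0.45 (for
the 20% rules) and 0.30 (for the 10% rules) — far from the thresholds, so
one-cell quantization cannot flip an indicator; that is what makes the
end-to-end ground-truth comparison an exact test rather than a tolerance
band. Injected relations (duplicates, nesting, overlap partners) are kept
off the violation-eligible list so a painted stripe on a parent cannot
leak into a child's ledger.

What the generator does **not** emulate: real landscape texture,
correlated cloud fields, mixed planting dates within a scene, concave
site boundaries, datum errors. Passing tests therefore demonstrate the
pipeline's correctness on well-posed inputs, not the accuracy of any
real-world dataset.

## Problem sizes and numerical choices

The reference regressions are re-simulated at their printed sample sizes
(469,500 observations; the pre-planting column prints 139,250, which is
not divisible by four, so the generator uses 139,248). The end-to-end
ground-truth scenario uses 50 sites at 20–25 m resolution; the
point-cohort property uses 10,000 sites. These sizes are the package's
test-design choices: large enough that coefficient recovery lands within
±0.003 and R² within ±0.002, small enough to run on a desk.

Tie-breaks and degenerate cases: greenest-month ties resolve to the
earlier calendar month; equal-quality admin matches resolve to the larger
min-overlap ratio; duplicate site ids are suffixed deterministically
(`id`, `id-2`, ...) rather than rejected, because the upstream sources
are explicitly messy; year-only planting dates resolve to July 1;
multipolygon children are numbered in drawing order and zero-area sliver
parts dropped with a logged count; reported and derived areas are both
kept and never reconciled.

## Known limitations

* Concave rings: buffering falls back to the convex hull (warned);
  concave–concave intersection areas are grid-estimated.
* Raster IO is plain-text ESRI ASCII grid with a JSON sidecar; vector IO
  is GeoJSON and CSV-with-WKT. Interchange with binary container formats
  is out of scope here.
* The common-trend assumption behind the DiD design is reported
  (pre-period gaps are visible in the panel) but not formally tested.
* Scores on real data inherit every upstream data quality issue (road
  vintages, land-cover misclassification); the score audits geometry
  integrity, not project quality.
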
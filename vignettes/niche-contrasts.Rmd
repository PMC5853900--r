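---
title: "Sister-group niche contrasts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sister-group niche contrasts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichecontrast)
```

## The question and the design

C3–C4 intermediate plants carry part of the C4 carbon-concentrating
machinery, and multiple flowering-plant lineages hold such intermediates
alongside close C3 and C4 relatives. Whether the intermediate condition
is associated with a consistent environmental shift cannot be read off a
pooled species comparison: relatives resemble each other ecologically for
reasons unrelated to photosynthesis (niche conservatism), so species are
not independent data points. The sister-group design used throughout this
package treats each lineage as one comparison: the niche summary of its
C3–C4 members against that of its C3 sister group, and likewise C4
against C3–C4. Two complementary statistics are computed across lineages:

- a **Kendall rank correlation** between the paired values. A positive
  correlation means lineage identity predicts the niche — a phylogenetic
  effect. Rank-based, so unequal divergence times across lineages and
  non-normal variables do not bias it.
- a **sign test** on the number `k` of lineages in which the focal type's
  value exceeds the reference's, out of `n` non-tied lineages. A
  consistent directional shift associated with the photosynthetic type
  shows up as `k` far from `n/2` under a Binomial(`n`, ½) null. The
  magnitude of each within-lineage difference is deliberately ignored;
  only its direction enters, which is what makes the comparison robust to
  lineage age differences.

Eight variables are tested (two PCA axes and six individual variables:
growing-season temperature, coldest-month minimum temperature,
driest-month precipitation, rainfall seasonality, topsoil organic carbon,
total exchangeable bases), and each p-value is compared with the
Bonferroni-corrected threshold `0.05 / 8 = 0.00625`.

## Aggregation: median, then mean of medians

Occurrence data are noisy: misidentified specimens and bad geocodes
produce extreme environmental values. Per species and variable the
package therefore uses the **median** over occurrences. Group values are
the **arithmetic mean of member-species medians**, so every species
weighs equally regardless of record count. Species with a single retained
occurrence are kept (several real taxa have exactly one usable record); a
warning can be requested via `species_medians(warn_singletons = TRUE)`.

## The sign-test tail convention

The package's default (`method = "paper"`) two-tailed p-value is

$$p = \min\big(1,\; 2\,\min(F(k),\, 1 - F(k))\big),$$

with $F$ the Binomial($n$, ½) CDF: the observed count is included in the
lower tail and excluded from the upper. This is not the textbook
symmetric convention $2\min(P(X \le k), P(X \ge k))$ — the two differ
whenever the observation sits in the upper tail (12 of 14 gives 0.0018
under the default but 0.0129 symmetric). The default is the convention
that reproduces, at printed precision, every published p-value in the
shift-count table packaged as `table4_counts()`; the symmetric version is
available behind `method = "symmetric"`. Two edge cases:

- at `k = n` the upper tail beyond the observation is empty, which would
  give `p = 0`; the package substitutes `P(X >= n)` so p stays in (0, 1].
- at `k = n/2` (even `n`) the convention yields `2(1 - F(n/2)) < 1`
  (0.79 at 7/14), not 1; the symmetric convention yields 1 there. The
  published table's own 6/14 → 0.79 entry is consistent with the default
  convention.

Tail masses for `n <= 30` are accumulated by exact integer arithmetic
(binomial coefficients over a power of two; `choose()` is exact in
doubles at these sizes); tests assert agreement with `pbinom()` to
1e−12. Tied lineages (possible only with degenerate inputs; continuous
niche summaries never tie) are removed from `n` and reported.

## Kendall correlation

`kendall_tau()` computes tie-corrected tau-b. For `n <= 9` without ties
the two-tailed p-value is exact, from the Mahonian (inversion-count)
null distribution of the concordant-minus-discordant statistic — an
O(n³) recursion, no permutation enumeration. Longer or tied series use
the normal approximation with continuity correction and the standard
tie-corrected variance. `stats::cor.test()` serves as an independent
cross-check in the test suite, never as the implementation.

## Extraction conventions

Grids are regular lat/lon with square cells; no reprojection and no
interpolation. A cell owns `[west, west + size)` in longitude and
`(south, south + size]` in latitude, rows north to south, so every point
belongs to at most one cell and shared edges resolve deterministically
(east/south cell wins). Off-extent or nodata lookups yield `NA`, which
propagates as a per-record missing flag; PCA drops incomplete rows
listwise; medians skip missing values per variable.

Quarters are any three consecutive months with December–January
wrap-around; the wettest quarter maximizes the precipitation sum, with
ties broken toward the earliest calendar start month. The seasonality
index is an absolute-deviation index rescaled by `11/6` so that its two
published anchor points hold exactly: 0 for equal rain in all months, 100
for all rain in one month. The exact formula behind the original
seasonality dataset is not published alongside its endpoints, so this
endpoint-matched index is a stand-in; the same applies to the fire return
interval, which the package accepts only as a pass-through raster layer.

## QC filter order and rounding

Filters run in the order: coordinate validation → land mask → institution
proximity → deduplication. Proximity and land tests intentionally use the
original (pre-rounding) coordinates; retained records leave the pipeline
with their rounded (2-decimal) coordinates, which makes a second pass a
no-op. "Close to GBIF headquarters" is undefined in the source; the
default is a 50 km great-circle radius around (55.6761° N, 12.5683° E) —
wide enough to cover metropolitan geocoding defaults, narrow enough not
to reach other Danish land — and is configurable. Rounding is half away
from zero (deterministic across platforms, matches spreadsheet practice),
with a 1e−9 nudge absorbing binary representation error of decimal
inputs. Duplicate classes keep their first record in input order.

## Ordination

PCA is fitted on standardized columns (correlation matrix) of the pooled
occurrences of all types — the shared axes onto which all three types are
projected. Listwise deletion handles missing values; axis signs are fixed
by making each loading vector's largest-magnitude entry positive;
zero-variance columns raise an error naming the column. PC1 (and PC2)
scores are appended to the matrix as derived variables so aggregation
treats them identically to measured ones.

## The synthetic world

`make_world()` builds the stated world the tests assume: a global
2.5° grid; MAT falling from 28 °C at the equator by 0.45 °C per degree of
latitude plus spatially smoothed noise (sd 2 °C, box-blur radius 3
cells); seasonal amplitude growing to 15 °C at the poles with July/January
peaks by hemisphere; monthly minima 6 °C below monthly means; annual
precipitation of 200 mm baseline plus a 2300 mm equatorial belt
(e-folding width 20° latitude) and smoothed noise (sd 200 mm), split into
months with a poleward-growing concentration; soil surfaces spanning the
published topsoil ranges (OC 0.05–40 % weight, TEB 0.1–80 and CEC
0.5–90 cmol/kg, pH 3–10); ~30 % ocean from a thresholded smooth field.
The 3×3 cells around the institution center are forced to land so that
planted proximity errors are dropped for the proximity reason.

`simulate_lineages()` mirrors the structure the analysis assumes: lineage
base niches, species optima `b + δ_type + N(0, σ_S)`, conservatism
`ρ = σ_L²/(σ_L² + σ_S²)`. The default comparison set mirrors the real
one — 19 lineages with a C3 sister, 5 lacking close C4 relatives, one
extra C4-only lineage — so the three comparisons count 19, 14 and 15
lineages. In **world mode** niches are anchored to actual land-cell
environments: variables covary across the globe (hot usually means wet
in the tropics belt), so independently drawn per-variable optima need
not co-occur anywhere. A lineage base is the environment of a uniformly
drawn land cell and each species optimum the environment of a cell drawn
with Gaussian weight `σ_S` around base + δ. An earlier design that
projected abstract optima to the *nearest* realizable environment was
rejected: nearest-point projection systematically selects locally extreme
environments (hull points of the environmental cloud), which biases
median recovery; drawing a *typical* nearby cell does not.

`simulate_occurrences()` samples land cells per species with probability
proportional to the separable Gaussian suitability
`exp(−½ Σ_v ((e_v − o_v)/τ_v)²)` and jitters each record uniformly within
its cell. The Gaussian kernel is the simplest choice whose optimum equals
the niche parameter, which is what makes median recovery a meaningful
test. Clean records are guaranteed clean — jitter is resampled until the
2-decimal key is unique within the taxon, the point is more than
radius + 2 km from the institution center and not exactly (0, 0) — so the
QC acceptance check can demand zero false drops. Errors are then injected
at configured per-record rates (binomial counts, logged one-to-one in the
ground truth): exact duplicates of clean records, water-cell points,
points inside the institution radius, invalid coordinates.

Determinism: stage `i` of master seed `s` uses seed
`(s · 7919 + i) mod 2147483629` (world 1, lineages 2, occurrences 3,
errors 4), so stages are independently reproducible.

### What a green test does and does not establish

The generator emulates the statistical structure the inference assumes —
exchangeable lineages, additive type shifts, suitability-driven sampling,
independent record errors. It does not emulate spatial sampling bias
(GBIF's Europe-heavy coverage), taxonomic misidentification, spatial
autocorrelation of occurrences beyond the environment, dispersal
limitation, or intraspecific photosynthetic variation. Green calibration
tests therefore establish correctness of the machinery under the stated
model, not robustness of the original biological conclusions to those
real-world complications.

### Calibration experiments (design choices)

- *Null calibration* and *shift detection* run at lineage level (species
  optima stand in for medians): occurrence sampling adds symmetric noise
  to both sides of a contrast and is exercised by its own criteria; this
  keeps 500-replicate runs cheap. The sign test's attainable level at
  `n = 14` is 0.0352, not 0.05 (discreteness plus the asymmetric
  convention), so the null-calibration envelope is computed around the
  attainable level.
- *Shift detection* plants `δ = 2σ_S` on growing-season temperature with
  3 species per type; the per-lineage probability that the focal group
  mean exceeds the reference is then `Φ(2/√(2/3)) ≈ 0.993`, making
  `k ≥ 12` of 14 (the significance region at 0.00625) almost certain.
- *Parameter recovery* uses a 0.625° world so the cell-to-cell
  environmental spacing is well below the kernel widths
  (τ = 0.7 °C / 30 mm): the suitability-weighted environment is then
  densely and near-symmetrically sampled around each optimum, and the
  sampled median converges to it. On coarse grids the median can snap to
  a neighbouring cell's value, and with wide kernels the local
  availability gradient biases it — both observed and documented during
  design, neither a property of the estimator itself.

## Biome classification

`classify_biome()` places (MAT, MAP) points in a Whittaker-style
temperature–precipitation diagram. The polygon boundaries shipped in
`inst/extdata/whittaker_biomes_synthetic.csv` are a simplified,
hand-constructed stand-in (the published digitized boundaries are not
redistributable here); the file name marks it synthetic. Points outside
all polygons take the nearest polygon's label, with MAP scaled by 1/50 so
both axes contribute comparably to the distance. Classification is
descriptive output only; no test statistic consumes it.

## Numerical and format choices

- ESRI ASCII is the raster interchange format (plain text; a GeoTIFF
  reader would need a GIS dependency not available here). Nodata values
  honor the header sentinel.
- Occurrence CSVs are written with 17 significant digits so coordinates
  round-trip bit-exactly.
- Report CSV/JSON are sorted and formatted to 12 significant digits;
  identical configurations produce byte-identical outputs, and each run
  log carries a hash of its configuration.
- Configuration files for the CLI use JSON rather than YAML (no YAML
  parser in the supported dependency set).

## Known limitations

- Frost days, wet days, sunshine and FRI enter only as direct raster
  layers; their upstream definitions are external to this package.
- No occurrence-level spatial thinning or bias correction; the QC stage
  is exactly the four published filters.
- The exact sample sizes behind the published correlation table are not
  recoverable desk-side, and external raster products are not bundled, so
  the published correlation/range values themselves are out of scope;
  every statistic here is validated on synthetic data plus the published
  shift counts.
- Kendall p-values with ties fall back to the normal approximation even
  for short series.
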
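---
title: "Object-based delineation and classification of individual tree crowns"
author: "uavCrowns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Object-based delineation and classification of individual tree crowns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uavCrowns)
```

## The problem

Dry-forest monitoring in northern Peru needs per-tree maps of three species
— Algarrobo (*Prosopis pallida*, the keystone tree, suffering a dieback
plague), Sapote (*Colicodendron scabridum*, a compact evergreen) and the
Overo shrub (*Cordia lutea*) — including whether each Algarrobo is alive or
dead. The inputs are what a small fixed-wing UAV with a filter-modified
consumer camera delivers: a three-band orthomosaic (blue, green, red-edge)
at about 8.3 cm ground resolution, plus a photogrammetric surface model
(DSM) and terrain model (DEM).

At this resolution a crown spans thousands of pixels, so the workflow is
object-based (OBIA) rather than per-pixel: homogeneous segments are built
first, then classified and reshaped by spectral, shape and contextual
rules until one object corresponds to one tree crown.

## The two index grids and the height model

Two normalised band ratios drive every spectral decision:

* **GV** (green vegetation, called GDVI in the parameter tables):
  $(RE - G)/(RE + G)$ — high where chlorophyll pushes the red-edge above
  the green band;
* **NPV** (non-photosynthetic vegetation): $(B - G)/(B + G)$ — high for
  grey, leafless or dead canopies whose blue response exceeds the green.

The canopy height model is $CHM = \max(DSM - DEM, 0)$; negative
differences are photogrammetric noise and are clamped. Both indices are
bounded in $[-1, 1]$ and undefined (nodata) where the denominator is zero.

A note on radiometric units: the mosaic is uncalibrated digital-number
imagery, and the published thresholds (0.053, 0.03, 0.08) implicitly
assume that scale. Because the indices are ratios the pipeline is
unit-agnostic, but every threshold is exposed in `RuleConfig` so users
with calibrated reflectance can re-derive them.

## Level 1: object candidates and vegetation masking

`segmentScene()` runs a multiresolution region-merging segmentation over
the four layers (blue, green, red-edge, CHM; weights 1/1/1/1). The merge
cost of two regions is the increase in weighted heterogeneity: a colour
term $\sum_b w_b (n_m \sigma_{b,m} - n_1 \sigma_{b,1} - n_2 \sigma_{b,2})$
plus a shape term mixing compactness ($\sqrt{n}\,P$) and smoothness
($nP/b$, with $b$ the bounding-box perimeter). Merging proceeds by local
mutual best fitting — a region merges with its cheapest neighbour when the
choice is mutual — and stops when the cheapest admissible merge costs at
least `scale^2`.

The published parameter table leaves scale, shape and compactness blank
(only the layer weights are printed). The defaults here are standard
starting values for this kind of imagery: scale 20, shape 0.1,
compactness 0.5. They are deliberately conservative: over-segmentation of
a crown is repaired one step later, when `maskVegetation()` merges
adjacent vegetation objects of the same kind, while under-segmentation
(crowns fused with soil) cannot be repaired. Nothing downstream depends
on matching any particular proprietary segmenter's geometry.

`maskVegetation()` tags each object (NPV > 0.053 → non-photosynthetic
vegetation; else GV > 0.03 → green vegetation; else background), merges
same-kind neighbours, absorbs background holes fully enclosed by
vegetation, and drops vegetation below the 4 m² minimum mapping unit.
`splitIsolatedVsCluster()` then routes each vegetation object: compact
and small (roundness < 0.9, area < 30,000 px) means an isolated crown;
everything else is a tree cluster for Level 2.

Roundness is not defined in the source parameter table; here it is the
deviation from a circle, $1 - 4\pi A / P^2$, computed on the pixel
footprint with $P$ the staircase (pixel-edge) perimeter. Because the
staircase perimeter of a convex footprint is $2(w+h) \approx 8r$, an
ideal rasterised disc scores about $1 - \pi^2/16 \approx 0.38$, a lobed
star crown 0.7–0.85, and chained multi-crown blobs approach 1; smaller is
rounder, consistent with "Roundness < 0.9" selecting single crowns.

A consequence worth stating plainly: under these two printed thresholds a
*tangent pair* of compact crowns (pixel roundness ≈ 0.7, area well below
30,000 px) is indistinguishable from one large single crown, and is
routed "isolated" — an irreducible under-detection mode of the published
rule set, consistent with the under-detection its field validation
reports. The synthetic generator therefore forms clusters as chains of
three or more crowns, which do exceed the thresholds.

## Level 2: de-clustering

Clusters are resolved seed-first. For green vegetation the seeds are CHM
local maxima (treetops), searched with a square window of half-width 50
px; for non-photosynthetic vegetation the CHM is unreliable — sparse
photogrammetric point clouds over leafless canopies — so seeds are NPV
local maxima with half-width 20 px. The parameter table's "Feature"
column for the two seed operations is transposed relative to the
narrative; the narrative (NPV maxima for deciduous, CHM maxima for green)
is followed. "Search range" is interpreted as the window half-width in
pixels, the window geometry being unstated in the source.

Two numerical choices make seeding robust and well-posed:

* the guidance raster is smoothed by a mask-aware box mean
  (`seedSmoothRadiusPx`, default 9 px ≈ 0.75 m) before the maximum scan —
  standard treetop-detection practice; without it, per-pixel noise
  spawns spurious window maxima on the flat NPV shoulders of large dead
  crowns (the NPV gradient there is ~0.001/px while raw NPV noise is an
  order of magnitude larger; smoothing reverses that ratio). Radius 0
  disables it, and the window-maximum semantics are unchanged;
* a pixel is a seed iff it is the maximum of its window intersected with
  the cluster, with exact ties resolved to the lexicographically first
  (row, col) pixel — so a perfectly flat plateau yields exactly one seed.

`growCrowns()` then assigns every cluster pixel by best-first region
growing: repeatedly, the unassigned pixel 4-adjacent to a region whose
guiding value (NPV or CHM) differs least from that region's *seed* value
is assigned, with deterministic (difference, row, col, region)
tie-breaking. The source does not state which criterion its grow-region
step used; guiding by distance-to-seed-value is this package's
concretisation, chosen because it needs no extra parameters and
reduces to an exact flood fill on plateau clusters. The result always
partitions the cluster; regions below the minimum mapping unit are
absorbed into the neighbour with the longest shared border.

Contextual refinement (`refineCrowns()`) repairs infested Algarrobo split
into a dead part and a live part: a crown sharing more than
`relBorderMergeMin` (default 0.5; the source cites "relative border to"
without a value) of its border with a single neighbour of the *other*
vegetation kind is merged into that neighbour, one pass, largest relative
border first.

## Classification

Crowns are classified by thresholds on object features:

| class | rule |
|---|---|
| Sapote | green vegetation, mean GV ≥ 0.08 |
| alive Algarrobo | green vegetation, mean GV < 0.08 |
| dead Algarrobo | NPV vegetation, area ≥ 10,000 px and CHM > 0.4 m |
| Overo | NPV vegetation, area < 10,000 px and CHM < 0.4 m |

The published table prints no CHM statistic; the maximum is used (the
treetop; configurable to the mean via `chmStatistic`), and the "≥"
readings at the 0.08 and 10,000 boundaries follow from the paired
alive-Algarrobo rule printing "< 0.08". NPV crowns in the two unprinted
quadrants (small-and-tall, large-and-flat) are resolved by the CHM test
alone — height is what biologically separates a tree from a bush — with a
warning. Overo is mapped but never counted as a tree. The area thresholds
are stored in pixels, as printed, and assume the 8.3 cm grid.

## Accuracy assessment and landscape metrics

The assessment mirrors the field campaign: plot-level, non-site-specific
detection rates (classified/reference counts per class, no tree-to-tree
matching; `detectionRates()`), a four-class error matrix with producer's,
user's and overall accuracy (`buildErrorMatrix()`, `matrixStats()`), and
detection-rate-adjusted abundances (`adjustCounts()`, rounding half-up).
Reference counts apply the field filters: crowns above 4 m² only,
Algarrobo health grades 1–2 alive and 3 dead (`groundTruthReference()`).

For synthetic scenes an error matrix needs labels in correspondence, so
`matchCrownsToTruth()` pairs each crown with the truth tree of maximum
footprint overlap (ties to the nearest centroid). That matching rule is
this package's own; the published assessment needed none.

One published figure is *not* reproducible from the stated rule: the
adjusted alive-Algarrobo count (printed 1122, but raw/rate gives 1151).
`reproduceTables()` prints the stated rule's answer and flags the row
"rule ambiguous" rather than silently matching the printed value. All
densities and percentages do reproduce when the printed adjusted counts
are taken as the input, which is what `densitySummary()` consumes.

`makeFishnet()`/`summarizeCells()` summarise the classified map on 50 m ×
50 m cells anchored at the extent's lower-left corner (the source does
not state the fishnet origin; it is configurable): centroid-in-cell
counts (half-open cells, left/bottom inclusive), zonal crown cover by
pixel-centre assignment (which conserves total crown area exactly), and
per-cell mortality, undefined — not zero — where a cell has no Algarrobo.

## The synthetic scene generator

`generateScene()` renders what the classifier assumes, not Peruvian
radiometry: no per-species reflectance statistics are published, so the
default profiles are chosen to satisfy the threshold orderings with
comfortable margins (Sapote GV ≈ 0.11, alive Algarrobo ≈ 0.056, dead
Algarrobo NPV ≈ 0.08–0.19, background GV 0, NPV −0.09), on a dark
bare-soil background with additive Gaussian band noise (sd 0.01).

Geometry follows the species descriptions: alive and dead Algarrobo are
k-lobed stars (k ∈ 5..8, boundary radius $R(0.7 + 0.3\cos k\theta)$),
Sapote are ellipses, Overo are chains of lobes along sinuous runnel
curves (the shrub's habitat), below 0.4 m. Dead Algarrobo are rendered
large (radius 7–9 m, a mature crown) so their footprints clear the
10,000-px rule. Every crown carries a cosine canopy dome peaking at its
centre — a unique CHM maximum per green tree, so CHM seeding is
well-posed — and NPV crowns carry a radially decaying blue boost, the
NPV analogue of the treetop. The DSM is the terrain plane plus the
tallest dome plus noise (sd 0.02 m, a smoothed photogrammetric surface);
an optional `sparseCloudFrac` knocks dead-crown DSM pixels down to the
terrain, emulating point-cloud dropout over leafless canopies (off by
default).

Clusters are tangent chains (members at 0.7 of the summed radii) whose
members are placed so that each apex clears every sibling's seed window
(Chebyshev metric) and tops every sibling dome reaching into its own
window — the well-posedness that "distinct apices separated by more than
the search range" presumes. Defaults: one alive chain of 4 and one dead
chain of 3 inside a 140 m × 120 m scene of 42 trees plus 6 Overo patches
(16 Sapote / 14 alive / 12 dead — about 25 trees/ha, matching an open
dry-forest stand), all placement rejection-sampled with a minimum 1.5 m
crown gap and a hard attempt budget.

What the generator deliberately does **not** emulate: radiative-transfer
realism, mixed-pixel anti-aliasing at crown edges, understorey
vegetation growing beneath canopies, co-registration error between
mosaic and elevation grids, and radiometric vignetting. Passing the
synthetic tests therefore demonstrates the *algorithmic* correctness of
segmentation, routing, seeding, growing and rule application under
controlled contrast — not field performance on real UAV imagery, where
edge mixing and calibration dominate the error budget. One realistic
failure mode does appear: thin, low (≈0.25 m) Overo patches contrast
weakly with soil in all four layers and are occasionally absorbed into
background by the segmentation — an omission affecting only the
unquantified shrub class.

## Problem sizes and determinism

The default synthetic scene is 1687 × 1446 px (≈2.4 M pixels); a full
pipeline run takes roughly 10–15 s on one core, and the package's
property checks run the noise-free scene once plus ten noisy seeds. All
randomness flows from a single seed (`rngSeed`), restored after use, so
scenes are bit-identical across runs; segmentation, seeding and growing
are deterministic by fixed scan order and explicit tie-breaks, so whole
pipeline runs are reproducible file-for-file.

## A small worked example

```{r example, eval = FALSE}
spec <- sceneSpec(rngSeed = 1)
sim <- generateScene(spec)
crownSet <- delineateCrowns(sim$scene, sim$heights)
classified <- classifyAll(crownSet)
assessScene(classified, sim$truth)$detection
```

## Known limitations

* Tangent *pairs* of compact crowns cannot be routed to de-clustering by
  the published shape/extent thresholds (see Level 1) and are counted as
  one tree.
* The pixel-based area thresholds (10,000 / 30,000 px) are tied to the
  8.3 cm grid; other resolutions require overriding them.
* Thresholds assume uncalibrated DN ratios; calibrated reflectance may
  shift the NPV threshold in particular.
* The GeoTIFF writer stores 32-bit rescaled samples with a sidecar and
  world file; heavyweight GIS metadata (projection WKT, overviews) is out
  of scope, and `.asc` is provided for exact-precision exchange.
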
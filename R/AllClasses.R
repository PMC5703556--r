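## Central S4 containers. Grid convention throughout the package:
## matrices are (row, col) with row 1 the northernmost line; the transform is
## c(origin_x, origin_y, pixel_size) with the origin at the lower-left corner
## of the grid and map coordinates taken at pixel centres. Internal nodata is
## NA; file-level sentinels are translated on read/write.

#' Three-band scene raster
#'
#' Holds the blue, green and red-edge bands of an orthomosaic on a common
#' grid. Values are reflectance-like (unitless, non-negative); invalid
#' pixels are \code{NA}.
#'
#' @slot blue,green,rededge Numeric matrices of identical shape.
#' @slot transform Numeric \code{c(origin_x, origin_y, pixel_size)} in map
#'   units (m); origin at the lower-left corner, coordinates at pixel centres.
#' @slot crsTag Free-text CRS identifier (e.g. \code{"EPSG:32717"}).
#' @slot nodata Sentinel used when writing to file; never a valid value.
#' @exportClass SceneRaster
setClass("SceneRaster",
  representation(blue = "matrix", green = "matrix", rededge = "matrix",
                 transform = "numeric", crsTag = "character",
                 nodata = "numeric"),
  prototype(crsTag = "local", nodata = -9999))

setValidity("SceneRaster", function(object) {
  msg <- character()
  d <- dim(object@blue)
  if (!identical(d, dim(object@green)) || !identical(d, dim(object@rededge)))
    msg <- c(msg, "all three bands must have identical shape")
  if (length(object@transform) != 3L)
    msg <- c(msg, "transform must be c(origin_x, origin_y, pixel_size)")
  else if (!is.finite(object@transform[3L]) || object@transform[3L] <= 0)
    msg <- c(msg, "pixel_size must be > 0")
  for (b in c("blue", "green", "rededge")) {
    v <- slot(object, b)
    if (any(v < 0, na.rm = TRUE))
      msg <- c(msg, sprintf("band '%s' contains negative values", b))
    if (any(v == object@nodata, na.rm = TRUE))
      msg <- c(msg, sprintf("band '%s' contains the nodata sentinel", b))
  }
  if (length(msg)) msg else TRUE
})

#' Elevation grids (DEM, DSM, CHM)
#'
#' Terrain (DEM), surface (DSM) and canopy height (CHM) grids in metres,
#' aligned to a \linkS4class{SceneRaster}. The CHM slot may be entirely
#' \code{NA} until filled by \code{\link{computeCHM}}.
#'
#' @slot dem,dsm,chm Numeric matrices of identical shape (m).
#' @slot transform As for \linkS4class{SceneRaster}.
#' @exportClass HeightGrids
setClass("HeightGrids",
  representation(dem = "matrix", dsm = "matrix", chm = "matrix",
                 transform = "numeric"))

setValidity("HeightGrids", function(object) {
  msg <- character()
  d <- dim(object@dem)
  if (!identical(d, dim(object@dsm)) || !identical(d, dim(object@chm)))
    msg <- c(msg, "dem, dsm and chm must have identical shape")
  if (length(object@transform) != 3L || object@transform[3L] <= 0)
    msg <- c(msg, "transform must be c(origin_x, origin_y, pixel_size > 0)")
  if (any(object@chm < 0, na.rm = TRUE))
    msg <- c(msg, "chm must be >= 0 wherever valid")
  if (length(msg)) msg else TRUE
})

#' Band-ratio index grid
#'
#' A normalised-difference index in \eqn{[-1, 1]}: either GV (green
#' vegetation, also called GDVI), \eqn{(RE - G)/(RE + G)}, or NPV
#' (non-photosynthetic vegetation), \eqn{(B - G)/(B + G)}. Degenerate pixels
#' (zero denominator, or nodata input) are \code{NA}.
#'
#' @slot values Numeric matrix in \eqn{[-1, 1]} (NA = nodata).
#' @slot kind \code{"GV"} or \code{"NPV"}.
#' @slot transform As for \linkS4class{SceneRaster}.
#' @exportClass IndexGrid
setClass("IndexGrid",
  representation(values = "matrix", kind = "character",
                 transform = "numeric"))

setValidity("IndexGrid", function(object) {
  msg <- character()
  if (!object@kind %in% c("GV", "NPV"))
    msg <- c(msg, "kind must be 'GV' or 'NPV'")
  if (any(abs(object@values) > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "index values must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Rule-set configuration
#'
#' Every threshold and parameter of the crown delineation and classification
#' rule set, in one validated object. Defaults are the published processing
#' parameters of the case study; see \code{\link{ruleConfig}}.
#'
#' @slot npvThreshold NPV above which an object is non-photosynthetic
#'   vegetation (default 0.053).
#' @slot gdviThreshold GV/GDVI above which an object is green vegetation
#'   (default 0.03).
#' @slot sapoteGdviMin GV at or above which a green crown is Sapote
#'   (default 0.08).
#' @slot roundnessMax Roundness (deviation from circle, 0 = perfect circle)
#'   below which a vegetation object can be an isolated crown (default 0.9).
#' @slot clusterAreaMaxPx Pixel area below which a vegetation object can be
#'   an isolated crown (default 30000).
#' @slot deadAreaMinPx Pixel area at or above which an NPV crown is a dead
#'   Algarrobo rather than an Overo bush (default 10000).
#' @slot chmBushMaxM Canopy height (m) separating trees from bushes
#'   (default 0.4).
#' @slot mmuM2 Minimum mapping unit in m2 (default 4).
#' @slot seedRangeNpvPx,seedRangeGvPx Local-maximum search half-widths in
#'   pixels for NPV and green (CHM) seeding (defaults 20 and 50).
#' @slot segScale,segShape,segCompactness Multiresolution segmentation scale,
#'   shape weight and compactness weight (defaults 20, 0.1, 0.5).
#' @slot layerWeights Segmentation layer weights for blue, green, red-edge,
#'   CHM (default 1, 1, 1, 1).
#' @slot relBorderMergeMin Relative border above which a crown is merged into
#'   a differently-kinded neighbour during contextual refinement (default 0.5).
#' @slot chmStatistic Object CHM statistic used by the tree/bush rule,
#'   \code{"max"} or \code{"mean"} (default \code{"max"}).
#' @slot seedSmoothRadiusPx Half-width of the mask-aware box mean applied to
#'   the guidance raster before local-maximum seeding; 0 disables (default 9).
#' @exportClass RuleConfig
setClass("RuleConfig",
  representation(npvThreshold = "numeric", gdviThreshold = "numeric",
                 sapoteGdviMin = "numeric", roundnessMax = "numeric",
                 clusterAreaMaxPx = "numeric", deadAreaMinPx = "numeric",
                 chmBushMaxM = "numeric", mmuM2 = "numeric",
                 seedRangeNpvPx = "integer", seedRangeGvPx = "integer",
                 segScale = "numeric", segShape = "numeric",
                 segCompactness = "numeric", layerWeights = "numeric",
                 relBorderMergeMin = "numeric", chmStatistic = "character",
                 seedSmoothRadiusPx = "integer"),
  prototype(npvThreshold = 0.053, gdviThreshold = 0.03, sapoteGdviMin = 0.08,
            roundnessMax = 0.9, clusterAreaMaxPx = 30000,
            deadAreaMinPx = 10000, chmBushMaxM = 0.4, mmuM2 = 4.0,
            seedRangeNpvPx = 20L, seedRangeGvPx = 50L,
            segScale = 20, segShape = 0.1, segCompactness = 0.5,
            layerWeights = c(blue = 1, green = 1, rededge = 1, chm = 1),
            relBorderMergeMin = 0.5, chmStatistic = "max",
            seedSmoothRadiusPx = 9L))

setValidity("RuleConfig", function(object) {
  msg <- character()
  num <- c("npvThreshold", "gdviThreshold", "sapoteGdviMin", "roundnessMax",
           "clusterAreaMaxPx", "deadAreaMinPx", "chmBushMaxM", "mmuM2",
           "segScale", "segShape", "segCompactness", "relBorderMergeMin")
  for (s in num)
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  for (s in c("clusterAreaMaxPx", "deadAreaMinPx", "mmuM2", "segScale"))
    if (length(slot(object, s)) == 1L && is.finite(slot(object, s)) &&
        slot(object, s) <= 0)
      msg <- c(msg, sprintf("'%s' must be > 0", s))
  if (length(object@layerWeights) != 4L || any(object@layerWeights < 0) ||
      all(object@layerWeights == 0))
    msg <- c(msg, "layerWeights must be 4 non-negative values, not all zero")
  if (object@segShape < 0 || object@segShape >= 1)
    msg <- c(msg, "segShape must lie in [0, 1)")
  if (object@segCompactness < 0 || object@segCompactness > 1)
    msg <- c(msg, "segCompactness must lie in [0, 1]")
  if (any(c(object@seedRangeNpvPx, object@seedRangeGvPx) < 1L))
    msg <- c(msg, "seed search ranges must be >= 1 pixel")
  if (object@seedSmoothRadiusPx < 0L)
    msg <- c(msg, "seedSmoothRadiusPx must be >= 0")
  if (!object@chmStatistic %in% c("max", "mean"))
    msg <- c(msg, "chmStatistic must be 'max' or 'mean'")
  if (length(msg)) msg else TRUE
})

#' Segmentation result
#'
#' An integer label partition of the valid pixels plus a per-object feature
#' table and a symmetric shared-border table.
#'
#' @slot labels Integer matrix; 0 = nodata, labels 1..K partition the valid
#'   pixels into 4-connected objects.
#' @slot table One row per object: areas, per-band mean/sd, index and CHM
#'   statistics, perimeter, roundness, bounding box, centroid and class tag.
#' @slot borders Data frame \code{a, b, edges} (a < b) of shared border
#'   lengths in pixel edges.
#' @slot transform As for \linkS4class{SceneRaster}.
#' @exportClass SegmentMap
setClass("SegmentMap",
  representation(labels = "matrix", table = "data.frame",
                 borders = "data.frame", transform = "numeric"))

#' Delineated crowns
#'
#' One object per delineated tree crown: a label grid of disjoint pixel
#' footprints plus the per-crown feature table (including the vegetation
#' kind, provenance and, after classification, the class label).
#'
#' @slot labels Integer matrix; 0 = no crown, values are crown ids.
#' @slot table One row per crown; columns as \linkS4class{SegmentMap} plus
#'   \code{vegetation_kind} (\code{green}/\code{npv}), \code{provenance}
#'   (\code{isolated}/\code{declustered}) and \code{class}.
#' @slot borders Shared-border table between adjacent crowns (as in
#'   \linkS4class{SegmentMap}), used by contextual refinement.
#' @slot transform As for \linkS4class{SceneRaster}.
#' @exportClass CrownSet
setClass("CrownSet",
  representation(labels = "matrix", table = "data.frame",
                 borders = "data.frame", transform = "numeric"),
  prototype(borders = data.frame(a = integer(), b = integer(),
                                 edges = integer())))

#' Classified crown map
#'
#' The result of running the four-class rule set over a
#' \linkS4class{CrownSet}: labelled crowns, per-class counts and crown-area
#' totals. The tree count excludes Overo, which is mapped but not counted
#' as a tree.
#'
#' @slot crowns \linkS4class{CrownSet} with the \code{class} column filled.
#' @slot counts Named integer vector over the four classes.
#' @slot areaTotals Named numeric vector of per-class crown area (m2).
#' @slot treeCount Number of crowns counted as trees (Overo excluded).
#' @exportClass ClassifiedMap
setClass("ClassifiedMap",
  representation(crowns = "CrownSet", counts = "integer",
                 areaTotals = "numeric", treeCount = "integer"))

setValidity("ClassifiedMap", function(object) {
  if (sum(object@counts) != nrow(object@crowns@table))
    return("class counts must sum to the number of crowns")
  TRUE
})

#' Synthetic ground truth
#'
#' Reference data rendered alongside a synthetic scene: the tree/patch
#' table, the per-tree crown mask grid and the survey plot rectangles.
#'
#' @slot trees Data frame with \code{id, species, health_grade,
#'   crown_spread_m2, x, y, plot_id, cluster}; \code{health_grade} is 1-3
#'   for Algarrobo (1 healthy, 2 infected, 3 dead) and NA otherwise.
#' @slot masks Integer matrix: 0 = background, otherwise the owning tree id
#'   (masks are disjoint; overlap within a cluster is resolved to the taller
#'   canopy).
#' @slot plots Data frame \code{plot_id, xmin, ymin, xmax, ymax} (map m).
#' @slot transform As for \linkS4class{SceneRaster}.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(trees = "data.frame", masks = "matrix",
                 plots = "data.frame", transform = "numeric"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  tr <- object@trees
  if (nrow(tr)) {
    if (!all(tr$species %in% c("sapote", "algarrobo", "overo", "other")))
      msg <- c(msg, "unknown species in truth table")
    alg <- tr$species == "algarrobo"
    if (any(is.na(tr$health_grade[alg])) ||
        any(!is.na(tr$health_grade[!alg])))
      msg <- c(msg, "health_grade must be present iff species is algarrobo")
    if (any(!tr$health_grade[alg] %in% 1:3))
      msg <- c(msg, "health_grade must be 1, 2 or 3")
    if (any(tr$crown_spread_m2 <= 0))
      msg <- c(msg, "crown_spread_m2 must be > 0")
    if (!all(tr$id %in% unique(as.vector(object@masks))))
      msg <- c(msg, "every truth tree must have a rendered mask")
  }
  if (length(msg)) msg else TRUE
})

## ---- show methods ---------------------------------------------------------

setMethod("show", "SceneRaster", function(object) {
  d <- dim(object@blue)
  cat(sprintf("SceneRaster: %d x %d px, pixel %.4g m, origin (%.6g, %.6g), CRS '%s'\n",
              d[1L], d[2L], object@transform[3L], object@transform[1L],
              object@transform[2L], object@crsTag))
  cat(sprintf("  bands: blue/green/red-edge, %d nodata px\n",
              sum(is.na(object@blue) | is.na(object@green) | is.na(object@rededge))))
})

setMethod("show", "HeightGrids", function(object) {
  d <- dim(object@dem)
  chm <- if (all(is.na(object@chm))) "unset" else
    sprintf("range %.2f-%.2f m", min(object@chm, na.rm = TRUE),
            max(object@chm, na.rm = TRUE))
  cat(sprintf("HeightGrids: %d x %d px, pixel %.4g m, CHM %s\n",
              d[1L], d[2L], object@transform[3L], chm))
})

setMethod("show", "IndexGrid", function(object) {
  rng <- suppressWarnings(range(object@values, na.rm = TRUE))
  cat(sprintf("IndexGrid (%s): %d x %d px, range %.3f to %.3f, %d nodata px\n",
              object@kind, nrow(object@values), ncol(object@values),
              rng[1L], rng[2L], sum(is.na(object@values))))
})

setMethod("show", "RuleConfig", function(object) {
  cat("RuleConfig:\n")
  for (s in slotNames(object))
    cat(sprintf("  %-20s %s\n", s, paste(format(slot(object, s)), collapse = " ")))
})

setMethod("show", "SegmentMap", function(object) {
  cat(sprintf("SegmentMap: %d objects over %d x %d px",
              nrow(object@table), nrow(object@labels), ncol(object@labels)))
  if (nrow(object@table) && "class" %in% names(object@table)) {
    tb <- table(object@table$class)
    cat(" (", paste(sprintf("%s: %d", names(tb), tb), collapse = ", "), ")", sep = "")
  }
  cat("\n")
})

setMethod("show", "CrownSet", function(object) {
  cat(sprintf("CrownSet: %d crowns, total area %.1f m2\n",
              nrow(object@table), sum(object@table$area_m2)))
})

setMethod("show", "ClassifiedMap", function(object) {
  cat(sprintf("ClassifiedMap: %d crowns, %d trees (Overo mapped, not counted)\n",
              nrow(object@crowns@table), object@treeCount))
  print(object@counts)
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d trees/patches, %d plots\n",
              nrow(object@trees), nrow(object@plots)))
})
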
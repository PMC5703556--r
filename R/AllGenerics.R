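#' Accessors for the package's grid containers
#'
#' \code{gridTransform} returns \code{c(origin_x, origin_y, pixel_size)};
#' \code{pixelSize} the pixel edge length in map units; \code{labelGrid} the
#' integer label matrix of a segmentation or crown set; \code{objectTable}
#' the per-object (or per-crown) feature table; \code{sharedBorders} the
#' symmetric shared-border table of a \linkS4class{SegmentMap};
#' \code{indexValues} the value matrix of an \linkS4class{IndexGrid}.
#'
#' @param x A package object.
#' @return See description.
#' @examples
#' cfg <- ruleConfig()
#' sc <- uavCrowns:::.flatScene(8, 8, c(0.1, 0.12, 0.12))
#' pixelSize(sc)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridTransform", function(x) standardGeneric("gridTransform"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("labelGrid", function(x) standardGeneric("labelGrid"))
#' @rdname accessors
#' @export
setGeneric("objectTable", function(x) standardGeneric("objectTable"))
#' @rdname accessors
#' @export
setGeneric("sharedBorders", function(x) standardGeneric("sharedBorders"))
#' @rdname accessors
#' @export
setGeneric("indexValues", function(x) standardGeneric("indexValues"))

#' @rdname accessors
setMethod("gridTransform", "SceneRaster", function(x) x@transform)
#' @rdname accessors
setMethod("gridTransform", "HeightGrids", function(x) x@transform)
#' @rdname accessors
setMethod("gridTransform", "IndexGrid", function(x) x@transform)
#' @rdname accessors
setMethod("gridTransform", "SegmentMap", function(x) x@transform)
#' @rdname accessors
setMethod("gridTransform", "CrownSet", function(x) x@transform)
#' @rdname accessors
setMethod("gridTransform", "GroundTruth", function(x) x@transform)

#' @rdname accessors
setMethod("pixelSize", "SceneRaster", function(x) x@transform[3L])
#' @rdname accessors
setMethod("pixelSize", "HeightGrids", function(x) x@transform[3L])
#' @rdname accessors
setMethod("pixelSize", "IndexGrid", function(x) x@transform[3L])
#' @rdname accessors
setMethod("pixelSize", "SegmentMap", function(x) x@transform[3L])
#' @rdname accessors
setMethod("pixelSize", "CrownSet", function(x) x@transform[3L])

#' @rdname accessors
setMethod("labelGrid", "SegmentMap", function(x) x@labels)
#' @rdname accessors
setMethod("labelGrid", "CrownSet", function(x) x@labels)
#' @rdname accessors
setMethod("labelGrid", "GroundTruth", function(x) x@masks)

#' @rdname accessors
setMethod("objectTable", "SegmentMap", function(x) x@table)
#' @rdname accessors
setMethod("objectTable", "CrownSet", function(x) x@table)
#' @rdname accessors
setMethod("objectTable", "ClassifiedMap", function(x) x@crowns@table)

#' @rdname accessors
setMethod("sharedBorders", "SegmentMap", function(x) x@borders)

#' @rdname accessors
setMethod("indexValues", "IndexGrid", function(x) x@values)

#' Crowns and counts of a classified map
#'
#' @param x A \linkS4class{ClassifiedMap}.
#' @return \code{crowns()} the underlying \linkS4class{CrownSet};
#'   \code{classCounts()} the named per-class crown counts;
#'   \code{treeCount()} the number of crowns counted as trees (Overo is
#'   mapped but not counted).
#' @name classified-accessors
NULL

#' @rdname classified-accessors
#' @export
setGeneric("crowns", function(x) standardGeneric("crowns"))
#' @rdname classified-accessors
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))
#' @rdname classified-accessors
#' @export
setGeneric("treeCount", function(x) standardGeneric("treeCount"))

#' @rdname classified-accessors
setMethod("crowns", "ClassifiedMap", function(x) x@crowns)
#' @rdname classified-accessors
setMethod("classCounts", "ClassifiedMap", function(x) x@counts)
#' @rdname classified-accessors
setMethod("treeCount", "ClassifiedMap", function(x) x@treeCount)

#' Ground-truth accessors
#'
#' @param x A \linkS4class{GroundTruth}.
#' @return \code{truthTrees()} the tree/patch table; \code{truthPlots()} the
#'   plot rectangles.
#' @name truth-accessors
NULL

#' @rdname truth-accessors
#' @export
setGeneric("truthTrees", function(x) standardGeneric("truthTrees"))
#' @rdname truth-accessors
#' @export
setGeneric("truthPlots", function(x) standardGeneric("truthPlots"))

#' @rdname truth-accessors
setMethod("truthTrees", "GroundTruth", function(x) x@trees)
#' @rdname truth-accessors
setMethod("truthPlots", "GroundTruth", function(x) x@plots)
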
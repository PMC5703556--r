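## Band-ratio vegetation indices and the canopy height model.

.ndRatio <- function(a, b) {
  den <- a + b
  out <- (a - b) / den
  out[!is.finite(out) | den == 0] <- NA_real_
  out
}

#' Green-vegetation index (GV / GDVI)
#'
#' Per-pixel \eqn{(RE - G)/(RE + G)}: the normalised difference of the
#' red-edge and green bands, high for photosynthetically active canopies.
#' Pixels with \eqn{RE + G = 0} or any nodata input are nodata.
#'
#' @param scene A \linkS4class{SceneRaster}.
#' @return An \linkS4class{IndexGrid} of kind \code{"GV"}.
#' @examples
#' sc <- uavCrowns:::.flatScene(4, 4, c(0.06, 0.2, 0.6))
#' indexValues(computeGV(sc))[1, 1]  # (0.6 - 0.2)/(0.6 + 0.2) = 0.5
#' @export
computeGV <- function(scene) {
  stopifnot(is(scene, "SceneRaster"))
  new("IndexGrid", values = .ndRatio(scene@rededge, scene@green),
      kind = "GV", transform = scene@transform)
}

#' Non-photosynthetic-vegetation index (NPV)
#'
#' Per-pixel \eqn{(B - G)/(B + G)}: high for grey, leafless or dead
#' canopies whose blue response exceeds the green. Degenerate pixels are
#' nodata.
#'
#' @param scene A \linkS4class{SceneRaster}.
#' @return An \linkS4class{IndexGrid} of kind \code{"NPV"}.
#' @export
computeNPV <- function(scene) {
  stopifnot(is(scene, "SceneRaster"))
  new("IndexGrid", values = .ndRatio(scene@blue, scene@green),
      kind = "NPV", transform = scene@transform)
}

#' Canopy height model
#'
#' Fills the CHM slot with \eqn{\max(DSM - DEM, 0)}; negative differences
#' (photogrammetric noise) are clamped to zero and nodata propagates.
#' Idempotent: the CHM is always recomputed from DEM and DSM.
#'
#' @param heights A \linkS4class{HeightGrids}.
#' @return The \linkS4class{HeightGrids} with \code{chm} filled.
#' @export
computeCHM <- function(heights) {
  stopifnot(is(heights, "HeightGrids"))
  if (!identical(dim(heights@dem), dim(heights@dsm)))
    stop("dem and dsm shapes differ")
  heights@chm <- pmax(heights@dsm - heights@dem, 0)
  validObject(heights)
  heights
}
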
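## Fishnet landscape metrics: per-cell counts, crown cover and Algarrobo
## mortality, plus whole-area densities.

#' Build a fishnet grid
#'
#' Axis-aligned square cells anchored at the extent's lower-left corner;
#' partial edge cells are included and flagged.
#'
#' @param extent \code{c(width, height)} in map units.
#' @param cellSizeM Cell edge (m), default 50.
#' @param origin Lower-left corner of the grid, default \code{c(0, 0)}.
#' @return Data frame \code{cell_id, xmin, ymin, xmax, ymax, partial}.
#' @examples
#' nrow(makeFishnet(c(100, 100)))  # 4 cells
#' @export
makeFishnet <- function(extent, cellSizeM = 50, origin = c(0, 0)) {
  if (any(extent <= 0)) stop("extent must be positive")
  nx <- ceiling(extent[1L] / cellSizeM - 1e-9)
  ny <- ceiling(extent[2L] / cellSizeM - 1e-9)
  g <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  out <- data.frame(cell_id = seq_len(nrow(g)),
                    xmin = origin[1L] + g$ix * cellSizeM,
                    ymin = origin[2L] + g$iy * cellSizeM)
  out$xmax <- pmin(out$xmin + cellSizeM, origin[1L] + extent[1L])
  out$ymax <- pmin(out$ymin + cellSizeM, origin[2L] + extent[2L])
  out$partial <- (out$xmax - out$xmin < cellSizeM - 1e-9) |
    (out$ymax - out$ymin < cellSizeM - 1e-9)
  out
}

#' Summarise crowns per fishnet cell
#'
#' Counts crowns by centroid-in-cell (half-open cells: left/bottom edges
#' inclusive), computes zonal crown cover by clipping crown footprints to
#' the cells (pixel-centre assignment, so cover is conserved exactly), and
#' the per-cell Algarrobo mortality, which is undefined (\code{NA}) where a
#' cell holds no Algarrobo.
#'
#' @param classified A \linkS4class{ClassifiedMap}.
#' @param cells A fishnet from \code{\link{makeFishnet}}.
#' @return The cells data frame extended with per-class counts,
#'   \code{total_trees}, \code{crown_cover_m2} and \code{pct_dead}.
#' @export
summarizeCells <- function(classified, cells) {
  cs <- classified@crowns
  tb <- cs@table
  out <- cells
  for (k in .classLevels) out[[k]] <- 0L
  out$total_trees <- 0L
  out$crown_cover_m2 <- 0
  if (nrow(tb)) {
    hit <- function(x, y)
      which(x >= cells$xmin & x < cells$xmax &
              y >= cells$ymin & y < cells$ymax)[1L]
    cellOf <- mapply(hit, tb$centroid_x, tb$centroid_y)
    for (i in seq_len(nrow(tb))) {
      ci <- cellOf[i]
      if (is.na(ci)) next
      k <- tb$class[i]
      out[[k]][ci] <- out[[k]][ci] + 1L
      if (k != "overo") out$total_trees[ci] <- out$total_trees[ci] + 1L
    }
    # zonal crown cover from the label grid (pixel-centre assignment)
    lab <- cs@labels
    idx <- which(lab > 0L)
    if (length(idx)) {
      nr <- nrow(lab)
      tf <- cs@transform
      px <- .mapX(((idx - 1L) %/% nr) + 1L, tf)
      py <- .mapY(((idx - 1L) %% nr) + 1L, tf, nr)
      cs0 <- max(cells$xmax - cells$xmin)
      ox <- min(cells$xmin); oy <- min(cells$ymin)
      gx <- round((cells$xmin - ox) / cs0)
      gy <- round((cells$ymin - oy) / cs0)
      ci <- match(paste(floor((px - ox) / cs0), floor((py - oy) / cs0)),
                  paste(gx, gy))
      tal <- table(ci)
      out$crown_cover_m2[as.integer(names(tal))] <-
        as.numeric(tal) * tf[3L]^2
    }
  }
  alg <- out$algarrobo_alive + out$algarrobo_dead
  out$pct_dead <- ifelse(alg > 0, 100 * out$algarrobo_dead / alg, NA_real_)
  out
}

#' Whole-area density and composition summary
#'
#' Per-class densities from (adjusted) counts, species shares and the
#' Algarrobo mortality rate. Overo is excluded: only trees are quantified.
#'
#' @param counts Named numeric vector over \code{sapote},
#'   \code{algarrobo_alive}, \code{algarrobo_dead} (typically
#'   detection-rate-adjusted).
#' @param areaHa Survey area (ha).
#' @return List with \code{perClass} (counts and trees/ha),
#'   \code{total_trees}, \code{total_per_ha}, \code{algarrobo_per_ha},
#'   \code{pct_sapote}, \code{pct_algarrobo} and \code{pct_dead} (dead /
#'   all Algarrobo).
#' @examples
#' densitySummary(c(sapote = 784, algarrobo_alive = 1122,
#'                  algarrobo_dead = 601), areaHa = 80)
#' @export
densitySummary <- function(counts, areaHa) {
  if (areaHa <= 0) stop("areaHa must be > 0")
  cls <- .rateClasses
  if (!all(cls %in% names(counts)))
    stop("counts must name all three tree classes")
  n <- as.numeric(counts[cls])
  total <- sum(n)
  alg <- n[2L] + n[3L]
  list(perClass = data.frame(class = cls, count = n, per_ha = n / areaHa),
       total_trees = total,
       total_per_ha = total / areaHa,
       algarrobo_per_ha = alg / areaHa,
       pct_sapote = 100 * n[1L] / total,
       pct_algarrobo = 100 * alg / total,
       pct_dead = if (alg > 0) 100 * n[3L] / alg else NA_real_)
}

#' Write fishnet cells with attributes to GeoJSON
#'
#' @param cells A data frame from \code{\link{summarizeCells}} (or
#'   \code{\link{makeFishnet}}).
#' @param path Output path (\code{.geojson}/\code{.json}).
#' @return \code{path}, invisibly.
#' @export
writeFishnet <- function(cells, path) {
  feats <- lapply(seq_len(nrow(cells)), function(i) {
    r <- cells[i, ]
    ring <- list(c(r$xmin, r$ymin), c(r$xmax, r$ymin), c(r$xmax, r$ymax),
                 c(r$xmin, r$ymax), c(r$xmin, r$ymin))
    props <- as.list(r[setdiff(names(r), c("xmin", "ymin", "xmax", "ymax"))])
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
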
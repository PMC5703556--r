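## Level-1 object candidates: multiresolution region-merging segmentation
## and the per-object feature machinery every later rule consumes.

.featureCols <- c("label", "area_px", "area_m2", "mean_blue", "mean_green",
                  "mean_rededge", "sd_blue", "sd_green", "sd_rededge",
                  "mean_gv", "mean_npv", "mean_chm", "max_chm", "sd_chm",
                  "perimeter_px", "roundness", "rmin", "rmax", "cmin",
                  "cmax", "centroid_x", "centroid_y", "class")

#' Multiresolution segmentation
#'
#' Bottom-up pairwise region merging over the weighted blue/green/red-edge/
#' CHM layer stack, minimising the increase in colour + shape heterogeneity
#' (the classic multiresolution criterion: the colour term is
#' \eqn{\sum_b w_b (n_m \sigma_{b,m} - n_1 \sigma_{b,1} - n_2 \sigma_{b,2})};
#' the shape term mixes compactness \eqn{\sqrt{n} P} and smoothness
#' \eqn{n P / b}, with \eqn{P} the pixel-edge perimeter and \eqn{b} the
#' bounding-box perimeter). Merging proceeds by local mutual best fitting:
#' regions are swept in ascending label order and a region merges with its
#' cheapest neighbour when the choice is mutual and the cost is below
#' \code{scale^2}; sweeps repeat until nothing changes. The fixed scan
#' order and the (cost, smaller label) tie-break make the result
#' deterministic; identical inputs give identical partitions.
#'
#' @param scene A \linkS4class{SceneRaster}.
#' @param heights A \linkS4class{HeightGrids}; the CHM is computed on the
#'   fly if still unset.
#' @param cfg A \linkS4class{RuleConfig} supplying defaults.
#' @param weights Layer weights (blue, green, red-edge, CHM).
#' @param scale,shape,compactness Scale parameter and shape/compactness
#'   weights.
#' @return A \linkS4class{SegmentMap} with an empty feature table; fill it
#'   with \code{\link{computeFeatures}}.
#' @export
segmentScene <- function(scene, heights, cfg = ruleConfig(),
                         weights = cfg@layerWeights, scale = cfg@segScale,
                         shape = cfg@segShape,
                         compactness = cfg@segCompactness) {
  stopifnot(is(scene, "SceneRaster"), is(heights, "HeightGrids"))
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be non-negative and not all zero")
  if (all(is.na(heights@chm))) heights <- computeCHM(heights)
  layers <- list(scene@blue, scene@green, scene@rededge, heights@chm)
  valid <- Reduce(`&`, lapply(layers, function(m) !is.na(m)))
  if (!any(valid)) stop("empty valid area: nothing to segment")
  layers <- lapply(layers, function(m) { m[!valid] <- 0; m })
  labels <- .cpp_segment(layers, as.numeric(weights), scale, shape,
                         compactness, valid)
  new("SegmentMap", labels = labels,
      table = data.frame(), borders = data.frame(a = integer(),
                                                 b = integer(),
                                                 edges = integer()),
      transform = scene@transform)
}

# per-label statistics of the label grid against the full layer stack
.objectStats <- function(labels, scene, heights, gv, npv, transform) {
  nr <- nrow(labels)
  idx <- which(labels > 0L)
  l <- labels[idx]
  K <- max(l)
  present <- sort(unique(l))
  n <- tabulate(l, K)
  ps <- transform[3L]
  layerMat <- cbind(blue = scene@blue[idx], green = scene@green[idx],
                    rededge = scene@rededge[idx], gv = gv@values[idx],
                    npv = npv@values[idx], chm = heights@chm[idx])
  sums <- rowsum(layerMat, l, na.rm = TRUE)
  cnts <- rowsum((!is.na(layerMat)) + 0, l)
  mu <- sums / pmax(cnts, 1)
  sq <- rowsum(layerMat^2, l, na.rm = TRUE) / pmax(cnts, 1)
  sd <- sqrt(pmax(sq - mu^2, 0))
  maxChm <- vapply(split(heights@chm[idx], l), function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE), 0)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  rmin <- vapply(split(rows, l), min, 0L)
  rmax <- vapply(split(rows, l), max, 0L)
  cmin <- vapply(split(cols, l), min, 0L)
  cmax <- vapply(split(cols, l), max, 0L)
  cx <- rowsum(.mapX(cols, transform), l) / n[present]
  cy <- rowsum(.mapY(rows, transform, nr), l) / n[present]
  # perimeter: pixel edges against a different label, nodata or the border
  pad <- function(m, dr, dc) {
    out <- matrix(0L, nr, ncol(labels))
    rs <- seq_len(nr) + dr; cs <- seq_len(ncol(labels)) + dc
    okr <- rs >= 1L & rs <= nr; okc <- cs >= 1L & cs <= ncol(labels)
    out[okr, okc] <- m[rs[okr], cs[okc]]
    out
  }
  perim <- integer(length(present))
  for (sh in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nb <- pad(labels, sh[1L], sh[2L])
    diffEdge <- labels[idx] != nb[idx]
    perim <- perim + tabulate(l[diffEdge], K)[present]
  }
  tab <- data.frame(
    label = present, area_px = n[present], area_m2 = n[present] * ps^2,
    mean_blue = mu[, "blue"], mean_green = mu[, "green"],
    mean_rededge = mu[, "rededge"], sd_blue = sd[, "blue"],
    sd_green = sd[, "green"], sd_rededge = sd[, "rededge"],
    mean_gv = mu[, "gv"], mean_npv = mu[, "npv"], mean_chm = mu[, "chm"],
    max_chm = unname(maxChm), sd_chm = sd[, "chm"],
    perimeter_px = perim,
    roundness = 1 - 4 * pi * n[present] / perim^2,
    rmin = unname(rmin), rmax = unname(rmax),
    cmin = unname(cmin), cmax = unname(cmax),
    centroid_x = as.vector(cx), centroid_y = as.vector(cy),
    class = "untagged", row.names = NULL, stringsAsFactors = FALSE)
  tab
}

# symmetric shared-border table (pixel edges) between distinct labels
.borderTable <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  pairs <- list()
  if (nc > 1L) {
    a <- labels[, -nc]; b <- labels[, -1L]
    sel <- a > 0L & b > 0L & a != b
    pairs[[1L]] <- cbind(a[sel], b[sel])
  }
  if (nr > 1L) {
    a <- labels[-nr, ]; b <- labels[-1L, ]
    sel <- a > 0L & b > 0L & a != b
    pairs[[2L]] <- cbind(a[sel], b[sel])
  }
  pr <- do.call(rbind, pairs)
  if (is.null(pr) || !nrow(pr))
    return(data.frame(a = integer(), b = integer(), edges = integer()))
  lo <- pmin(pr[, 1L], pr[, 2L])
  hi <- pmax(pr[, 1L], pr[, 2L])
  key <- paste(lo, hi)
  cnt <- table(key)
  parts <- do.call(rbind, strsplit(names(cnt), " ", fixed = TRUE))
  out <- data.frame(a = as.integer(parts[, 1L]), b = as.integer(parts[, 2L]),
                    edges = as.integer(cnt))
  out[order(out$a, out$b), , drop = FALSE]
}

#' Compute per-object features
#'
#' Fills the feature table of a \linkS4class{SegmentMap}: pixel and map
#' areas, per-band mean and standard deviation, mean GV/NPV, mean/max/sd
#' CHM, pixel-edge perimeter, roundness, bounding box, centroid and the
#' symmetric neighbour border-length table. Roundness is the deviation from
#' a circle, \eqn{1 - 4\pi A / P^2}, computed on the pixel footprint (0 for
#' an ideal continuous disc; about 0.38 for a rasterised disc, whose
#' staircase perimeter is \eqn{8r}); smaller is rounder.
#'
#' @param seg A \linkS4class{SegmentMap}.
#' @param scene,heights The layer sources (CHM must be filled).
#' @param gv,npv The two \linkS4class{IndexGrid}s.
#' @return The \linkS4class{SegmentMap} with table and borders filled.
#' @export
computeFeatures <- function(seg, scene, heights, gv, npv) {
  stopifnot(is(seg, "SegmentMap"))
  tab <- .objectStats(seg@labels, scene, heights, gv, npv, seg@transform)
  if (nrow(seg@table) && "class" %in% names(seg@table))
    tab$class <- seg@table$class[match(tab$label, seg@table$label)]
  seg@table <- tab
  seg@borders <- .borderTable(seg@labels)
  seg
}

#' Merge two adjacent objects
#'
#' The smaller numeric label survives; features of the merged object are
#' recombined exactly (pooled moments, perimeter minus twice the shared
#' border, merged bounding box) and the border table is updated.
#'
#' @param seg A \linkS4class{SegmentMap} with features computed.
#' @param labelA,labelB Labels of two adjacent objects.
#' @return The updated \linkS4class{SegmentMap}.
#' @export
mergeObjects <- function(seg, labelA, labelB) {
  tb <- seg@table
  if (!all(c(labelA, labelB) %in% tb$label))
    stop("unknown label: ", paste(setdiff(c(labelA, labelB), tb$label),
                                  collapse = ", "))
  bo <- seg@borders
  lo <- min(labelA, labelB); hi <- max(labelA, labelB)
  hit <- bo$a == lo & bo$b == hi
  if (!any(hit)) stop("objects ", labelA, " and ", labelB, " are not adjacent")
  shared <- bo$edges[hit]
  i <- which(tb$label == lo); j <- which(tb$label == hi)
  n1 <- tb$area_px[i]; n2 <- tb$area_px[j]; nm <- n1 + n2
  pool <- function(muCol, sdCol) {
    s <- n1 * tb[[muCol]][i] + n2 * tb[[muCol]][j]
    q <- n1 * (tb[[sdCol]][i]^2 + tb[[muCol]][i]^2) +
      n2 * (tb[[sdCol]][j]^2 + tb[[muCol]][j]^2)
    c(mean = s / nm, sd = sqrt(max(q / nm - (s / nm)^2, 0)))
  }
  for (band in c("blue", "green", "rededge")) {
    p <- pool(paste0("mean_", band), paste0("sd_", band))
    tb[[paste0("mean_", band)]][i] <- p[["mean"]]
    tb[[paste0("sd_", band)]][i] <- p[["sd"]]
  }
  for (col in c("mean_gv", "mean_npv"))
    tb[[col]][i] <- (n1 * tb[[col]][i] + n2 * tb[[col]][j]) / nm
  p <- pool("mean_chm", "sd_chm")
  tb$mean_chm[i] <- p[["mean"]]; tb$sd_chm[i] <- p[["sd"]]
  tb$max_chm[i] <- max(tb$max_chm[i], tb$max_chm[j], na.rm = TRUE)
  tb$centroid_x[i] <- (n1 * tb$centroid_x[i] + n2 * tb$centroid_x[j]) / nm
  tb$centroid_y[i] <- (n1 * tb$centroid_y[i] + n2 * tb$centroid_y[j]) / nm
  tb$area_px[i] <- nm
  tb$area_m2[i] <- nm * seg@transform[3L]^2
  tb$perimeter_px[i] <- tb$perimeter_px[i] + tb$perimeter_px[j] - 2L * shared
  tb$roundness[i] <- 1 - 4 * pi * nm / tb$perimeter_px[i]^2
  tb$rmin[i] <- min(tb$rmin[i], tb$rmin[j])
  tb$rmax[i] <- max(tb$rmax[i], tb$rmax[j])
  tb$cmin[i] <- min(tb$cmin[i], tb$cmin[j])
  tb$cmax[i] <- max(tb$cmax[i], tb$cmax[j])
  seg@table <- tb[tb$label != hi, , drop = FALSE]
  seg@labels[seg@labels == hi] <- lo
  # fold the border table: hi -> lo, re-aggregate, drop the merged pair
  bo <- bo[!hit, , drop = FALSE]
  bo$a[bo$a == hi] <- lo; bo$b[bo$b == hi] <- lo
  lo2 <- pmin(bo$a, bo$b); hi2 <- pmax(bo$a, bo$b)
  agg <- rowsum(bo$edges, paste(lo2, hi2))
  parts <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
  nb <- data.frame(a = as.integer(parts[, 1L]), b = as.integer(parts[, 2L]),
                   edges = as.integer(agg))
  seg@borders <- nb[order(nb$a, nb$b), , drop = FALSE]
  seg
}
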
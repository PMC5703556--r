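## Raster, vector and configuration I/O.
##
## Rasters travel either as TIFF (pixel store via the `tiff` package, with an
## ESRI world file alongside for georeferencing and a small JSON sidecar
## carrying CRS, nodata and the linear scaling used to fit values into the
## TIFF's 32-bit [0,1] samples) or as ESRI ASCII grids (.asc), a plain-text
## format that stores full-precision values and georeferencing in one file.
## Crowns, fishnet cells and ground truth travel as GeoJSON.

.auxPath <- function(path) paste0(path, ".aux.json")
.tfwPath <- function(path) sub("\\.tiff?$", ".tfw", path, ignore.case = TRUE)

#' Write a raster grid to file
#'
#' Writes a matrix (one band) or a 3-band array to \code{.tif} (TIFF +
#' world file + JSON sidecar; values are stored as 32-bit samples after an
#' affine rescaling recorded in the sidecar — a quantisation of about 5e-10
#' of the value range — with the top of the sample range reserved as the
#' nodata marker) or, for a single band, to
#' \code{.asc} (ESRI ASCII grid, full-precision text). \code{NA} pixels are
#' written as the nodata sentinel.
#'
#' @param values Numeric matrix or \code{nr x nc x 3} array.
#' @param path Output path; format chosen by extension (.tif/.tiff/.asc).
#' @param transform \code{c(origin_x, origin_y, pixel_size)}.
#' @param crs CRS tag stored in the sidecar.
#' @param nodata Sentinel value replacing \code{NA} on file.
#' @param range Optional fixed \code{c(low, high)} scaling range for TIFF;
#'   by default the observed value range (including the sentinel) is used.
#' @return \code{path}, invisibly.
#' @export
writeRasterGrid <- function(values, path, transform, crs = "local",
                            nodata = -9999, range = NULL) {
  if (grepl("\\.asc$", path, ignore.case = TRUE)) {
    if (length(dim(values)) != 2L)
      stop("ESRI ASCII grids are single-band; use TIFF for multiband data")
    return(.writeAsc(values, path, transform, nodata))
  }
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("unsupported raster extension (use .tif, .tiff or .asc): ", path)
  v <- values
  na <- is.na(v)
  if (is.null(range)) {
    range <- suppressWarnings(base::range(v, na.rm = TRUE))
    if (!all(is.finite(range))) range <- c(0, 1)
    if (range[1L] == range[2L]) range[2L] <- range[1L] + 1
  }
  # data occupy [0, 0.5] of the sample range; the top marks nodata, so the
  # sentinel never contaminates the value scaling
  scaled <- (v - range[1L]) / (range[2L] - range[1L]) * 0.5
  scaled[na] <- 0
  if (any(scaled < -1e-9 | scaled > 0.5 + 1e-9))
    stop("values fall outside the supplied scaling range")
  scaled[scaled < 0] <- 0; scaled[scaled > 0.5] <- 0.5
  scaled[na] <- 1
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  nr <- dim(values)[1L]
  ps <- transform[3L]
  tfw <- c(ps, 0, 0, -ps,
           transform[1L] + 0.5 * ps,
           transform[2L] + (nr - 0.5) * ps)
  writeLines(formatC(tfw, format = "g", digits = 15), .tfwPath(path))
  aux <- list(crs = crs, nodata = nodata,
              offset = range[1L], scale = 2 * (range[2L] - range[1L]),
              bands = if (length(dim(values)) == 3L) dim(values)[3L] else 1L)
  jsonlite::write_json(aux, .auxPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.writeAsc <- function(values, path, transform, nodata) {
  v <- values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(v)),
               paste("nrows", nrow(v)),
               paste("xllcorner", formatC(transform[1L], format = "g", digits = 15)),
               paste("yllcorner", formatC(transform[2L], format = "g", digits = 15)),
               paste("cellsize", formatC(transform[3L], format = "g", digits = 15)),
               paste("NODATA_value", formatC(nodata, format = "g", digits = 15))),
             con)
  writeLines(apply(v, 1L, function(row)
    paste(formatC(row, format = "g", digits = 17), collapse = " ")), con)
  invisible(path)
}

#' Read a raster grid from file
#'
#' Counterpart of \code{\link{writeRasterGrid}}. Nodata pixels come back as
#' \code{NA}.
#'
#' @param path A \code{.tif}/\code{.tiff} or \code{.asc} file.
#' @return List with \code{values} (matrix or array), \code{transform},
#'   \code{crs} and \code{nodata}.
#' @export
readRasterGrid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.asc$", path, ignore.case = TRUE)) return(.readAsc(path))
  v <- tiff::readTIFF(path)
  aux <- if (file.exists(.auxPath(path)))
    jsonlite::read_json(.auxPath(path), simplifyVector = TRUE)
  else list(crs = "local", nodata = -9999, offset = 0, scale = 2)
  na <- v > 0.75                      # stored nodata marker (data <= 0.5)
  v <- v * aux$scale + aux$offset
  v[na] <- NA_real_
  nr <- dim(v)[1L]
  transform <- c(0, 0, 1)
  if (file.exists(.tfwPath(path))) {
    tfw <- as.numeric(readLines(.tfwPath(path)))
    ps <- tfw[1L]
    transform <- c(tfw[5L] - 0.5 * ps, tfw[6L] - (nr - 0.5) * ps, ps)
  }
  list(values = v, transform = transform, crs = aux$crs, nodata = aux$nodata)
}

.readAsc <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "[[:space:]]+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  body <- scan(path, skip = 6L, quiet = TRUE)
  v <- matrix(body, nrow = vals[["nrows"]], ncol = vals[["ncols"]], byrow = TRUE)
  nodata <- vals[["nodata_value"]]
  v[v == nodata] <- NA_real_
  list(values = v,
       transform = c(vals[["xllcorner"]], vals[["yllcorner"]], vals[["cellsize"]]),
       crs = "local", nodata = nodata)
}

#' Read a scene (3-band mosaic plus DSM and DEM)
#'
#' Reads the three-band orthomosaic and the two elevation grids and returns
#' them aligned on the mosaic's grid. Elevation grids whose transform
#' disagrees with the mosaic are resampled onto it by nearest neighbour,
#' with a warning. The CHM is left unset; fill it with
#' \code{\link{computeCHM}}.
#'
#' @param multibandPath 3-band raster (blue, green, red-edge).
#' @param dsmPath,demPath Single-band elevation rasters (m).
#' @return List with elements \code{scene} (\linkS4class{SceneRaster}) and
#'   \code{heights} (\linkS4class{HeightGrids}).
#' @export
readScene <- function(multibandPath, dsmPath, demPath) {
  for (p in c(multibandPath, dsmPath, demPath))
    if (!file.exists(p)) stop("missing input file: ", p)
  mb <- readRasterGrid(multibandPath)
  if (length(dim(mb$values)) != 3L || dim(mb$values)[3L] != 3L)
    stop("expected 3 bands in ", multibandPath, " (got ",
         if (length(dim(mb$values)) == 3L) dim(mb$values)[3L] else 1L, ")")
  dims <- dim(mb$values)[1:2]
  pick <- function(p) {
    g <- readRasterGrid(p)
    if (!is.null(g$crs) && g$crs != "local" && mb$crs != "local" &&
        !identical(g$crs, mb$crs))
      stop("CRS mismatch: ", g$crs, " vs ", mb$crs)
    if (!.sameTransform(g$transform, mb$transform) ||
        !identical(dim(g$values), dims)) {
      warning("grid ", p, " is not co-registered with the mosaic; ",
              "resampling to the mosaic grid by nearest neighbour")
      g$values <- .resampleNN(g$values, g$transform, mb$transform, dims)
    }
    g$values
  }
  dsm <- pick(dsmPath)
  dem <- pick(demPath)
  scene <- new("SceneRaster",
               blue = mb$values[, , 1L], green = mb$values[, , 2L],
               rededge = mb$values[, , 3L], transform = mb$transform,
               crsTag = if (is.null(mb$crs)) "local" else mb$crs,
               nodata = mb$nodata)
  heights <- new("HeightGrids", dem = dem, dsm = dsm,
                 chm = matrix(NA_real_, dims[1L], dims[2L]),
                 transform = mb$transform)
  validObject(scene); validObject(heights)
  list(scene = scene, heights = heights)
}

## ---- configuration --------------------------------------------------------

.configKeyMap <- c(
  npv_threshold = "npvThreshold", gdvi_threshold = "gdviThreshold",
  sapote_gdvi_min = "sapoteGdviMin", roundness_max = "roundnessMax",
  cluster_area_max_px = "clusterAreaMaxPx", dead_area_min_px = "deadAreaMinPx",
  chm_bush_max_m = "chmBushMaxM", mmu_m2 = "mmuM2",
  seed_search_range_npv_px = "seedRangeNpvPx",
  seed_search_range_gv_px = "seedRangeGvPx",
  seg_scale = "segScale", seg_shape = "segShape",
  seg_compactness = "segCompactness",
  relative_border_merge_min = "relBorderMergeMin",
  chm_statistic = "chmStatistic",
  seed_smooth_radius_px = "seedSmoothRadiusPx",
  layer_weight_blue = NA, layer_weight_green = NA,
  layer_weight_rededge = NA, layer_weight_chm = NA)

#' Build or load the rule-set configuration
#'
#' \code{ruleConfig()} builds a \linkS4class{RuleConfig} from defaults plus
#' slot-name overrides. \code{loadConfig()} reads a flat \code{key: value}
#' text file (YAML subset); absent keys take the defaults, unknown keys are
#' an error. \code{saveConfig()} writes the full configuration back in the
#' same format.
#'
#' @param ... For \code{ruleConfig}: named slot overrides, e.g.
#'   \code{segScale = 30}.
#' @return A validated \linkS4class{RuleConfig}.
#' @examples
#' cfg <- ruleConfig()
#' cfg@npvThreshold
#' @export
ruleConfig <- function(...) {
  over <- list(...)
  cfg <- new("RuleConfig")
  for (nm in names(over)) {
    if (!nm %in% slotNames(cfg)) stop("unknown RuleConfig slot: ", nm)
    v <- over[[nm]]
    if (nm %in% c("seedRangeNpvPx", "seedRangeGvPx", "seedSmoothRadiusPx"))
      v <- as.integer(v)
    slot(cfg, nm) <- v
  }
  validObject(cfg)
  cfg
}

#' @rdname ruleConfig
#' @param path Config file path (for \code{loadConfig}, \code{NULL} gives
#'   pure defaults).
#' @export
loadConfig <- function(path = NULL) {
  cfg <- new("RuleConfig")
  if (is.null(path)) { validObject(cfg); return(cfg) }
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  lw <- cfg@layerWeights
  for (key in names(raw)) {
    if (!key %in% names(.configKeyMap)) stop("unknown config key: ", key)
    val <- raw[[key]]
    if (key == "chm_statistic") {
      if (!is.character(val)) stop("config key ", key, " must be text")
    } else if (!is.numeric(val)) {
      stop("config key ", key, " must be numeric, got: ", deparse(val))
    }
    if (startsWith(key, "layer_weight_")) {
      lw[[sub("layer_weight_", "", key)]] <- val
    } else {
      nm <- .configKeyMap[[key]]
      val <- if (nm %in% c("seedRangeNpvPx", "seedRangeGvPx",
                           "seedSmoothRadiusPx")) as.integer(val)
             else if (is.numeric(val)) as.numeric(val) else val
      slot(cfg, nm) <- val
    }
  }
  cfg@layerWeights <- lw
  validObject(cfg)
  cfg
}

#' @rdname ruleConfig
#' @param cfg A \linkS4class{RuleConfig} (for \code{saveConfig}).
#' @export
saveConfig <- function(cfg, path) {
  inv <- names(.configKeyMap)[!is.na(.configKeyMap)]
  lines <- vapply(inv, function(key) {
    v <- slot(cfg, .configKeyMap[[key]])
    paste0(key, ": ", if (is.character(v)) v else formatC(v, format = "g", digits = 15))
  }, "")
  wl <- vapply(seq_along(cfg@layerWeights), function(i)
    paste0("layer_weight_", names(cfg@layerWeights)[i], ": ",
           formatC(cfg@layerWeights[i], format = "g", digits = 15)), "")
  writeLines(c(lines, wl), path)
  invisible(path)
}

## ---- crowns as GeoJSON ----------------------------------------------------

#' Write delineated crowns to a GeoJSON file
#'
#' One polygon feature per crown, with attributes \code{id}, \code{class},
#' \code{area_m2}, \code{mean_gdvi}, \code{mean_npv} and \code{max_chm}.
#' Polygons are the exact pixel-footprint outlines in map coordinates
#' (exterior ring counter-clockwise, holes clockwise).
#'
#' @param crowns A \linkS4class{CrownSet} or \linkS4class{ClassifiedMap}.
#' @param path Output path (\code{.geojson} or \code{.json}).
#' @return \code{path}, invisibly.
#' @export
writeCrowns <- function(crowns, path) {
  if (is(crowns, "ClassifiedMap")) crowns <- crowns@crowns
  if (!grepl("\\.(geo)?json$", path, ignore.case = TRUE))
    stop("unsupported vector extension (GeoJSON only): ", path)
  tb <- crowns@table
  feats <- lapply(seq_len(nrow(tb)), function(i) {
    rings <- .tracePolygons(crowns@labels == tb$id[i], crowns@transform)
    coords <- lapply(rings, function(r) lapply(seq_len(nrow(r)),
                                               function(k) unname(r[k, ])))
    list(type = "Feature",
         properties = list(id = tb$id[i],
                           class = if ("class" %in% names(tb)) tb$class[i] else NA,
                           area_m2 = tb$area_m2[i],
                           mean_gdvi = tb$mean_gv[i],
                           mean_npv = tb$mean_npv[i],
                           max_chm = tb$max_chm[i]),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read crowns back from GeoJSON
#'
#' @param path A GeoJSON file written by \code{\link{writeCrowns}} (or
#'   compatible).
#' @return Data frame of feature attributes with a \code{geometry} list
#'   column of polygon rings (matrices of x, y).
#' @export
readCrowns <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fc <- jsonlite::read_json(path)
  if (is.null(fc$features)) stop("not a GeoJSON FeatureCollection: ", path)
  rows <- lapply(fc$features, function(f) {
    p <- f$properties
    data.frame(id = as.integer(p$id),
               class = if (is.null(p$class)) NA_character_ else as.character(p$class),
               area_m2 = as.numeric(p$area_m2),
               mean_gdvi = as.numeric(p$mean_gdvi),
               mean_npv = as.numeric(p$mean_npv),
               max_chm = as.numeric(p$max_chm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(id = integer(), class = character(),
                      area_m2 = numeric(), mean_gdvi = numeric(),
                      mean_npv = numeric(), max_chm = numeric())
  } else {
    out$geometry <- lapply(fc$features, function(f)
      lapply(f$geometry$coordinates, function(ring)
        do.call(rbind, lapply(ring, function(pt)
          c(x = pt[[1L]], y = pt[[2L]])))))
  }
  out
}

#' Write a scene (bands + heights) to a directory
#'
#' Convenience writer producing \code{bands.tif}, \code{dsm.tif} and
#' \code{dem.tif} that \code{\link{readScene}} can read back.
#'
#' @param scene A \linkS4class{SceneRaster}.
#' @param heights A \linkS4class{HeightGrids}.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths.
#' @export
writeScene <- function(scene, heights, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bands <- array(c(scene@blue, scene@green, scene@rededge),
                 dim = c(dim(scene@blue), 3L))
  p1 <- file.path(dir, "bands.tif")
  p2 <- file.path(dir, "dsm.tif")
  p3 <- file.path(dir, "dem.tif")
  writeRasterGrid(bands, p1, scene@transform, scene@crsTag, scene@nodata)
  writeRasterGrid(heights@dsm, p2, heights@transform, scene@crsTag, scene@nodata)
  writeRasterGrid(heights@dem, p3, heights@transform, scene@crsTag, scene@nodata)
  c(bands = p1, dsm = p2, dem = p3)
}
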
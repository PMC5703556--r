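# Shared fixture builders and independent oracles. Everything is generated
# in code; no stored binary fixtures.

flatScene <- function(nr, nc, profile, pixel = 1, origin = c(0, 0)) {
  uavCrowns:::.flatScene(nr, nc, profile, pixel = pixel, origin = origin)
}

flatHeights <- function(nr, nc, dem = 0, dsm = dem, pixel = 1) {
  uavCrowns:::.flatHeights(nr, nc, dem = dem, dsm = dsm, pixel = pixel)
}

# scene whose bands are given matrices (all same values across bands unless
# supplied separately)
bandScene <- function(blue, green = blue, rededge = blue, pixel = 1) {
  methods::new("SceneRaster", blue = blue, green = green, rededge = rededge,
               transform = c(0, 0, pixel), crsTag = "local", nodata = -9999)
}

# a small SceneSpec without clusters, convenient for fast pipeline tests
tinySpec <- function(...) {
  args <- list(...)
  base <- list(extent = c(40, 40),
               counts = c(sapote = 2, algarrobo_alive = 2,
                          algarrobo_dead = 0, overo = 0),
               clusters = list(), noiseSd = 0, noiseSdDsm = 0, rngSeed = 42)
  base[names(args)] <- args
  do.call(sceneSpec, base)
}

# CrownSet built from a label grid over flat layers, with features computed
# through the package's exported feature path
crownSetFrom <- function(labels, scene, heights, kinds) {
  heights <- computeCHM(heights)
  gv <- computeGV(scene)
  npv <- computeNPV(scene)
  seg <- methods::new("SegmentMap", labels = labels, table = data.frame(),
                      borders = data.frame(a = integer(), b = integer(),
                                           edges = integer()),
                      transform = gridTransform(scene))
  seg <- computeFeatures(seg, scene, heights, gv, npv)
  tb <- objectTable(seg)
  tb$vegetation_kind <- kinds[tb$label]
  tb$provenance <- "isolated"
  tb$class <- NA_character_
  methods::new("CrownSet", labels = labels, table = tb,
               borders = sharedBorders(seg),
               transform = gridTransform(scene))
}

## ---- independent oracles --------------------------------------------------

# per-object mean of a grid by explicit pixel accumulation
oracleMean <- function(labels, grid, lab) {
  v <- grid[labels == lab]
  sum(v) / length(v)
}

# brute-force windowed local maxima (Chebyshev window, lexicographic ties)
oracleSeeds <- function(values, mask, range) {
  nr <- nrow(values); nc <- ncol(values)
  out <- NULL
  for (cc in seq_len(nc)) for (r in seq_len(nr)) {
    if (!mask[r, cc] || is.na(values[r, cc])) next
    v <- values[r, cc]
    seed <- TRUE
    for (c2 in max(1, cc - range):min(nc, cc + range)) {
      for (r2 in max(1, r - range):min(nr, r + range)) {
        if (r2 == r && c2 == cc) next
        if (!mask[r2, c2] || is.na(values[r2, c2])) next
        u <- values[r2, c2]
        if (u > v || (u == v && (r2 < r || (r2 == r && c2 < cc)))) {
          seed <- FALSE
          break
        }
      }
      if (!seed) break
    }
    if (seed) out <- rbind(out, c(r, cc))
  }
  out
}

# region heterogeneity-increase cost of merging two pixel sets, computed
# from scratch (the multiresolution merge criterion)
oracleMergeCost <- function(layers, weights, maskA, maskB,
                            shapeW = 0.1, compactW = 0.5) {
  stats <- function(mask) {
    n <- sum(mask)
    idx <- which(mask, arr.ind = TRUE)
    per <- 0
    nr <- nrow(mask); nc <- ncol(mask)
    for (i in seq_len(nrow(idx))) {
      r <- idx[i, 1]; cc <- idx[i, 2]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- r + d[1]; c2 <- cc + d[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || !mask[r2, c2])
          per <- per + 1
      }
    }
    bbox <- 2 * ((max(idx[, 1]) - min(idx[, 1]) + 1) +
                   (max(idx[, 2]) - min(idx[, 2]) + 1))
    list(n = n, per = per, bbox = bbox,
         sd = vapply(layers, function(l) {
           v <- l[mask]
           sqrt(max(mean(v^2) - mean(v)^2, 0))
         }, 0))
  }
  a <- stats(maskA); b <- stats(maskB); m <- stats(maskA | maskB)
  colour <- sum(weights * (m$n * m$sd - a$n * a$sd - b$n * b$sd))
  cmp <- sqrt(m$n) * m$per - sqrt(a$n) * a$per - sqrt(b$n) * b$per
  smo <- m$n * m$per / m$bbox - a$n * a$per / a$bbox - b$n * b$per / b$bbox
  (1 - shapeW) * colour + shapeW * (compactW * cmp + (1 - compactW) * smo)
}

# split every label of an arbitrary label grid into 4-connected components
relabelCC <- function(lab) {
  out <- matrix(0L, nrow(lab), ncol(lab))
  nxt <- 0L
  for (l in unique(as.vector(lab))) {
    cc <- uavCrowns:::.cpp_cc_label(lab == l)
    for (k in seq_len(max(cc))) {
      nxt <- nxt + 1L
      out[cc == k] <- nxt
    }
  }
  out
}

# random connected blob mask grown from a point (for partition properties)
randomBlob <- function(nr, nc, npix) {
  mask <- matrix(FALSE, nr, nc)
  r <- sample.int(nr, 1); cc <- sample.int(nc, 1)
  mask[r, cc] <- TRUE
  frontier <- list(c(r, cc))
  while (sum(mask) < npix && length(frontier)) {
    i <- sample.int(length(frontier), 1)
    p <- frontier[[i]]
    nbs <- list(p + c(-1, 0), p + c(1, 0), p + c(0, -1), p + c(0, 1))
    nbs <- Filter(function(q) q[1] >= 1 && q[1] <= nr && q[2] >= 1 &&
                    q[2] <= nc && !mask[q[1], q[2]], nbs)
    if (!length(nbs)) {
      frontier[[i]] <- NULL
      next
    }
    q <- nbs[[sample.int(length(nbs), 1)]]
    mask[q[1], q[2]] <- TRUE
    frontier[[length(frontier) + 1]] <- q
  }
  mask
}
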
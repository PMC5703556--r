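## Internal grid helpers shared by all stages.

# map coordinates of pixel centres; transform = c(origin_x, origin_y, pixel)
.mapX <- function(col, transform) transform[1L] + (col - 0.5) * transform[3L]
.mapY <- function(row, transform, nr) transform[2L] + (nr - row + 0.5) * transform[3L]

# inverse: map coords -> (row, col), 1-based
.rowOf <- function(y, transform, nr) nr - floor((y - transform[2L]) / transform[3L])
.colOf <- function(x, transform) floor((x - transform[1L]) / transform[3L]) + 1L

.sameTransform <- function(a, b, tol = 1e-6) {
  all(abs(a - b) <= tol * max(1, abs(a[3L])))
}

# mask-aware box mean of half-width `radius` via integral images; pixels
# outside the mask (or NA) do not contribute and come back NA.
.boxMeanMasked <- function(values, mask, radius) {
  if (radius <= 0L) {
    out <- values
    out[!mask] <- NA_real_
    return(out)
  }
  nr <- nrow(values); nc <- ncol(values)
  ok <- mask & is.finite(values)
  v <- values
  v[!ok] <- 0
  cs2 <- function(m) {                # padded 2-D cumulative sum
    mm <- matrix(if (nr > 1L) apply(m, 2L, cumsum) else m, nr, nc)
    for (j in seq(2L, length.out = max(0L, nc - 1L)))
      mm[, j] <- mm[, j] + mm[, j - 1L]
    p <- matrix(0, nr + 1L, nc + 1L)
    p[-1L, -1L] <- mm
    p
  }
  S <- cs2(v); C <- cs2(ok + 0)
  r1 <- pmax(seq_len(nr) - radius, 1L); r2 <- pmin(seq_len(nr) + radius, nr)
  c1 <- pmax(seq_len(nc) - radius, 1L); c2 <- pmin(seq_len(nc) + radius, nc)
  win <- function(p) {
    p[r2 + 1L, c2 + 1L, drop = FALSE] - p[r1, c2 + 1L, drop = FALSE] -
      p[r2 + 1L, c1, drop = FALSE] + p[r1, c1, drop = FALSE]
  }
  n <- win(C)
  out <- win(S) / ifelse(n > 0, n, NA_real_)
  out[!mask] <- NA_real_
  out
}

# nearest-neighbour resampling of `m` from its transform onto a target grid
.resampleNN <- function(m, fromTransform, toTransform, dims) {
  nrTo <- dims[1L]; ncTo <- dims[2L]
  nrFrom <- nrow(m)
  x <- .mapX(seq_len(ncTo), toTransform)
  y <- .mapY(seq_len(nrTo), toTransform, nrTo)
  cols <- pmin(pmax(.colOf(x, fromTransform), 1L), ncol(m))
  rows <- pmin(pmax(.rowOf(y, fromTransform, nrFrom), 1L), nrFrom)
  m[rows, cols, drop = FALSE]
}

# flat constant-band scene, used in examples and tests
.flatScene <- function(nr, nc, profile, pixel = 0.083, origin = c(0, 0)) {
  mk <- function(v) matrix(v, nr, nc)
  new("SceneRaster", blue = mk(profile[1L]), green = mk(profile[2L]),
      rededge = mk(profile[3L]), transform = c(origin, pixel),
      crsTag = "local", nodata = -9999)
}

.flatHeights <- function(nr, nc, dem = 0, dsm = dem, pixel = 0.083,
                         origin = c(0, 0)) {
  new("HeightGrids", dem = matrix(dem, nr, nc), dsm = matrix(dsm, nr, nc),
      chm = matrix(NA_real_, nr, nc), transform = c(origin, pixel))
}

## ---- polygon tracing ------------------------------------------------------

# Trace the boundary of a pixel footprint into closed rings of map
# coordinates. Corners are lattice points; edges are oriented with the
# interior on the left (matrix space), then rings are re-oriented in map
# space: first (outer) ring counter-clockwise, holes clockwise.
.tracePolygons <- function(mask, transform) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(list())
  r <- idx[, 1L]; c <- idx[, 2L]
  inside <- function(rr, cc) {
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    out <- logical(length(rr))
    out[ok] <- mask[cbind(rr[ok], cc[ok])]
    out
  }
  # boundary edges as corner index pairs; corner (i, j) -> key i*(nc+1)+j,
  # i in 0..nr, j in 0..nc
  key <- function(i, j) i * (nc + 1L) + j
  es <- list()
  top <- !inside(r - 1L, c)
  es[[1L]] <- cbind(key(r[top] - 1L, c[top] - 1L), key(r[top] - 1L, c[top]))
  bot <- !inside(r + 1L, c)
  es[[2L]] <- cbind(key(r[bot], c[bot]), key(r[bot], c[bot] - 1L))
  lef <- !inside(r, c - 1L)
  es[[3L]] <- cbind(key(r[lef], c[lef] - 1L), key(r[lef] - 1L, c[lef] - 1L))
  rig <- !inside(r, c + 1L)
  es[[4L]] <- cbind(key(r[rig] - 1L, c[rig]), key(r[rig], c[rig]))
  edges <- do.call(rbind, es)
  o <- order(edges[, 1L], edges[, 2L])
  edges <- edges[o, , drop = FALSE]
  used <- logical(nrow(edges))
  starts <- edges[, 1L]
  firstAt <- match(unique(starts), starts)
  lookup <- new.env(hash = TRUE, size = length(firstAt))
  for (i in seq_len(nrow(edges)))
    assign(as.character(edges[i, 1L]),
           c(get0(as.character(edges[i, 1L]), envir = lookup), i),
           envir = lookup)
  rings <- list()
  for (e0 in seq_len(nrow(edges))) {
    if (used[e0]) next
    ring <- edges[e0, 1L]
    cur <- e0
    repeat {
      used[cur] <- TRUE
      nxt <- edges[cur, 2L]
      ring <- c(ring, nxt)
      if (nxt == ring[1L]) break
      cand <- get0(as.character(nxt), envir = lookup)
      cand <- cand[!used[cand]]
      if (!length(cand)) break                  # should not happen
      if (length(cand) > 1L) {
        # pinch corner: prefer the sharpest left turn to stay on one ring
        din <- .cornerDir(edges[cur, 1L], edges[cur, 2L], nc)
        turn <- vapply(cand, function(k)
          .turnScore(din, .cornerDir(edges[k, 1L], edges[k, 2L], nc)), 0)
        cand <- cand[order(turn)][1L]
      }
      cur <- cand
    }
    i <- ring %/% (nc + 1L); j <- ring %% (nc + 1L)
    xy <- cbind(x = transform[1L] + j * transform[3L],
                y = transform[2L] + (nr - i) * transform[3L])
    rings[[length(rings) + 1L]] <- .dropCollinear(xy)
  }
  areas <- vapply(rings, .ringArea, 0)
  ord <- order(-abs(areas))
  rings <- rings[ord]; areas <- areas[ord]
  # RFC 7946 winding: exterior CCW (positive area), holes CW
  rings[[1L]] <- if (areas[1L] < 0) rings[[1L]][rev(seq_len(nrow(rings[[1L]]))), ] else rings[[1L]]
  if (length(rings) > 1L)
    for (k in 2L:length(rings))
      if (areas[k] > 0) rings[[k]] <- rings[[k]][rev(seq_len(nrow(rings[[k]]))), ]
  rings
}

.cornerDir <- function(a, b, nc) {
  c((b %% (nc + 1L)) - (a %% (nc + 1L)), (b %/% (nc + 1L)) - (a %/% (nc + 1L)))
}

# 0 = left turn, 1 = straight, 2 = right turn (matrix space, row down)
.turnScore <- function(din, dout) {
  cross <- din[1L] * dout[2L] - din[2L] * dout[1L]
  if (cross < 0) 0 else if (cross == 0) 1 else 2
}

.ringArea <- function(xy) {
  n <- nrow(xy)
  x <- xy[, 1L]; y <- xy[, 2L]
  sum(x[-n] * y[-1L] - x[-1L] * y[-n]) / 2
}

.dropCollinear <- function(xy) {
  n <- nrow(xy)
  if (n <= 4L) return(xy)
  keep <- rep(TRUE, n)
  for (i in 2L:(n - 1L)) {
    d1 <- xy[i, ] - xy[i - 1L, ]
    d2 <- xy[i + 1L, ] - xy[i, ]
    if (d1[1L] * d2[2L] - d1[2L] * d2[1L] == 0) keep[i] <- FALSE
  }
  out <- xy[keep, , drop = FALSE]
  if (!identical(out[1L, ], out[nrow(out), ]))
    out <- rbind(out, out[1L, ])
  out
}
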
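## Synthetic labelled scenes: star-shaped Algarrobo crowns (alive green /
## dead grey with elevated blue), compact Sapote ellipses with a strong
## red-edge response, and low reticulated Overo patches along sinuous
## runnels, over dark bare soil, with cosine canopy domes on a sloping DEM.

#' Synthetic scene specification
#'
#' All knobs of the scene generator in one validated object. Class spectral
#' profiles must respect, in expectation, the orderings the published rule
#' set assumes: Sapote GV at or above 0.08; alive Algarrobo GV strictly
#' between 0.03 and 0.08; dead Algarrobo and Overo NPV above 0.053; dead
#' Algarrobo taller than 0.4 m and Overo lower.
#'
#' @slot extent Scene width and height (m).
#' @slot pixelSize Ground resolution (m, default 0.083).
#' @slot counts Named integer vector: trees/patches per class.
#' @slot radii Named list of \code{c(min, max)} crown radii (m); for Overo
#'   the half-width of the patch lobes.
#' @slot crownHeights Named list of \code{c(min, max)} canopy heights (m).
#' @slot profiles Named list of mean (blue, green, red-edge) reflectance per
#'   class plus \code{background}.
#' @slot blueBoost Extra blue reflectance at the crown centre of the
#'   non-photosynthetic classes, decaying linearly to the crown edge; gives
#'   each dead crown a unique interior NPV maximum.
#' @slot noiseSd Additive per-band Gaussian noise sd.
#' @slot noiseSdDsm Additive DSM noise sd (m).
#' @slot demBase,demSlope Terrain plane: base elevation (m) and (x, y)
#'   gradients.
#' @slot clusters List of \code{list(class =, size =)} tangent crown
#'   clusters carved out of \code{counts}.
#' @slot sparseCloudFrac Fraction of dead-crown DSM pixels collapsed to the
#'   terrain, emulating photogrammetric point-cloud dropout over leafless
#'   canopies (0 disables).
#' @slot minSeparation Minimum gap between non-clustered crowns (m).
#' @slot rngSeed Integer seed; scenes are bit-identical given the same seed.
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(extent = "numeric", pixelSize = "numeric",
                 counts = "integer", radii = "list",
                 crownHeights = "list", profiles = "list",
                 blueBoost = "numeric", noiseSd = "numeric",
                 noiseSdDsm = "numeric", demBase = "numeric",
                 demSlope = "numeric", clusters = "list",
                 sparseCloudFrac = "numeric", minSeparation = "numeric",
                 rngSeed = "integer"),
  prototype(
    extent = c(140, 120), pixelSize = 0.083,
    counts = c(sapote = 16L, algarrobo_alive = 14L, algarrobo_dead = 12L,
               overo = 6L),
    radii = list(sapote = c(2.5, 4), algarrobo_alive = c(3.5, 5.5),
                 algarrobo_dead = c(7, 9), overo = c(1.0, 1.6)),
    crownHeights = list(sapote = c(4, 7), algarrobo_alive = c(5, 9),
                        algarrobo_dead = c(3, 7), overo = c(0.15, 0.3)),
    profiles = list(background = c(0.10, 0.12, 0.12),
                    sapote = c(0.06, 0.16, 0.20),
                    algarrobo_alive = c(0.06, 0.17, 0.19),
                    algarrobo_dead = c(0.20, 0.17, 0.17),
                    overo = c(0.21, 0.175, 0.175)),
    blueBoost = c(algarrobo_dead = 0.05, overo = 0.02),
    noiseSd = 0.01, noiseSdDsm = 0.02,
    demBase = 100, demSlope = c(0.01, 0.005),
    clusters = list(list(class = "algarrobo_alive", size = 4L),
                    list(class = "algarrobo_dead", size = 3L)),
    sparseCloudFrac = 0, minSeparation = 1.5, rngSeed = 1L))

.treeClasses <- c("sapote", "algarrobo_alive", "algarrobo_dead")
.allClasses <- c(.treeClasses, "overo")

setValidity("SceneSpec", function(object) {
  msg <- character()
  gv <- function(p) (p[3L] - p[2L]) / (p[3L] + p[2L])
  npv <- function(p) (p[1L] - p[2L]) / (p[1L] + p[2L])
  pr <- object@profiles
  if (!all(c("background", .allClasses) %in% names(pr)))
    return("profiles must cover background and all four classes")
  if (gv(pr$sapote) < 0.08)
    msg <- c(msg, "Sapote profile must have GV >= 0.08")
  if (gv(pr$algarrobo_alive) <= 0.03 || gv(pr$algarrobo_alive) >= 0.08)
    msg <- c(msg, "alive Algarrobo profile must have 0.03 < GV < 0.08")
  for (k in c("algarrobo_dead", "overo"))
    if (npv(pr[[k]]) <= 0.053)
      msg <- c(msg, sprintf("%s profile must have NPV > 0.053", k))
  if (gv(pr$background) > 0.03 || npv(pr$background) > 0.053)
    msg <- c(msg, "background profile must be below both vegetation thresholds")
  if (min(object@crownHeights$algarrobo_dead) <= 0.4)
    msg <- c(msg, "dead Algarrobo must be taller than 0.4 m")
  if (max(object@crownHeights$overo) >= 0.4)
    msg <- c(msg, "Overo must stay below 0.4 m")
  if (length(object@extent) != 2L || any(object@extent <= 0))
    msg <- c(msg, "extent must be two positive lengths")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (!all(.allClasses %in% names(object@counts)) || any(object@counts < 0))
    msg <- c(msg, "counts must name all four classes, non-negative")
  if (any(c(object@noiseSd, object@noiseSdDsm, object@sparseCloudFrac) < 0))
    msg <- c(msg, "noise and dropout parameters must be >= 0")
  for (cl in object@clusters) {
    if (!cl$class %in% .treeClasses)
      msg <- c(msg, "clusters are made of tree classes only")
    if (cl$size < 2L) msg <- c(msg, "a cluster needs at least 2 members")
  }
  for (k in .treeClasses) {
    want <- sum(vapply(object@clusters,
                       function(cl) if (cl$class == k) cl$size else 0L, 0L))
    if (want > object@counts[[k]])
      msg <- c(msg, sprintf("clustered %s exceed counts['%s']", k, k))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn generateScene Build a \linkS4class{SceneSpec} from defaults
#'   plus slot overrides (e.g. \code{counts =}, \code{noiseSd = 0},
#'   \code{rngSeed =}).
#' @param ... Slot overrides for \code{sceneSpec}.
#' @export
sceneSpec <- function(...) {
  over <- list(...)
  sp <- new("SceneSpec")
  for (nm in names(over)) {
    if (!nm %in% slotNames(sp)) stop("unknown SceneSpec slot: ", nm)
    v <- over[[nm]]
    if (nm == "counts") {
      cnt <- sp@counts
      cnt[names(v)] <- as.integer(v)
      v <- cnt
    }
    if (nm == "rngSeed") v <- as.integer(v)
    slot(sp, nm) <- v
  }
  validObject(sp)
  sp
}

# run expr under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# cosine canopy dome height at normalised radial position rho in [0, 1]
.dome <- function(h, rho) h * cos(pi / 2 * pmin(rho, 1))

#' Generate a labelled synthetic scene
#'
#' Renders bands, DEM/DSM and ground truth for a \linkS4class{SceneSpec}.
#' Alive and dead Algarrobo are k-lobed star polygons (k in 5..8), Sapote
#' are ellipses, Overo are chains of overlapping lobes along sinuous runnel
#' curves. Every crown carries a cosine canopy dome peaking at its centre,
#' so each green tree has a unique CHM maximum; dead crowns additionally
#' carry a radially decaying blue boost giving a unique interior NPV
#' maximum. Clusters are placed as tangent chains whose apices are separated
#' by more than the seed search range and mutually dominant within it, so
#' de-clustering is well posed. Deterministic given \code{rngSeed}.
#'
#' @param spec A \linkS4class{SceneSpec}.
#' @return List with \code{scene} (\linkS4class{SceneRaster}),
#'   \code{heights} (\linkS4class{HeightGrids}, CHM unset) and \code{truth}
#'   (\linkS4class{GroundTruth}).
#' @examples
#' out <- generateScene(sceneSpec(extent = c(30, 30),
#'   counts = c(sapote = 3, algarrobo_alive = 0, algarrobo_dead = 0,
#'              overo = 0),
#'   clusters = list(), noiseSd = 0, noiseSdDsm = 0, rngSeed = 7))
#' nrow(truthTrees(out$truth))
#' @export
generateScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  .withSeed(spec@rngSeed, .generateSceneImpl(spec))
}

.generateSceneImpl <- function(spec) {
  ps <- spec@pixelSize
  W <- spec@extent[1L]; H <- spec@extent[2L]
  nc <- as.integer(round(W / ps)); nr <- as.integer(round(H / ps))
  transform <- c(0, 0, ps)
  maxTry <- 800L

  trees <- data.frame(id = integer(), class = character(), x = numeric(),
                      y = numeric(), R = numeric(), h = numeric(),
                      ecc = numeric(), rot = numeric(), k = integer(),
                      phase = numeric(), cluster = integer(),
                      stringsAsFactors = FALSE)
  addTree <- function(df, class, x, y, R, h, cluster = 0L) {
    rbind(df, data.frame(id = nrow(df) + 1L, class = class, x = x, y = y,
                         R = R, h = h,
                         ecc = if (class == "sapote") runif(1, 0.75, 1) else 1,
                         rot = runif(1, 0, pi),
                         k = if (class == "sapote") 0L else sample(5:8, 1L),
                         phase = runif(1, 0, 2 * pi), cluster = cluster,
                         stringsAsFactors = FALSE))
  }
  farEnough <- function(df, x, y, R, sep = spec@minSeparation) {
    !nrow(df) ||
      all(sqrt((df$x - x)^2 + (df$y - y)^2) >= df$R + R + sep)
  }

  # tangent cluster chains; members must dominate their own seed window
  seedRangeM <- c(green = 50 * ps, npv = 20 * ps)
  for (ci in seq_along(spec@clusters)) {
    cl <- spec@clusters[[ci]]
    mode <- if (cl$class == "algarrobo_dead") "npv" else "green"
    rng <- spec@radii[[cl$class]]
    hrg <- spec@crownHeights[[cl$class]]
    placed <- FALSE
    for (tr in seq_len(maxTry)) {
      Rs <- runif(cl$size, rng[1L], rng[2L])
      hs <- runif(cl$size, hrg[1L], hrg[2L])
      xs <- ys <- numeric(cl$size)
      xs[1L] <- runif(1, max(Rs) + 1, W - max(Rs) - 1)
      ys[1L] <- runif(1, max(Rs) + 1, H - max(Rs) - 1)
      ang <- runif(1, 0, 2 * pi)
      ok <- TRUE
      for (m in seq(2L, length.out = cl$size - 1L)) {
        ang <- ang + runif(1, -pi / 6, pi / 6)
        step <- 0.70 * (Rs[m - 1L] + Rs[m])
        xs[m] <- xs[m - 1L] + step * cos(ang)
        ys[m] <- ys[m - 1L] + step * sin(ang)
      }
      if (any(xs < Rs + 1 | xs > W - Rs - 1 | ys < Rs + 1 | ys > H - Rs - 1))
        ok <- FALSE
      if (ok)
        for (m in seq_len(cl$size))
          if (!farEnough(trees, xs[m], ys[m], Rs[m])) { ok <- FALSE; break }
      if (ok && mode == "green") {
        # each apex must clear every sibling window (Chebyshev geometry)
        # and top every sibling dome reaching into its own window
        for (i in seq_len(cl$size)) {
          for (j in seq_len(cl$size)[-i]) {
            W0 <- seedRangeM[["green"]]
            adx <- abs(xs[i] - xs[j]); ady <- abs(ys[i] - ys[j])
            # distance from j's centre to the nearest point of i's window
            dmin <- sqrt(max(0, adx - W0)^2 + max(0, ady - W0)^2)
            if (max(adx, ady) <= W0 + 4 * ps ||
                hs[i] <= .dome(hs[j], dmin / Rs[j]) + 0.2) {
              ok <- FALSE; break
            }
          }
          if (!ok) break
        }
      }
      if (ok && mode == "npv") {
        for (i in seq_len(cl$size)) {
          cheb <- pmax(abs(xs[i] - xs[-i]), abs(ys[i] - ys[-i]))
          if (any(cheb <= seedRangeM[["npv"]] + 4 * ps)) { ok <- FALSE; break }
        }
      }
      if (ok) {
        for (m in seq_len(cl$size))
          trees <- addTree(trees, cl$class, xs[m], ys[m], Rs[m], hs[m], ci)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place cluster ", ci, " within the attempt budget")
  }

  # isolated trees
  for (class in .treeClasses) {
    nClustered <- sum(trees$class == class)
    nSingle <- spec@counts[[class]] - nClustered
    rng <- spec@radii[[class]]
    hrg <- spec@crownHeights[[class]]
    for (s in seq_len(max(0L, nSingle))) {
      done <- FALSE
      for (tr in seq_len(maxTry)) {
        R <- runif(1, rng[1L], rng[2L])
        x <- runif(1, R + 0.6, W - R - 0.6)
        y <- runif(1, R + 0.6, H - R - 0.6)
        if (farEnough(trees, x, y, R)) {
          trees <- addTree(trees, class, x, y, R,
                           runif(1, hrg[1L], hrg[2L]))
          done <- TRUE
          break
        }
      }
      if (!done)
        stop("could not place all requested ", class,
             " crowns within the attempt budget")
    }
  }

  # Overo: lobed patches along sinuous runnel polylines
  nOvero <- spec@counts[["overo"]]
  runnels <- list()
  if (nOvero > 0L) {
    for (rn in seq_len(max(1L, ceiling(nOvero / 3L)))) {
      x <- 0; y <- runif(1, 0.15 * H, 0.85 * H)
      ang <- runif(1, -pi / 8, pi / 8)
      pts <- matrix(c(x, y), ncol = 2L)
      while (x >= -2 && x <= W + 2 && y >= -2 && y <= H + 2) {
        ang <- ang + runif(1, -0.35, 0.35)
        x <- x + 2 * cos(ang); y <- y + 2 * sin(ang)
        pts <- rbind(pts, c(x, y))
      }
      runnels[[rn]] <- pts
    }
  }
  patches <- list()   # per patch: data.frame(x, y, r) of lobes
  hOv <- spec@crownHeights$overo
  for (p in seq_len(nOvero)) {
    done <- FALSE
    for (tr in seq_len(maxTry)) {
      if (tr <= maxTry / 2) {        # preferred habitat: along a runnel
        pts <- runnels[[sample.int(length(runnels), 1L)]]
        if (nrow(pts) < 8L) next
        at <- sample.int(nrow(pts) - 6L, 1L)
        seg <- pts[at:(at + 5L), , drop = FALSE]
      } else {                       # fall back to a free drifting chain
        x0 <- runif(1, 3, W - 3); y0 <- runif(1, 3, H - 3)
        ang0 <- runif(1, 0, 2 * pi)
        seg <- matrix(NA_real_, 6L, 2L)
        seg[1L, ] <- c(x0, y0)
        for (q in 2:6) {
          ang0 <- ang0 + runif(1, -0.35, 0.35)
          seg[q, ] <- seg[q - 1L, ] + 2 * c(cos(ang0), sin(ang0))
        }
      }
      r <- runif(1, spec@radii$overo[1L], spec@radii$overo[2L])
      lob <- data.frame(x = seg[, 1L], y = seg[, 2L],
                        r = r * runif(6L, 0.8, 1.2))
      if (any(lob$x < lob$r | lob$x > W - lob$r |
              lob$y < lob$r | lob$y > H - lob$r)) next
      ok <- all(vapply(seq_len(nrow(lob)), function(i)
        farEnough(trees, lob$x[i], lob$y[i], lob$r[i]), TRUE))
      if (ok && length(patches))
        for (q in patches) {
          dd <- outer(lob$x, q$x, `-`)^2 + outer(lob$y, q$y, `-`)^2
          rr <- outer(lob$r, q$r, `+`) + spec@minSeparation
          if (any(dd < rr^2)) { ok <- FALSE; break }
        }
      if (ok) {
        patches[[length(patches) + 1L]] <- lob
        trees <- rbind(trees, data.frame(
          id = nrow(trees) + 1L, class = "overo",
          x = mean(lob$x), y = mean(lob$y), R = max(lob$r),
          h = runif(1, hOv[1L], hOv[2L]), ecc = 1, rot = 0, k = 0L,
          phase = 0, cluster = 0L, stringsAsFactors = FALSE))
        done <- TRUE
        break
      }
    }
    if (!done)
      stop("could not place all requested overo patches within the attempt budget")
  }

  # ---- rasterise -----------------------------------------------------------
  prof <- spec@profiles
  blue <- matrix(prof$background[1L], nr, nc)
  green <- matrix(prof$background[2L], nr, nc)
  rededge <- matrix(prof$background[3L], nr, nc)
  masks <- matrix(0L, nr, nc)
  ownerDome <- matrix(0, nr, nc)
  ownerRho <- matrix(1, nr, nc)
  canopy <- matrix(0, nr, nc)
  xs <- .mapX(seq_len(nc), transform)
  ys <- .mapY(seq_len(nr), transform, nr)

  patchOf <- integer(0)
  if (length(patches))
    patchOf <- setNames(seq_along(patches),
                        trees$id[trees$class == "overo"])

  for (i in seq_len(nrow(trees))) {
    ti <- trees[i, ]
    if (ti$class == "overo") {
      lob <- patches[[patchOf[[as.character(ti$id)]]]]
      cs <- which(xs >= min(lob$x - lob$r) & xs <= max(lob$x + lob$r))
      rs <- which(ys >= min(lob$y - lob$r) & ys <= max(lob$y + lob$r))
      if (!length(cs) || !length(rs)) next
      dx <- outer(rep(1, length(rs)), xs[cs])
      dy <- outer(ys[rs], rep(1, length(cs)))
      rho <- matrix(Inf, length(rs), length(cs))
      for (q in seq_len(nrow(lob)))
        rho <- pmin(rho, sqrt((dx - lob$x[q])^2 + (dy - lob$y[q])^2) / lob$r[q])
    } else {
      cs <- which(xs >= ti$x - ti$R & xs <= ti$x + ti$R)
      rs <- which(ys >= ti$y - ti$R & ys <= ti$y + ti$R)
      if (!length(cs) || !length(rs)) next
      dx <- outer(rep(1, length(rs)), xs[cs]) - ti$x
      dy <- outer(ys[rs], rep(1, length(cs))) - ti$y
      if (ti$class == "sapote") {
        u <- cos(ti$rot) * dx + sin(ti$rot) * dy
        v <- -sin(ti$rot) * dx + cos(ti$rot) * dy
        rho <- sqrt((u / ti$R)^2 + (v / (ti$ecc * ti$R))^2)
      } else {
        d <- sqrt(dx^2 + dy^2)
        th <- atan2(dy, dx)
        rb <- ti$R * (0.70 + 0.30 * cos(ti$k * (th - ti$phase)))
        rho <- d / rb
      }
    }
    inside <- rho <= 1
    if (!any(inside)) next
    dome <- .dome(ti$h, rho)
    sub <- masks[rs, cs, drop = FALSE]
    subDome <- ownerDome[rs, cs, drop = FALSE]
    subRho <- ownerRho[rs, cs, drop = FALSE]
    take <- inside & dome > subDome
    sub[take] <- ti$id
    subDome[take] <- dome[take]
    subRho[take] <- rho[take]
    masks[rs, cs] <- sub
    ownerDome[rs, cs] <- subDome
    ownerRho[rs, cs] <- subRho
    cano <- canopy[rs, cs, drop = FALSE]
    cano[inside] <- pmax(cano[inside], dome[inside])
    canopy[rs, cs] <- cano
  }

  for (class in .allClasses) {
    ids <- trees$id[trees$class == class]
    if (!length(ids)) next
    sel <- masks %in% ids
    blue[sel] <- prof[[class]][1L]
    green[sel] <- prof[[class]][2L]
    rededge[sel] <- prof[[class]][3L]
    if (class %in% names(spec@blueBoost))
      blue[sel] <- blue[sel] + spec@blueBoost[[class]] * (1 - ownerRho[sel])
  }

  if (spec@noiseSd > 0) {
    blue <- pmax(blue + rnorm(nr * nc, 0, spec@noiseSd), 0)
    green <- pmax(green + rnorm(nr * nc, 0, spec@noiseSd), 0)
    rededge <- pmax(rededge + rnorm(nr * nc, 0, spec@noiseSd), 0)
  }

  dem <- outer(rep(1, nr), xs) * spec@demSlope[1L] +
    outer(ys, rep(1, nc)) * spec@demSlope[2L] + spec@demBase
  if (spec@sparseCloudFrac > 0) {
    deadIds <- trees$id[trees$class == "algarrobo_dead"]
    drop <- masks %in% deadIds & runif(nr * nc) < spec@sparseCloudFrac
    canopy[drop] <- 0
  }
  dsm <- dem + canopy
  if (spec@noiseSdDsm > 0)
    dsm <- dsm + rnorm(nr * nc, 0, spec@noiseSdDsm)

  scene <- new("SceneRaster", blue = blue, green = green, rededge = rededge,
               transform = transform, crsTag = "local", nodata = -9999)
  heights <- new("HeightGrids", dem = dem, dsm = dsm,
                 chm = matrix(NA_real_, nr, nc), transform = transform)

  areas <- tabulate(masks[masks > 0L], nbins = max(1L, nrow(trees)))
  species <- ifelse(trees$class == "sapote", "sapote",
                    ifelse(trees$class == "overo", "overo", "algarrobo"))
  health <- rep(NA_integer_, nrow(trees))
  health[trees$class == "algarrobo_alive"] <-
    sample(1:2, sum(trees$class == "algarrobo_alive"), replace = TRUE)
  health[trees$class == "algarrobo_dead"] <- 3L
  plots <- data.frame(plot_id = 1:4,
                      xmin = c(0, W / 2, 0, W / 2),
                      ymin = c(0, 0, H / 2, H / 2),
                      xmax = c(W / 2, W, W / 2, W),
                      ymax = c(H / 2, H / 2, H, H))
  inPlot <- function(x, y) {
    hit <- which(x >= plots$xmin & x < plots$xmax &
                   y >= plots$ymin & y < plots$ymax)
    if (length(hit)) hit[1L] else NA_integer_
  }
  truthTrees <- data.frame(
    id = trees$id, species = species, health_grade = health,
    crown_spread_m2 = areas[trees$id] * ps^2,
    x = trees$x, y = trees$y,
    plot_id = mapply(inPlot, trees$x, trees$y),
    cluster = trees$cluster, stringsAsFactors = FALSE)
  if (!nrow(trees))
    truthTrees <- truthTrees[0, , drop = FALSE]
  truth <- new("GroundTruth", trees = truthTrees, masks = masks,
               plots = plots, transform = transform)
  validObject(scene); validObject(heights); validObject(truth)
  list(scene = scene, heights = heights, truth = truth)
}

#' Reference counts per survey plot
#'
#' Applies the field protocol's filters to synthetic truth: only crowns
#' larger than 4 m2 count; Algarrobo of health grades 1-2 are alive and
#' grade 3 dead; Overo is tallied as present patches, not trees. A tree
#' outside every plot is counted nowhere.
#'
#' @param truth A \linkS4class{GroundTruth}.
#' @param plots Plot rectangles (default: the truth's own plots).
#' @param mmuM2 Minimum crown spread (m2, strictly greater; default 4).
#' @return Data frame with one row per plot and columns \code{sapote},
#'   \code{algarrobo_alive}, \code{algarrobo_dead}, \code{overo_patches}.
#' @export
truthPlotCounts <- function(truth, plots = truthPlots(truth), mmuM2 = 4) {
  tr <- truthTrees(truth)
  out <- data.frame(plot_id = plots$plot_id, sapote = 0L,
                    algarrobo_alive = 0L, algarrobo_dead = 0L,
                    overo_patches = 0L)
  if (!nrow(tr)) return(out)
  tr <- tr[tr$crown_spread_m2 > mmuM2, , drop = FALSE]
  lab <- .truthLabel(tr)
  for (p in seq_len(nrow(plots))) {
    sel <- tr$x >= plots$xmin[p] & tr$x < plots$xmax[p] &
      tr$y >= plots$ymin[p] & tr$y < plots$ymax[p]
    out$sapote[p] <- sum(sel & lab == "sapote")
    out$algarrobo_alive[p] <- sum(sel & lab == "algarrobo_alive")
    out$algarrobo_dead[p] <- sum(sel & lab == "algarrobo_dead")
    out$overo_patches[p] <- sum(sel & lab == "overo")
  }
  out
}

# truth species + health grade -> four-class label
.truthLabel <- function(tr) {
  ifelse(tr$species == "sapote", "sapote",
         ifelse(tr$species == "overo", "overo",
                ifelse(tr$species == "algarrobo" & tr$health_grade == 3L,
                       "algarrobo_dead", "algarrobo_alive")))
}
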
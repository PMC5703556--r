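## Levels 1 and 2 of the crown workflow: vegetation masking, isolated-tree
## vs tree-cluster routing, seed detection, region growing and contextual
## refinement. Object features are recombined exactly (pooled moments,
## perimeters minus shared borders) whenever objects merge, so none of the
## Level-1 operations need the pixel grids again.

# batch-merge table rows by group; groupOf maps each table row to a group
# key. The smallest member label survives; carry columns (anything outside
# the numeric feature set) are taken from repLabel if given, else from the
# surviving label's row. Returns the pooled table, the re-aggregated border
# table and the old->new label map.
.poolGroups <- function(tab, borders, groupOf, ps, repLabel = NULL) {
  groupOf <- as.character(groupOf)
  survivor <- tapply(tab$label, groupOf, min)
  map <- setNames(as.integer(survivor[groupOf]), tab$label)
  n <- tab$area_px
  grp <- factor(groupOf, levels = names(survivor))
  agg <- function(x) as.vector(rowsum(x, grp))
  nm <- agg(n)
  wmean <- function(col) agg(n * tab[[col]]) / nm
  out <- data.frame(label = as.integer(survivor), area_px = as.integer(nm),
                    area_m2 = nm * ps^2)
  for (band in c("blue", "green", "rededge")) {
    mu <- wmean(paste0("mean_", band))
    q <- agg(n * (tab[[paste0("sd_", band)]]^2 +
                    tab[[paste0("mean_", band)]]^2)) / nm
    out[[paste0("mean_", band)]] <- mu
    out[[paste0("sd_", band)]] <- sqrt(pmax(q - mu^2, 0))
  }
  out$mean_gv <- wmean("mean_gv")
  out$mean_npv <- wmean("mean_npv")
  muC <- wmean("mean_chm")
  qC <- agg(n * (tab$sd_chm^2 + tab$mean_chm^2)) / nm
  out$mean_chm <- muC
  out$max_chm <- as.vector(tapply(tab$max_chm, grp, max, na.rm = TRUE))
  out$sd_chm <- sqrt(pmax(qC - muC^2, 0))
  # internal borders vanish from the perimeter
  internal <- rep(0, length(survivor))
  names(internal) <- names(survivor)
  if (nrow(borders)) {
    ga <- groupOf[match(borders$a, tab$label)]
    gb <- groupOf[match(borders$b, tab$label)]
    int <- ga == gb
    if (any(int)) {
      s <- tapply(borders$edges[int], ga[int], sum)
      internal[names(s)] <- s
    }
  }
  out$perimeter_px <- agg(tab$perimeter_px) - 2 * internal
  out$roundness <- 1 - 4 * pi * out$area_px / out$perimeter_px^2
  out$rmin <- as.vector(tapply(tab$rmin, grp, min))
  out$rmax <- as.vector(tapply(tab$rmax, grp, max))
  out$cmin <- as.vector(tapply(tab$cmin, grp, min))
  out$cmax <- as.vector(tapply(tab$cmax, grp, max))
  out$centroid_x <- wmean("centroid_x")
  out$centroid_y <- wmean("centroid_y")
  carry <- setdiff(names(tab), names(out))
  ref <- if (is.null(repLabel)) out$label else
    as.integer(repLabel[names(survivor)])
  for (cc in carry) out[[cc]] <- tab[[cc]][match(ref, tab$label)]
  nb <- data.frame(a = integer(), b = integer(), edges = integer())
  if (nrow(borders)) {
    a2 <- map[as.character(borders$a)]
    b2 <- map[as.character(borders$b)]
    keep <- a2 != b2
    if (any(keep)) {
      lo <- pmin(a2[keep], b2[keep]); hi <- pmax(a2[keep], b2[keep])
      s <- rowsum(borders$edges[keep], paste(lo, hi))
      parts <- do.call(rbind, strsplit(rownames(s), " ", fixed = TRUE))
      nb <- data.frame(a = as.integer(parts[, 1L]),
                       b = as.integer(parts[, 2L]),
                       edges = as.integer(s))
      nb <- nb[order(nb$a, nb$b), , drop = FALSE]
    }
  }
  out <- out[order(out$label), , drop = FALSE]
  rownames(out) <- NULL
  list(table = out, borders = nb, map = map)
}

# tiny union-find over integer labels
.ufFind <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Level-1 vegetation masking
#'
#' Tags every object by its mean index values: non-photosynthetic
#' vegetation (NPV above the threshold), else green vegetation (GV above
#' its threshold), else background. Adjacent vegetation objects of the same
#' tag are merged; background objects fully enclosed by vegetation are
#' absorbed into the enclosing vegetation object (largest shared border);
#' vegetation objects below the minimum mapping unit are returned to
#' background. All features are recombined exactly.
#'
#' @param seg A \linkS4class{SegmentMap} with features computed.
#' @param cfg A \linkS4class{RuleConfig}.
#' @return The reworked \linkS4class{SegmentMap}; the \code{class} column is
#'   \code{"green"}, \code{"npv"} or \code{"background"}.
#' @export
maskVegetation <- function(seg, cfg = ruleConfig()) {
  tb <- seg@table
  if (!nrow(tb)) stop("feature table is empty; run computeFeatures first")
  tag <- ifelse(tb$mean_npv > cfg@npvThreshold, "npv",
                ifelse(tb$mean_gv > cfg@gdviThreshold, "green", "background"))
  K <- max(tb$label)
  tagOf <- rep(NA_character_, K)
  tagOf[tb$label] <- tag
  parent <- seq_len(K)
  link <- function(a, b) {
    ra <- .ufFind(parent, a); rb <- .ufFind(parent, b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  bo <- seg@borders
  for (i in seq_len(nrow(bo))) {
    ta <- tagOf[bo$a[i]]; tbg <- tagOf[bo$b[i]]
    if (!is.na(ta) && ta != "background" && identical(ta, tbg))
      link(bo$a[i], bo$b[i])
  }
  # enclosed background: a connected background component none of whose
  # objects touch the image edge/nodata and whose outside neighbours are all
  # vegetation is absorbed into the vegetation object sharing most border
  touched <- setNames(tb$perimeter_px, tb$label)
  if (nrow(bo)) {
    ext <- rowsum(c(bo$edges, bo$edges), c(bo$a, bo$b))
    touched[rownames(ext)] <- touched[rownames(ext)] - ext[, 1L]
  }
  bgParent <- seq_len(K)
  bgLink <- function(a, b) {
    ra <- .ufFind(bgParent, a); rb <- .ufFind(bgParent, b)
    if (ra != rb) bgParent[max(ra, rb)] <<- min(ra, rb)
  }
  for (i in seq_len(nrow(bo)))
    if (identical(tagOf[bo$a[i]], "background") &&
        identical(tagOf[bo$b[i]], "background"))
      bgLink(bo$a[i], bo$b[i])
  bgRoots <- vapply(tb$label[tag == "background"],
                    function(l) .ufFind(bgParent, l), 0L)
  names(bgRoots) <- tb$label[tag == "background"]
  if (length(bgRoots)) {
    comp <- split(as.integer(names(bgRoots)), bgRoots)
    for (members in comp) {
      if (any(touched[as.character(members)] > 0)) next    # reaches the edge
      outN <- bo[(bo$a %in% members) != (bo$b %in% members), , drop = FALSE]
      other <- ifelse(outN$a %in% members, outN$b, outN$a)
      if (!length(other)) next
      if (any(tagOf[other] == "background")) next          # shouldn't happen
      host <- other[which.max(outN$edges)]
      for (m in members) {
        tagOf[m] <- tagOf[host]
        link(m, host)
      }
    }
  }
  groupOf <- vapply(tb$label, function(l) .ufFind(parent, l), 0L)
  pool <- .poolGroups(tb, bo, groupOf, seg@transform[3L])
  newTab <- pool$table
  newTab$class <- tagOf[vapply(split(tb$label, as.character(groupOf)),
                               min, 0L)[as.character(newTab$label)]]
  small <- newTab$class != "background" & newTab$area_m2 < cfg@mmuM2
  newTab$class[small] <- "background"
  lut <- integer(K)
  lut[as.integer(names(pool$map))] <- pool$map
  labels <- seg@labels
  pos <- labels > 0L
  labels[pos] <- lut[labels[pos]]
  new("SegmentMap", labels = labels, table = newTab, borders = pool$borders,
      transform = seg@transform)
}

#' Split vegetation objects into isolated crowns and clusters
#'
#' A vegetation object is an isolated crown iff it is compact
#' (roundness below \code{roundnessMax}) and small (pixel area below
#' \code{clusterAreaMaxPx}); everything else is a tree cluster for Level-2
#' de-clustering.
#'
#' @param seg A \linkS4class{SegmentMap} from \code{\link{maskVegetation}}.
#' @param cfg A \linkS4class{RuleConfig}.
#' @return List with \code{isolated} (a \linkS4class{CrownSet}, provenance
#'   \code{"isolated"}) and \code{clusters} (a \linkS4class{SegmentMap}
#'   restricted to the cluster objects).
#' @export
splitIsolatedVsCluster <- function(seg, cfg = ruleConfig()) {
  tb <- seg@table
  veg <- tb$class %in% c("green", "npv")
  iso <- veg & tb$roundness < cfg@roundnessMax &
    tb$area_px < cfg@clusterAreaMaxPx
  clu <- veg & !iso
  isoTab <- tb[iso, , drop = FALSE]
  isoLabels <- seg@labels
  isoLabels[!(isoLabels %in% isoTab$label)] <- 0L
  isoTab$vegetation_kind <- rep(isoTab$class, length.out = nrow(isoTab))
  isoTab$provenance <- rep("isolated", nrow(isoTab))
  isoTab$class <- rep(NA_character_, nrow(isoTab))
  cluTab <- tb[clu, , drop = FALSE]
  cluLabels <- seg@labels
  cluLabels[!(cluLabels %in% cluTab$label)] <- 0L
  keep <- seg@borders$a %in% cluTab$label & seg@borders$b %in% cluTab$label
  list(isolated = new("CrownSet", labels = isoLabels, table = isoTab,
                      borders = data.frame(a = integer(), b = integer(),
                                           edges = integer()),
                      transform = seg@transform),
       clusters = new("SegmentMap", labels = cluLabels, table = cluTab,
                      borders = seg@borders[keep, , drop = FALSE],
                      transform = seg@transform))
}

#' Find crown seeds inside a cluster
#'
#' Local maxima of the guidance raster within the cluster footprint: the
#' NPV grid for non-photosynthetic clusters (search half-width
#' \code{seedRangeNpvPx}) or the CHM for green clusters (half-width
#' \code{seedRangeGvPx}). The guidance raster is first smoothed by a
#' mask-aware box mean of half-width \code{seedSmoothRadiusPx} (0 disables)
#' so that pixel noise cannot spawn spurious treetops. A pixel is a seed iff
#' it is the maximum of its window intersected with the cluster; on exact
#' plateaus the lexicographically first (row, col) pixel wins. In green mode
#' seeds falling on nodata CHM are dropped; NPV mode permits them, which is
#' the point of NPV seeding over sparse point clouds.
#'
#' @param clusterMask Logical matrix: the cluster footprint.
#' @param mode \code{"npv"} or \code{"green"}.
#' @param cfg A \linkS4class{RuleConfig}.
#' @param npv,chm The guidance grids (\linkS4class{IndexGrid} /
#'   \linkS4class{HeightGrids} or plain matrices); supply the one the mode
#'   needs.
#' @return Integer matrix with columns \code{row}, \code{col} (1-based).
#' @export
findSeeds <- function(clusterMask, mode = c("npv", "green"),
                      cfg = ruleConfig(), npv = NULL, chm = NULL) {
  mode <- match.arg(mode)
  if (!any(clusterMask)) stop("empty cluster")
  guide <- if (mode == "npv") {
    if (is(npv, "IndexGrid")) npv@values else npv
  } else {
    if (is(chm, "HeightGrids")) chm@chm else chm
  }
  if (is.null(guide)) stop("guidance grid for mode '", mode, "' is missing")
  range <- if (mode == "npv") cfg@seedRangeNpvPx else cfg@seedRangeGvPx
  sm <- .boxMeanMasked(guide, clusterMask, cfg@seedSmoothRadiusPx)
  seeds <- .cpp_local_maxima(sm, clusterMask, as.integer(range))
  if (mode == "green" && nrow(seeds)) {
    raw <- guide[seeds]
    seeds <- seeds[!is.na(raw), , drop = FALSE]
  }
  colnames(seeds) <- c("row", "col")
  seeds
}

#' Grow crowns from seeds
#'
#' Best-first region growing: repeatedly assign the unassigned cluster
#' pixel 4-adjacent to a region whose guiding value (NPV in npv mode, CHM
#' in green mode) differs least from that region's seed value. The result
#' partitions the cluster; regions below the minimum mapping unit are
#' merged into the neighbour with the longest shared border. With no seeds
#' the whole cluster is returned as one region, with a message.
#'
#' @inheritParams findSeeds
#' @param seeds Seed matrix from \code{\link{findSeeds}}.
#' @param pixelSizeM Pixel edge length (m), used for the minimum-mapping-
#'   unit absorption; inferred from \code{npv}/\code{chm} when those are
#'   package grid objects.
#' @return Integer matrix: 0 outside the cluster, region numbers 1..k
#'   inside (a partition of the cluster).
#' @export
growCrowns <- function(clusterMask, seeds, mode = c("npv", "green"),
                       cfg = ruleConfig(), npv = NULL, chm = NULL,
                       pixelSizeM = NULL) {
  mode <- match.arg(mode)
  if (!any(clusterMask)) stop("empty cluster")
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 2L)
  if (!nrow(seeds)) {
    message("cluster has no seeds; returning it as a single crown")
    return(clusterMask + 0L)
  }
  guide <- if (mode == "npv") {
    if (is(npv, "IndexGrid")) npv@values else npv
  } else {
    if (is(chm, "HeightGrids")) chm@chm else chm
  }
  if (is.null(pixelSizeM)) {
    if (is(npv, "IndexGrid")) pixelSizeM <- npv@transform[3L]
    else if (is(chm, "HeightGrids")) pixelSizeM <- chm@transform[3L]
  }
  seedVals <- guide[seeds[, 1:2, drop = FALSE]]
  seedVals[is.na(seedVals)] <- 0
  grown <- .cpp_grow(guide, clusterMask, seeds[, 1:2, drop = FALSE],
                     as.numeric(seedVals))
  if (!is.null(pixelSizeM))
    grown <- .absorbSmall(grown, cfg@mmuM2 / pixelSizeM^2)
  grown
}

# merge regions below minAreaPx into the neighbour with the longest shared
# border (ties: smaller neighbour label); repeats until stable
.absorbSmall <- function(lab, minAreaPx) {
  repeat {
    ids <- sort(unique(lab[lab > 0L]))
    if (length(ids) <= 1L) break
    n <- tabulate(lab[lab > 0L], max(ids))
    small <- ids[n[ids] < minAreaPx]
    if (!length(small)) break
    bo <- .borderTable(lab)
    target <- small[1L]
    cand <- bo[bo$a == target | bo$b == target, , drop = FALSE]
    if (!nrow(cand)) break
    other <- ifelse(cand$a == target, cand$b, cand$a)
    host <- other[order(-cand$edges, other)][1L]
    lab[lab == target] <- host
  }
  lab
}

#' Contextual refinement of crowns
#'
#' A crown whose relative border to its dominant neighbouring crown exceeds
#' \code{relBorderMergeMin}, where the two crowns are of different
#' vegetation kinds (the dead-branch / live-branch split of an infested
#' tree), is merged into that neighbour. The rule is applied in one pass,
#' largest relative border first; features are recombined exactly and the
#' surviving crown keeps the absorbing neighbour's kind.
#'
#' @param crownSet A \linkS4class{CrownSet} with borders computed.
#' @param cfg A \linkS4class{RuleConfig}.
#' @return The refined \linkS4class{CrownSet}.
#' @export
refineCrowns <- function(crownSet, cfg = ruleConfig()) {
  tb <- crownSet@table
  bo <- crownSet@borders
  if (!nrow(tb) || !nrow(bo)) return(crownSet)
  perim <- setNames(tb$perimeter_px, tb$label)
  kind <- setNames(tb$vegetation_kind, tb$label)
  cand <- rbind(
    data.frame(from = bo$a, to = bo$b, rel = bo$edges / perim[as.character(bo$a)]),
    data.frame(from = bo$b, to = bo$a, rel = bo$edges / perim[as.character(bo$b)]))
  # dominant neighbour of each crown
  cand <- cand[order(cand$from, -cand$rel, cand$to), , drop = FALSE]
  cand <- cand[!duplicated(cand$from), , drop = FALSE]
  cand <- cand[cand$rel > cfg@relBorderMergeMin &
                 kind[as.character(cand$from)] != kind[as.character(cand$to)], ,
               drop = FALSE]
  if (!nrow(cand)) return(crownSet)
  cand <- cand[order(-cand$rel, cand$from), , drop = FALSE]
  # group key = label of the absorbing crown; one pass, each crown at most
  # once on either side of a merge
  grp <- setNames(tb$label, as.character(tb$label))
  used <- setNames(logical(nrow(tb)), as.character(tb$label))
  for (i in seq_len(nrow(cand))) {
    f <- as.character(cand$from[i]); t <- as.character(cand$to[i])
    if (used[f] || used[t]) next
    grp[f] <- grp[t]
    used[f] <- TRUE; used[t] <- TRUE
  }
  groupOf <- grp[as.character(tb$label)]
  keys <- unique(as.character(groupOf))
  pool <- .poolGroups(tb, bo, groupOf, crownSet@transform[3L],
                      repLabel = setNames(as.integer(keys), keys))
  lut <- integer(max(tb$label))
  lut[as.integer(names(pool$map))] <- pool$map
  labels <- crownSet@labels
  pos <- labels > 0L
  labels[pos] <- lut[labels[pos]]
  new("CrownSet", labels = labels, table = pool$table,
      borders = pool$borders, transform = crownSet@transform)
}

#' Full crown delineation (Levels 1 and 2)
#'
#' Runs indices, CHM, segmentation, vegetation masking, the isolated /
#' cluster split, per-cluster seeding and region growing, and contextual
#' refinement, returning one object per tree crown with disjoint footprints
#' of at least the minimum mapping unit.
#'
#' @param scene A \linkS4class{SceneRaster}.
#' @param heights A \linkS4class{HeightGrids} (CHM computed if unset).
#' @param cfg A \linkS4class{RuleConfig}.
#' @param verbose Log stage progress to stderr.
#' @return A \linkS4class{CrownSet} (classes unset; see
#'   \code{\link{classifyAll}}).
#' @export
delineateCrowns <- function(scene, heights, cfg = ruleConfig(),
                            verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  heights <- computeCHM(heights)
  gv <- computeGV(scene)
  npv <- computeNPV(scene)
  say("segmenting ...")
  seg <- segmentScene(scene, heights, cfg)
  seg <- computeFeatures(seg, scene, heights, gv, npv)
  say(sprintf("  %d raw objects", nrow(seg@table)))
  vm <- maskVegetation(seg, cfg)
  spl <- splitIsolatedVsCluster(vm, cfg)
  say(sprintf("  %d isolated crowns, %d clusters",
              nrow(spl$isolated@table), nrow(spl$clusters@table)))
  crownLab <- spl$isolated@labels
  pos <- crownLab > 0L
  crownLab[pos] <- match(crownLab[pos], sort(unique(crownLab[pos])))
  nextId <- max(0L, crownLab)
  kindOf <- character(0)
  if (nrow(spl$isolated@table))
    kindOf <- spl$isolated@table$vegetation_kind[
      order(spl$isolated@table$label)]
  provOf <- rep("isolated", length(kindOf))
  for (i in seq_len(nrow(spl$clusters@table))) {
    row <- spl$clusters@table[i, ]
    mode <- if (row$class == "npv") "npv" else "green"
    mask <- spl$clusters@labels == row$label
    seeds <- findSeeds(mask, mode, cfg, npv = npv, chm = heights)
    grown <- if (nrow(seeds)) {
      growCrowns(mask, seeds, mode, cfg, npv = npv, chm = heights)
    } else {
      message("cluster ", row$label,
              " has no seeds; keeping it as a single crown")
      mask + 0L
    }
    ids <- sort(unique(grown[grown > 0L]))
    say(sprintf("  cluster %d (%s): %d seeds -> %d crowns",
                row$label, mode, nrow(seeds), length(ids)))
    for (g in ids) {
      nextId <- nextId + 1L
      crownLab[grown == g] <- nextId
      kindOf <- c(kindOf, row$class)
      provOf <- c(provOf, "declustered")
    }
  }
  if (!any(crownLab > 0L)) {
    return(new("CrownSet", labels = crownLab,
               table = data.frame(), transform = scene@transform))
  }
  tab <- .objectStats(crownLab, scene, heights, gv, npv, scene@transform)
  tab$vegetation_kind <- kindOf[tab$label]
  tab$provenance <- provOf[tab$label]
  tab$class <- NA_character_
  cs <- new("CrownSet", labels = crownLab, table = tab,
            borders = .borderTable(crownLab), transform = scene@transform)
  cs <- refineCrowns(cs, cfg)
  # the refinement merge can only grow crowns, but guard the MMU anyway
  keep <- cs@table$area_m2 >= cfg@mmuM2
  if (!all(keep)) {
    drop <- cs@table$label[!keep]
    cs@labels[cs@labels %in% drop] <- 0L
    cs@table <- cs@table[keep, , drop = FALSE]
    cs@borders <- cs@borders[!(cs@borders$a %in% drop |
                                 cs@borders$b %in% drop), , drop = FALSE]
  }
  # renumber ids 1..n for presentation
  old <- sort(cs@table$label)
  lut <- integer(max(old))
  lut[old] <- seq_along(old)
  pos <- cs@labels > 0L
  cs@labels[pos] <- lut[cs@labels[pos]]
  cs@table$label <- lut[cs@table$label]
  cs@table <- cs@table[order(cs@table$label), , drop = FALSE]
  names(cs@table)[names(cs@table) == "label"] <- "id"
  cs@table <- cbind(id = cs@table$id,
                    cs@table[setdiff(names(cs@table), "id")])
  if (nrow(cs@borders)) {
    cs@borders$a <- lut[cs@borders$a]
    cs@borders$b <- lut[cs@borders$b]
  }
  rownames(cs@table) <- NULL
  say(sprintf("  %d crowns after refinement", nrow(cs@table)))
  cs
}
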
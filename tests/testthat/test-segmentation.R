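test_that("a perfectly uniform image segments into a single object", {
  sc <- flatScene(30, 30, c(0.3, 0.3, 0.3))
  seg <- segmentScene(sc, flatHeights(30, 30), ruleConfig(segScale = 5))
  expect_identical(max(labelGrid(seg)), 1L)
  expect_true(all(labelGrid(seg) == 1L))
})

test_that("strong two-region and four-region images recover the exact partition,
           and no admissible cross-boundary merge remains (oracle)", {
  cfg <- ruleConfig(segScale = 5)
  h <- flatHeights(40, 40)
  # two homogeneous half-planes
  b <- matrix(0.1, 40, 40); b[, 21:40] <- 0.8
  sc <- bandScene(b)
  seg <- segmentScene(sc, h, cfg)
  lab <- labelGrid(seg)
  expect_identical(max(lab), 2L)
  expect_true(all(lab[, 1:20] == lab[1, 1]) && all(lab[, 21:40] == lab[1, 40]))
  layers <- list(sc@blue, sc@green, sc@rededge, matrix(0, 40, 40))
  cost <- oracleMergeCost(layers, rep(1, 4), lab == 1, lab == 2)
  expect_gte(cost, cfg@segScale^2)
  # checkerboard of four uniform quadrants
  b2 <- matrix(0.1, 40, 40)
  b2[1:20, 21:40] <- 0.5; b2[21:40, 1:20] <- 0.8; b2[21:40, 21:40] <- 0.3
  sc2 <- bandScene(b2)
  seg2 <- segmentScene(sc2, h, cfg)
  lab2 <- labelGrid(seg2)
  expect_identical(max(lab2), 4L)
  expect_true(all(table(lab2) == 400))
  layers2 <- list(sc2@blue, sc2@green, sc2@rededge, matrix(0, 40, 40))
  bt <- sharedBorders(computeFeatures(seg2, sc2, computeCHM(h),
                                      computeGV(sc2), computeNPV(sc2)))
  for (i in seq_len(nrow(bt))) {
    cst <- oracleMergeCost(layers2, rep(1, 4), lab2 == bt$a[i],
                           lab2 == bt$b[i])
    expect_gte(cst, cfg@segScale^2)
  }
})

test_that("object feature means match per-pixel accumulation on random partitions", {
  set.seed(21)
  for (rep in 1:5) {
    nr <- 25; nc <- 25
    # random rectangular patchwork of ~10 objects
    lab <- matrix(1L, nr, nc)
    nxt <- 1L
    for (k in 1:9) {
      r <- sort(sample.int(nr, 2)); cc <- sort(sample.int(nc, 2))
      nxt <- nxt + 1L
      lab[r[1]:r[2], cc[1]:cc[2]] <- nxt
    }
    # relabel connected components so the invariant (4-connected) holds
    lab <- relabelCC(lab)
    sc <- bandScene(matrix(runif(nr * nc), nr, nc),
                    matrix(runif(nr * nc), nr, nc),
                    matrix(runif(nr * nc), nr, nc))
    h <- computeCHM(flatHeights(nr, nc, dem = 0,
                                dsm = matrix(runif(nr * nc, 0, 5), nr, nc)))
    seg <- methods::new("SegmentMap", labels = lab, table = data.frame(),
                        borders = data.frame(a = integer(), b = integer(),
                                             edges = integer()),
                        transform = c(0, 0, 1))
    seg <- computeFeatures(seg, sc, h, computeGV(sc), computeNPV(sc))
    tb <- objectTable(seg)
    pick <- sample(tb$label, min(10, nrow(tb)))
    for (l in pick) {
      expect_equal(tb$mean_blue[tb$label == l], oracleMean(lab, sc@blue, l))
      expect_equal(tb$mean_gv[tb$label == l],
                   oracleMean(lab, indexValues(computeGV(sc)), l))
      expect_equal(tb$max_chm[tb$label == l], max(h@chm[lab == l]))
      expect_equal(tb$area_px[tb$label == l], sum(lab == l))
    }
  }
})

test_that("a rasterised disc has the ideal pixel-roundness of 1 - pi^2/16", {
  nr <- 201; nc <- 201
  d <- sqrt(outer((1:nr - 101)^2, (1:nc - 101)^2, `+`))
  lab <- matrix(0L, nr, nc)
  lab[d <= 80] <- 1L
  sc <- flatScene(nr, nc, c(0.2, 0.2, 0.2))
  seg <- methods::new("SegmentMap", labels = lab, table = data.frame(),
                      borders = data.frame(a = integer(), b = integer(),
                                           edges = integer()),
                      transform = c(0, 0, 1))
  seg <- computeFeatures(seg, sc, computeCHM(flatHeights(nr, nc)),
                         computeGV(sc), computeNPV(sc))
  # staircase perimeter of a convex footprint is 2(w + h) = 8r, so the
  # deviation-from-circle metric tends to 1 - 4*pi*(pi r^2)/(8r)^2
  expect_equal(objectTable(seg)$roundness[1], 1 - pi^2 / 16,
               tolerance = 0.05)
})

test_that("mergeObjects pools features exactly and validates adjacency", {
  b <- matrix(0.1, 20, 20); b[, 11:20] <- 0.8
  b[1:10, 1:10] <- 0.4
  sc <- bandScene(b)
  h <- computeCHM(flatHeights(20, 20, dsm = matrix(runif(400, 0, 2), 20, 20)))
  seg <- segmentScene(sc, h, ruleConfig(segScale = 4))
  seg <- computeFeatures(seg, sc, h, computeGV(sc), computeNPV(sc))
  tb <- objectTable(seg)
  expect_gte(nrow(tb), 3L)
  bo <- sharedBorders(seg)
  a <- bo$a[1]; bb <- bo$b[1]
  n1 <- tb$area_px[tb$label == a]; n2 <- tb$area_px[tb$label == bb]
  m <- mergeObjects(seg, a, bb)
  mt <- objectTable(m)
  row <- mt[mt$label == min(a, bb), ]
  expect_identical(row$area_px, n1 + n2)            # additivity
  expect_equal(row$mean_blue,
               oracleMean(labelGrid(m), sc@blue, min(a, bb)))
  expect_equal(row$sd_chm, {
    v <- h@chm[labelGrid(m) == min(a, bb)]
    sqrt(mean(v^2) - mean(v)^2)
  })
  expect_false(max(a, bb) %in% mt$label)            # merged label is gone
  expect_error(mergeObjects(m, a, bb), "unknown label")
  far <- setdiff(mt$label, c(min(a, bb),
                             c(m@borders$a[m@borders$a == min(a, bb) |
                                             m@borders$b == min(a, bb)],
                               m@borders$b[m@borders$a == min(a, bb) |
                                             m@borders$b == min(a, bb)])))
  if (length(far))
    expect_error(mergeObjects(m, min(a, bb), far[1]), "not adjacent")
})

test_that("segmentation is deterministic and label partitions are 4-connected", {
  set.seed(31)
  b <- matrix(0.2 + rnorm(2500, 0, 0.02), 50, 50)
  sc <- bandScene(b)
  h <- flatHeights(50, 50)
  s1 <- segmentScene(sc, h, ruleConfig(segScale = 10))
  s2 <- segmentScene(sc, h, ruleConfig(segScale = 10))
  expect_identical(labelGrid(s1), labelGrid(s2))
  # every object is one 4-connected component
  lab <- labelGrid(s1)
  for (l in unique(as.vector(lab))) {
    cc <- uavCrowns:::.cpp_cc_label(lab == l)
    expect_identical(max(cc), 1L)
  }
  # labels partition all valid pixels
  expect_true(all(lab > 0L))
})

test_that("increasing the scale parameter never increases the object count", {
  set.seed(41)
  b <- matrix(0.2 + rnorm(1600, 0, 0.05), 40, 40)
  b[11:30, 11:30] <- b[11:30, 11:30] + 0.3
  sc <- bandScene(b)
  h <- flatHeights(40, 40)
  counts <- vapply(c(3, 6, 10, 15, 25), function(s)
    max(labelGrid(segmentScene(sc, h, ruleConfig(segScale = s)))), 0L)
  expect_true(all(diff(counts) <= 0L))
})
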
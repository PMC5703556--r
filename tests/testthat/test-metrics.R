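test_that("the fishnet tiles the extent, flagging partial edge cells", {
  f1 <- makeFishnet(c(100, 100))
  expect_identical(nrow(f1), 4L)
  expect_true(all(!f1$partial))
  f2 <- makeFishnet(c(120, 100))
  expect_identical(nrow(f2), 6L)
  expect_identical(sum(f2$partial), 2L)
  # cells tile without overlap: areas sum to the extent, corners align
  expect_equal(sum((f2$xmax - f2$xmin) * (f2$ymax - f2$ymin)), 120 * 100)
  expect_error(makeFishnet(c(-5, 10)), "positive")
})

test_that("cell summaries count centroids exactly (exhaustive oracle) and
           conserve crown cover", {
  sim <- generateScene(sceneSpec(rngSeed = 15, noiseSd = 0, noiseSdDsm = 0))
  cm <- classifyAll(delineateCrowns(sim$scene, sim$heights))
  extent <- c(ncol(sim$scene@blue), nrow(sim$scene@blue)) *
    pixelSize(sim$scene)
  cells <- makeFishnet(extent)
  out <- summarizeCells(cm, cells)
  tb <- objectTable(cm)
  # exhaustive point-in-rectangle tally per cell and class
  for (ci in seq_len(nrow(cells))) {
    inCell <- tb$centroid_x >= cells$xmin[ci] &
      tb$centroid_x < cells$xmax[ci] &
      tb$centroid_y >= cells$ymin[ci] & tb$centroid_y < cells$ymax[ci]
    for (k in c("sapote", "overo", "algarrobo_alive", "algarrobo_dead"))
      expect_identical(out[[k]][ci], sum(inCell & tb$class == k))
    expect_identical(out$total_trees[ci],
                     sum(inCell & tb$class != "overo"))
  }
  # every centroid lands in exactly one cell
  expect_identical(sum(out$total_trees) + sum(out$overo),
                   nrow(tb))
  # clipping conserves area
  expect_equal(sum(out$crown_cover_m2), sum(tb$area_m2), tolerance = 1e-6)
})

test_that("per-cell mortality is dead over all Algarrobo, NA without any", {
  cells <- makeFishnet(c(100, 50))
  fake <- cells
  fake$algarrobo_alive <- c(3L, 0L)
  fake$algarrobo_dead <- c(1L, 0L)
  alg <- fake$algarrobo_alive + fake$algarrobo_dead
  pct <- ifelse(alg > 0, 100 * fake$algarrobo_dead / alg, NA_real_)
  expect_equal(pct, c(25, NA_real_))
})

test_that("area-wide densities and composition reproduce the published
           arithmetic from the adjusted counts", {
  d <- densitySummary(c(sapote = 784, algarrobo_alive = 1122,
                        algarrobo_dead = 601), areaHa = 80)
  expect_equal(round(d$total_per_ha, 1), 31.3)
  expect_equal(round(d$algarrobo_per_ha, 1), 21.5)
  expect_equal(round(d$perClass$per_ha, 1), c(9.8, 14.0, 7.5))
  expect_equal(round(d$pct_algarrobo), 69)
  expect_equal(round(d$pct_sapote), 31)
  expect_equal(round(d$pct_dead), 35)
  expect_error(densitySummary(c(sapote = 1, algarrobo_alive = 1,
                                algarrobo_dead = 1), areaHa = 0),
               "areaHa")
})

test_that("fishnet cells serialise to GeoJSON with their attributes", {
  dir <- withr::local_tempdir()
  cells <- makeFishnet(c(100, 100))
  cells$total_trees <- 1:4
  p <- file.path(dir, "cells.geojson")
  writeFishnet(cells, p)
  fc <- jsonlite::read_json(p)
  expect_identical(length(fc$features), 4L)
  expect_identical(fc$features[[2]]$properties$total_trees, 2L)
})
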
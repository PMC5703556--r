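test_that("a Sapote-only spec renders the requested trees with GV above the rule", {
  sim <- generateScene(sceneSpec(extent = c(40, 40),
    counts = c(sapote = 5, algarrobo_alive = 0, algarrobo_dead = 0,
               overo = 0),
    clusters = list(), noiseSd = 0, noiseSdDsm = 0, rngSeed = 7))
  tr <- truthTrees(sim$truth)
  expect_identical(nrow(tr), 5L)
  expect_true(all(tr$species == "sapote"))
  gv <- indexValues(computeGV(sim$scene))
  msk <- labelGrid(sim$truth)
  for (id in tr$id)
    expect_gt(mean(gv[msk == id]), 0.08)
})

test_that("generation is deterministic given the seed", {
  spec <- tinySpec(rngSeed = 9)
  a <- generateScene(spec)
  b <- generateScene(spec)
  expect_identical(a$scene@blue, b$scene@blue)
  expect_identical(a$heights@dsm, b$heights@dsm)
  expect_identical(truthTrees(a$truth), truthTrees(b$truth))
  c <- generateScene(tinySpec(rngSeed = 10))
  expect_false(identical(a$scene@blue, c$scene@blue))
})

test_that("an empty spec yields a background-only scene", {
  sim <- generateScene(sceneSpec(extent = c(20, 20),
    counts = c(sapote = 0, algarrobo_alive = 0, algarrobo_dead = 0,
               overo = 0),
    clusters = list(), noiseSd = 0, noiseSdDsm = 0, rngSeed = 1))
  expect_identical(nrow(truthTrees(sim$truth)), 0L)
  expect_true(all(labelGrid(sim$truth) == 0L))
  expect_equal(max(sim$scene@blue) - min(sim$scene@blue), 0)
})

test_that("rendered masks are disjoint and areas match the truth table", {
  sim <- generateScene(sceneSpec(rngSeed = 4, noiseSd = 0, noiseSdDsm = 0))
  tr <- truthTrees(sim$truth)
  msk <- labelGrid(sim$truth)
  areas <- table(msk[msk > 0])
  ps2 <- pixelSize(sim$scene)^2
  expect_equal(unname(areas[as.character(tr$id)]) * ps2,
               tr$crown_spread_m2, tolerance = 1e-12,
               ignore_attr = TRUE)
  # total rendered crown area equals the sum of per-tree mask areas
  expect_equal(sum(msk > 0) * ps2, sum(tr$crown_spread_m2))
})

test_that("noise-free class signatures respect every threshold ordering", {
  sim <- generateScene(sceneSpec(rngSeed = 2, noiseSd = 0, noiseSdDsm = 0))
  tr <- truthTrees(sim$truth)
  msk <- labelGrid(sim$truth)
  gv <- indexValues(computeGV(sim$scene))
  npv <- indexValues(computeNPV(sim$scene))
  chm <- computeCHM(sim$heights)@chm
  lab <- uavCrowns:::.truthLabel(tr)
  for (i in seq_len(nrow(tr))) {
    sel <- msk == tr$id[i]
    switch(lab[i],
      sapote = expect_gt(mean(gv[sel]), 0.08),
      algarrobo_alive = {
        expect_gt(mean(gv[sel]), 0.03)
        expect_lt(mean(gv[sel]), 0.08)
        expect_gt(max(chm[sel]), 0.4)
      },
      algarrobo_dead = {
        expect_gt(mean(npv[sel]), 0.053)
        expect_gt(max(chm[sel]), 0.4)
        expect_gt(sum(sel), 10000)      # large enough for the tree rule
      },
      overo = {
        expect_gt(mean(npv[sel]), 0.053)
        expect_lt(max(chm[sel]), 0.4)
      })
  }
  # background stays below both vegetation thresholds
  bg <- msk == 0
  expect_lt(mean(gv[bg]), 0.03)
  expect_lt(mean(npv[bg]), 0.053)
})

test_that("cluster members are tangent chains with well-separated apices", {
  sim <- generateScene(sceneSpec(rngSeed = 6, noiseSd = 0, noiseSdDsm = 0))
  tr <- truthTrees(sim$truth)
  for (ci in setdiff(unique(tr$cluster), 0L)) {
    mem <- tr[tr$cluster == ci, ]
    expect_gte(nrow(mem), 3L)
    # apices clear each other's seed search window (Chebyshev metric)
    rangePx <- if (mem$health_grade[1] %in% 3L) 20 else 50
    ps <- pixelSize(sim$scene)
    for (i in seq_len(nrow(mem) - 1)) {
      for (j in (i + 1):nrow(mem)) {
        cheb <- max(abs(mem$x[i] - mem$x[j]), abs(mem$y[i] - mem$y[j]))
        expect_gt(cheb, rangePx * ps)
      }
    }
  }
})

test_that("the sparse-point-cloud degradation knocks out dead-crown CHM", {
  spec <- sceneSpec(extent = c(60, 60),
    counts = c(sapote = 0, algarrobo_alive = 0, algarrobo_dead = 2,
               overo = 0),
    clusters = list(), noiseSd = 0, noiseSdDsm = 0,
    sparseCloudFrac = 0.5, rngSeed = 5)
  sim <- generateScene(spec)
  chm <- computeCHM(sim$heights)@chm
  msk <- labelGrid(sim$truth)
  dropped <- mean(chm[msk > 0] == 0)
  expect_gt(dropped, 0.3)
  expect_lt(dropped, 0.7)
  # off by default
  spec0 <- sceneSpec(extent = c(60, 60),
    counts = c(sapote = 0, algarrobo_alive = 0, algarrobo_dead = 2,
               overo = 0),
    clusters = list(), noiseSd = 0, noiseSdDsm = 0, rngSeed = 5)
  sim0 <- generateScene(spec0)
  chm0 <- computeCHM(sim0$heights)@chm
  expect_equal(mean(chm0[labelGrid(sim0$truth) > 0] == 0), 0)
})

test_that("plot counts apply the field filters", {
  # synthetic truth table assembled directly
  trees <- data.frame(
    id = 1:6,
    species = c("algarrobo", "algarrobo", "algarrobo", "sapote", "sapote",
                "overo"),
    health_grade = c(1L, 2L, 3L, NA, NA, NA),
    crown_spread_m2 = c(20, 15, 30, 3, 12, 8),
    x = c(10, 12, 14, 16, 18, 20), y = rep(10, 6),
    plot_id = 1L, cluster = 0L)
  masks <- matrix(0L, 5, 5)
  masks[1:6] <- 1:6          # minimal mask presence for validity
  truth <- methods::new("GroundTruth", trees = trees, masks = masks,
                        plots = data.frame(plot_id = 1L, xmin = 0, ymin = 0,
                                           xmax = 50, ymax = 50),
                        transform = c(0, 0, 1))
  counts <- truthPlotCounts(truth)
  expect_identical(counts$algarrobo_alive, 2L)  # health 1 and 2
  expect_identical(counts$algarrobo_dead, 1L)   # health 3
  expect_identical(counts$sapote, 1L)           # the 3 m2 crown is excluded
  expect_identical(counts$overo_patches, 1L)
  # a tree outside all plots is counted nowhere
  smallPlot <- data.frame(plot_id = 1L, xmin = 0, ymin = 0, xmax = 13,
                          ymax = 50)
  counts2 <- truthPlotCounts(truth, smallPlot)
  expect_identical(counts2$algarrobo_alive, 2L)
  expect_identical(counts2$algarrobo_dead, 0L)
  expect_identical(counts2$sapote, 0L)
})
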
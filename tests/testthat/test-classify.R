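mkFeat <- function(kind, gv = 0, npv = 0, area = 5000, chm = 1) {
  data.frame(mean_gv = gv, mean_npv = npv, area_px = area, max_chm = chm,
             mean_chm = chm / 2, vegetation_kind = kind)
}

test_that("the four-class rule set follows the printed thresholds", {
  cfg <- ruleConfig()
  expect_identical(classifyCrown(mkFeat("green", gv = 0.10), cfg), "sapote")
  expect_identical(classifyCrown(mkFeat("green", gv = 0.05), cfg),
                   "algarrobo_alive")
  expect_identical(classifyCrown(mkFeat("green", gv = 0.08), cfg), "sapote")
  expect_identical(
    classifyCrown(mkFeat("npv", npv = 0.1, area = 12000, chm = 1.2), cfg),
    "algarrobo_dead")
  expect_identical(
    classifyCrown(mkFeat("npv", npv = 0.1, area = 5000, chm = 0.2), cfg),
    "overo")
})

test_that("NPV crowns outside the printed quadrants fall back to the CHM
           test with a warning", {
  cfg <- ruleConfig()
  expect_warning(
    lab <- classifyCrown(mkFeat("npv", npv = 0.1, area = 5000, chm = 2), cfg),
    "printed rule quadrants")
  expect_identical(lab, "algarrobo_dead")        # small but tall -> tree
  expect_warning(
    lab2 <- classifyCrown(mkFeat("npv", npv = 0.1, area = 20000, chm = 0.1),
                          cfg),
    "printed rule quadrants")
  expect_identical(lab2, "overo")                # large but flat -> bush
})

test_that("the chm statistic used by the tree/bush rule is configurable", {
  f <- mkFeat("npv", npv = 0.1, area = 12000, chm = 1.2)  # mean_chm = 0.6
  f$mean_chm <- 0.2
  expect_identical(classifyCrown(f, ruleConfig()), "algarrobo_dead")
  expect_warning(
    lab <- classifyCrown(f, ruleConfig(chmStatistic = "mean")),
    "printed rule quadrants")
  expect_identical(lab, "overo")
  expect_error(classifyCrown(f[, 1:2], ruleConfig()), "missing crown features")
})

test_that("classifyAll tallies counts, excludes Overo from the tree count,
           and matches a brute-force tally", {
  sim <- generateScene(sceneSpec(extent = c(70, 70),
    counts = c(sapote = 3, algarrobo_alive = 2, algarrobo_dead = 1,
               overo = 2),
    clusters = list(), noiseSd = 0, noiseSdDsm = 0, rngSeed = 8))
  cm <- classifyAll(delineateCrowns(sim$scene, sim$heights))
  lab <- objectTable(cm)$class
  for (k in names(classCounts(cm)))
    expect_identical(classCounts(cm)[[k]], sum(lab == k))
  expect_identical(treeCount(cm), sum(lab != "overo"))
  expect_identical(sum(classCounts(cm)), length(lab))
  # pure function of features: same input, same labels, in any order
  tb <- objectTable(crowns(cm))
  perm <- sample(nrow(tb))
  expect_identical(classifyCrown(tb[perm, ], ruleConfig()), lab[perm])
})

test_that("an empty crown set classifies to an empty map", {
  empty <- methods::new("CrownSet", labels = matrix(0L, 3, 3),
                        table = data.frame(), transform = c(0, 0, 1))
  cm <- classifyAll(empty)
  expect_identical(sum(classCounts(cm)), 0L)
  expect_identical(treeCount(cm), 0L)
})
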
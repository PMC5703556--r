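test_that("detection rates divide classified by reference counts", {
  det <- detectionRates(
    c(sapote = 72, algarrobo_alive = 59, algarrobo_dead = 73),
    c(sapote = 76, algarrobo_alive = 51, algarrobo_dead = 87))
  expect_equal(det$rate_pct[det$class == "sapote"], 100 * 72 / 76)
  expect_equal(det$rate_pct[det$class == "total"], 100 * 204 / 214)
  expect_equal(det$difference, c(-4, 8, -14, -10))
  # identity: classified == reference -> 100% everywhere
  same <- detectionRates(c(sapote = 5, algarrobo_alive = 3,
                           algarrobo_dead = 2),
                         c(sapote = 5, algarrobo_alive = 3,
                           algarrobo_dead = 2))
  expect_true(all(same$rate_pct == 100))
  expect_error(detectionRates(c(sapote = 1), c(sapote = 0)),
               "zero reference")
  # per-plot rows are summed before comparison (plot-level, non-site-specific)
  cls <- data.frame(sapote = c(2, 3), algarrobo_alive = c(1, 1),
                    algarrobo_dead = c(0, 2))
  ref <- data.frame(sapote = c(2, 3), algarrobo_alive = c(1, 2),
                    algarrobo_dead = c(1, 1))
  det2 <- detectionRates(cls, ref)
  expect_equal(det2$classified[det2$class == "total"], 9)
  expect_equal(det2$reference[det2$class == "total"], 10)
})

test_that("count adjustment inverts the detection rate with half-up rounding", {
  adj <- adjustCounts(c(sapote = 743), c(sapote = 100 * 72 / 76))
  expect_equal(adj$adjusted, 784)
  adj2 <- adjustCounts(c(algarrobo_dead = 504),
                       c(algarrobo_dead = 100 * 73 / 87))
  expect_equal(adj2$adjusted, 601)
  expect_equal(adjustCounts(c(x = 55), c(x = 100))$adjusted, 55)
  expect_error(adjustCounts(c(x = 5), c(x = 0)), "rates must be > 0")
  # inverse property: adjusting the classified count by the rate recovers
  # the reference count (up to rounding)
  set.seed(5)
  for (i in 1:25) {
    ref <- sample(20:300, 1)
    cls <- sample(10:300, 1)
    rate <- 100 * cls / ref
    expect_equal(adjustCounts(c(k = cls), c(k = rate))$adjusted, ref)
  }
})

test_that("error matrices tally pairs in the fixed class order", {
  m <- buildErrorMatrix(rep("sapote", 3), rep("sapote", 3))
  expect_identical(m["sapote", "sapote"], 3L)
  expect_identical(sum(m), 3L)
  m0 <- buildErrorMatrix(character(0), character(0))
  expect_true(all(m0 == 0L))
  expect_identical(rownames(m0),
                   c("sapote", "overo", "algarrobo_alive", "algarrobo_dead"))
  expect_error(buildErrorMatrix("sapote", "ceiba"), "unknown label")
  expect_error(buildErrorMatrix(c("sapote", "overo"), "sapote"), "pair up")
})

test_that("matrix statistics: producer's, user's and overall accuracy", {
  m <- diag(c(5L, 3L, 2L, 4L))
  dimnames(m) <- list(classified = rownames(caseStudyTables()$errorMatrix),
                      reference = rownames(caseStudyTables()$errorMatrix))
  st <- matrixStats(m)
  expect_true(all(st$perClass$producers_pct == 100))
  expect_true(all(st$perClass$users_pct == 100))
  expect_equal(st$overall_pct, 100)
  # zero totals are undefined, not zero
  m2 <- m; m2[2, ] <- 0L; m2[, 2] <- 0L
  st2 <- matrixStats(m2)
  expect_true(is.na(st2$perClass$producers_pct[2]))
  expect_true(is.na(st2$perClass$users_pct[2]))
  expect_error(matrixStats(matrix(0L, 4, 4)), "empty")
})

test_that("overall accuracy is the count-weighted mean of user's accuracies
           (algebraic identity, random matrices)", {
  set.seed(13)
  for (i in 1:30) {
    m <- matrix(rpois(16, 8), 4, 4)
    if (sum(m) == 0) next
    st <- matrixStats(m)
    w <- rowSums(m) / sum(m)
    ua <- ifelse(rowSums(m) > 0, 100 * diag(m) / rowSums(m), 0)
    expect_equal(st$overall_pct, sum(w * ua))
  }
})

test_that("synthetic truth reduces to reference labels with the field filters", {
  trees <- data.frame(
    id = 1:5,
    species = c("algarrobo", "algarrobo", "algarrobo", "algarrobo", "sapote"),
    health_grade = c(1L, 2L, 3L, 3L, NA),
    crown_spread_m2 = c(20, 15, 30, 25, 3.5),
    x = 1:5, y = 1:5, plot_id = 1L, cluster = 0L)
  masks <- matrix(0L, 3, 3); masks[1:5] <- 1:5
  truth <- methods::new("GroundTruth", trees = trees, masks = masks,
                        plots = data.frame(plot_id = 1L, xmin = 0, ymin = 0,
                                           xmax = 10, ymax = 10),
                        transform = c(0, 0, 1))
  ref <- groundTruthReference(truth)
  expect_identical(ref$counts[["algarrobo_alive"]], 2L)
  expect_identical(ref$counts[["algarrobo_dead"]], 2L)
  expect_identical(ref$counts[["sapote"]], 0L)   # 3.5 m2 crown excluded
  # no algarrobo at all
  t2 <- trees[trees$species == "sapote", ]
  t2$crown_spread_m2 <- 10
  m2 <- matrix(0L, 2, 2); m2[1] <- 5L
  truth2 <- methods::new("GroundTruth", trees = t2, masks = m2,
                         plots = truth@plots, transform = c(0, 0, 1))
  ref2 <- groundTruthReference(truth2)
  expect_identical(ref2$counts[["algarrobo_alive"]], 0L)
  expect_identical(ref2$counts[["algarrobo_dead"]], 0L)
  expect_identical(ref2$counts[["sapote"]], 1L)
})

test_that("crowns match to truth by maximum footprint overlap", {
  sim <- generateScene(tinySpec(rngSeed = 21))
  cm <- classifyAll(delineateCrowns(sim$scene, sim$heights))
  mm <- matchCrownsToTruth(cm, sim$truth)
  expect_true(all(!is.na(mm$truth_id)))
  expect_identical(anyDuplicated(mm$truth_id), 0L)
  # each crown overlaps its matched tree more than any other tree
  lab <- labelGrid(crowns(cm))
  msk <- labelGrid(sim$truth)
  for (i in seq_len(nrow(mm))) {
    ov <- table(msk[lab == mm$crown_id[i] & msk > 0])
    expect_identical(as.integer(names(which.max(ov))), mm$truth_id[i])
  }
})
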
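test_that("GV and NPV compute the normalised band differences", {
  sc <- flatScene(4, 4, c(0.6, 0.2, 0.6))
  expect_equal(indexValues(computeGV(sc))[1, 1], 0.5)    # (0.6-0.2)/0.8
  expect_equal(indexValues(computeNPV(sc))[1, 1], 0.5)
  sc2 <- flatScene(4, 4, c(0, 0.3, 0.3))
  expect_equal(indexValues(computeGV(sc2))[1, 1], 0)     # RE == G
  expect_equal(indexValues(computeNPV(sc2))[1, 1], -1)   # B = 0
  sc3 <- flatScene(4, 4, c(0.5, 0, 0))
  expect_true(is.na(indexValues(computeGV(sc3))[1, 1]))  # RE + G = 0
})

test_that("indices propagate nodata and stay within [-1, 1] (antisymmetry)", {
  set.seed(11)
  b <- matrix(runif(400, 0, 0.5), 20, 20)
  g <- matrix(runif(400, 0, 0.5), 20, 20)
  re <- matrix(runif(400, 0, 0.5), 20, 20)
  b[1, 1] <- NA
  sc <- bandScene(b, g, re)
  gv <- indexValues(computeGV(sc))
  expect_true(is.na(computeNPV(sc)@values[1, 1]))
  expect_true(all(abs(gv) <= 1, na.rm = TRUE))
  # swapping the two bands negates the index
  swapped <- bandScene(b, re, g)
  expect_equal(indexValues(computeGV(swapped)), -gv)
})

test_that("the CHM is max(DSM - DEM, 0), idempotent and shape-checked", {
  h <- flatHeights(6, 6, dem = 100, dsm = 100)
  expect_true(all(computeCHM(h)@chm == 0))
  h@dsm[3, 4] <- 103
  h1 <- computeCHM(h)
  expect_equal(h1@chm[3, 4], 3)
  expect_equal(sum(h1@chm), 3)
  h@dsm[2, 2] <- 95                       # photogrammetric undershoot
  h2 <- computeCHM(h)
  expect_equal(h2@chm[2, 2], 0)
  expect_equal(computeCHM(h2)@chm, h2@chm)  # idempotent
  h@dem <- matrix(0, 3, 3)
  expect_error(computeCHM(h), "shapes differ")
})
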
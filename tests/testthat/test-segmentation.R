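# Deterministic toy section: dark disks at known centers on a bright
# background.
diskSection <- function(nr = 120, nc = 120, centers, r = 4, noise = 0.02,
                        seed = 1) {
  set.seed(seed)
  mask <- HistoDMRI:::rasterizeEllipses(nr, nc, centers[, 1], centers[, 2],
                                        rep(r, nrow(centers)),
                                        rep(1, nrow(centers)),
                                        rep(0, nrow(centers)))
  img <- matrix(0.85, nr, nc)
  img[mask] <- 0.25
  img <- pmin(pmax(img + rnorm(nr * nc, 0, noise), 0), 1)
  list(img = img, mask = mask)
}

gridCenters <- function(n, nr, spacing) {
  k <- ceiling(sqrt(n))
  xy <- expand.grid(x = seq(spacing / 2, by = spacing, length.out = k),
                    y = seq(spacing / 2, by = spacing, length.out = k))
  as.matrix(xy[seq_len(n), ])
}

test_that("a blank section yields an empty mask", {
  set.seed(25)
  img <- pmin(pmax(matrix(0.85 + rnorm(3600, 0, 0.02), 60, 60), 0), 1)
  cm <- segmentCells(img, segConfig(cellRadiusPx = 3))
  expect_equal(cm@nCells, 0L)
  expect_equal(sum(cm@binary), 0L)
  expect_warning(segmentCells(matrix(0.5, 10, 10)), "constant")
})

test_that("well-separated disks are counted and overlapped accurately", {
  d <- diskSection(centers = gridCenters(50, 120, 16), r = 4)
  cm <- segmentCells(d$img, segConfig(cellRadiusPx = 4))
  expect_equal(cm@nCells, 50L)
  expect_gte(dice(cm, d$mask), 0.95)
})

test_that("the polarity switch segments bright objects instead", {
  d <- diskSection(centers = gridCenters(20, 120, 24), r = 4)
  inv <- 1 - d$img
  cmDark <- segmentCells(d$img, segConfig(cellRadiusPx = 4))
  cmBright <- segmentCells(inv, segConfig(cellRadiusPx = 4,
                                          polarity = "bright"))
  expect_equal(cmBright@nCells, cmDark@nCells)
  expect_gte(dice(cmBright@binary, cmDark@binary), 0.99)
})

test_that("dice obeys its definition and edge conventions", {
  a <- matrix(FALSE, 10, 20); b <- a
  expect_equal(dice(a, b), 1)                     # both empty
  a[1:10, 1:10] <- TRUE
  b[1:10, 6:15] <- TRUE                           # overlap 50 of 100 each
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, b), dice(b, a))
  expect_equal(dice(a, a), 1)
  b2 <- matrix(FALSE, 10, 20); b2[1:10, 11:20] <- TRUE
  expect_equal(dice(a, b2), 0)                    # disjoint
  expect_error(dice(a, matrix(FALSE, 5, 5)), "shapes differ")
})

test_that("cell area density is an exact pixel fraction", {
  roi <- matrix(FALSE, 10, 20); roi[1:10, 1:10] <- TRUE
  mask <- matrix(FALSE, 10, 20)
  expect_equal(cellAreaDensity(mask, roi), 0)
  mask[1:10, 1:10] <- TRUE
  expect_equal(cellAreaDensity(mask, roi), 1)
  mask[,] <- FALSE; mask[1, 1:10] <- TRUE
  expect_equal(cellAreaDensity(mask, roi), 0.10)
  expect_error(cellAreaDensity(mask, matrix(FALSE, 10, 20)), "empty ROI")
})

test_that("density error is the absolute difference, averaged over samples", {
  expect_equal(densityError(0.20, 0.20), 0)
  expect_equal(densityError(0.25, 0.20), 0.05)
  auto <- c(0.21, 0.18, 0.25); manual <- c(0.20, 0.20, 0.20)
  expect_equal(mean(densityError(auto, manual)), mean(abs(auto - manual)))
  expect_error(densityError(1.2, 0.5), ">= 0")
})

test_that("segmentation density is invariant to global intensity rescaling", {
  d <- diskSection(centers = gridCenters(40, 120, 18), r = 4)
  cm1 <- segmentCells(d$img, segConfig(cellRadiusPx = 4))
  cm2 <- segmentCells(0.2 + 0.5 * d$img, segConfig(cellRadiusPx = 4))
  roi <- matrix(TRUE, 120, 120)
  expect_equal(cellAreaDensity(cm1, roi), cellAreaDensity(cm2, roi),
               tolerance = 0.005)
})

test_that("connectivity choice splits or joins diagonal neighbors", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_equal(max(labelComponents(m, 8L)), 1L)
  expect_equal(max(labelComponents(m, 4L)), 2L)
})

test_that("small components are removed by the min-area rule", {
  d <- diskSection(centers = gridCenters(9, 120, 36), r = 5, noise = 0)
  img <- d$img
  img[60, 110] <- 0.25                      # a single dark speck
  cm <- segmentCells(img, segConfig(cellRadiusPx = 5))
  expect_equal(cm@nCells, 9L)
  cm2 <- segmentCells(img, segConfig(cellRadiusPx = 5, minAreaPx = 0))
  expect_gte(cm2@nCells, 10L)
})

test_that("LoG edges outline cells without altering any mask", {
  d <- diskSection(centers = gridCenters(4, 80, 40), r = 6, noise = 0)
  e <- logEdges(d$img, sigma = 2)
  expect_true(any(e))
  expect_lt(mean(e), 0.2)   # edges are sparse contours, not regions
})
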
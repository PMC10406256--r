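test_that("heterogeneity reproduces the double-sum statistic exactly", {
  expect_equal(regionalHeterogeneity(c(0, 1)), 0.5)
  expect_equal(regionalHeterogeneity(c(1, 2, 3)), 8 / 9)
  expect_equal(regionalHeterogeneity(rep(4.2, 10)), 0)
  expect_true(is.na(regionalHeterogeneity(3)))
  expect_equal(regionalHeterogeneity(c(0, 1)),
               heterogeneityDoubleLoop(c(0, 1)))
  set.seed(26)
  for (i in 1:50) {
    x <- rnorm(sample(2:40, 1), sd = runif(1, 0.1, 10))
    expect_equal(regionalHeterogeneity(x), heterogeneityOuter(x),
                 tolerance = 1e-12)
  }
})

test_that("heterogeneity is translation invariant and homogeneous", {
  set.seed(27)
  for (i in 1:20) {
    x <- rnorm(sample(2:60, 1))
    a <- runif(1, -5, 5); c <- runif(1, -10, 10)
    expect_equal(regionalHeterogeneity(x + c), regionalHeterogeneity(x),
                 tolerance = 1e-12)
    expect_equal(regionalHeterogeneity(a * x),
                 abs(a) * regionalHeterogeneity(x), tolerance = 1e-12)
    # Gini-mean-difference bound against the population variance
    expect_lte(regionalHeterogeneity(x),
               2 * sqrt(HistoDMRI:::popVar(x)) + 1e-12)
  }
})

test_that("regional averages respect masks and flagged voxels", {
  vals <- array(NA_real_, c(3, 1, 1))
  vals[, 1, 1] <- c(1, NA, 3)
  lab <- labelVolume(array(1L, c(3, 1, 1)),
                     data.frame(label = 1, name = "r", class = "cortical"))
  m <- new("ScalarMap", values = vals, measure = "TR")
  expect_equal(regionalAverage(m, lab, 1), 2)          # NA excluded
  expect_equal(regionalAverage(m, lab, "r"), 2)
  vals[, 1, 1] <- c(7, 7, 7)
  expect_equal(regionalAverage(new("ScalarMap", values = vals,
                                   measure = "TR"), lab, 1), 7)
  empty <- new("ScalarMap", values = array(NA_real_, c(3, 1, 1)),
               measure = "TR")
  expect_warning(out <- regionalAverage(empty, lab, 1), "no valid voxels")
  expect_true(is.na(out))
})

test_that("grid densities follow their hand-computable cases", {
  # section of 2 x 1 grid squares (40 px at 20 um, grid 0.8 mm)
  img <- matrix(0.8, 40, 80)
  sec <- new("HistologySection", image = img, pixelSize = 20,
             roiMasks = list(roi = matrix(TRUE, 40, 80)))
  # mask identical to roi -> every square density 1, variance 0
  g <- gridCellAreaDensity(sec, matrix(TRUE, 40, 80))
  expect_equal(g$average, 1)
  expect_equal(g$heterogeneity, 0)
  expect_equal(g$nSquares, 2L)
  # densities {0.1, 0.3}: population variance 0.01
  mask <- matrix(FALSE, 40, 80)
  mask[1:40, 1:4] <- TRUE      # 160 of 1600 px in square 1 -> 0.1
  mask[1:40, 41:52] <- TRUE    # 480 of 1600 px in square 2 -> 0.3
  g2 <- gridCellAreaDensity(sec, mask)
  expect_equal(sort(g2$squareDensities), c(0.1, 0.3))
  expect_equal(g2$heterogeneity, 0.01)
  expect_equal(g2$average, (160 + 480) / 3200)   # whole-ROI fraction
  # fewer than 2 qualifying squares -> missing heterogeneity
  secSmall <- new("HistologySection", image = matrix(0.8, 40, 40),
                  pixelSize = 20,
                  roiMasks = list(roi = matrix(TRUE, 40, 40)))
  g3 <- gridCellAreaDensity(secSmall, matrix(TRUE, 40, 40))
  expect_true(is.na(g3$heterogeneity))
  expect_error(gridCellAreaDensity(sec, mask, gridMM = 0.02),
               "at least 2 px")
})

test_that("partial squares obey the coverage rule", {
  # ROI covers 1.5 grid squares; the partial square is 50% covered and
  # qualifies at the default threshold but not at a stricter one
  img <- matrix(0.8, 40, 60)
  roi <- matrix(FALSE, 40, 60); roi[, 1:60] <- TRUE
  sec <- new("HistologySection", image = img, pixelSize = 20,
             roiMasks = list(roi = roi))
  mask <- matrix(TRUE, 40, 60)
  g <- gridCellAreaDensity(sec, mask, coverage = 0.5)
  expect_equal(g$nSquares, 2L)
  g2 <- gridCellAreaDensity(sec, mask, coverage = 0.6)
  expect_equal(g2$nSquares, 1L)
})

test_that("summary assembly yields one row per subject, region and measure", {
  set.seed(28)
  gt <- smallProtocol()
  study <- generateStudy(nSubjects = 2,
                         regions = defaultRegionSpecs(meanCellRadius = 24,
                                                      sectionMM = 2.4)[1:3],
                         coupling = couplingSpec(kappa = 1, noiseSNR = 60),
                         gtab = gt, blockSize = c(3, 3, 2), pixelSize = 12,
                         seed = 29)
  res <- runStudyPipeline(study)
  expect_s4_class(res$summary, "RegionalSummary")
  expect_equal(nrow(res$summary), 2 * 3 * 5)
  expect_true(all(res$summary$n >= 2))
  expect_true(all(is.finite(res$summary$average)))
  # a region absent from the labels is flagged but does not stop the run
  maps <- list(`sub-01` = res$maps$`sub-01`)
  lab <- study$subjects$`sub-01`$labels
  lab@labels[lab@labels == 3L] <- 0L
  hist1 <- lapply(study$subjects$`sub-01`$histology, function(h)
    list(section = h$section, mask = segmentCells(h$section,
                                                  segConfig(cellRadiusPx = 2))))
  sm <- buildSummary(maps, list(`sub-01` = lab),
                     list(`sub-01` = hist1), gridMM = 0.8)
  r3 <- sm[sm$region == regionTable(lab)$name[3] & sm$measure != "CAD", ]
  expect_true(all(is.na(r3$average)))
})
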
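test_that("pearson matches the covariance formula and exact t p-value", {
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  res <- pearsonCorr(x, y)
  expect_equal(res$r, 0.6)
  tStat <- 0.6 * sqrt(2 / (1 - 0.36))
  expect_equal(res$p, 2 * stats::pt(-tStat, df = 2), tolerance = 1e-12)

  expect_equal(pearsonCorr(1:5, 2 * (1:5) + 1)$r, 1)
  expect_lt(pearsonCorr(1:20, 2 * (1:20) + 1)$p, 1e-12)
  expect_equal(pearsonCorr(1:5, -(1:5))$r, -1)
  expect_error(pearsonCorr(rep(1, 5), 1:5), "constant")
  expect_error(pearsonCorr(1:2, 1:2), "at least 3")

  set.seed(30)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    r <- cov(x, y) / (sd(x) * sd(y))
    expect_equal(pearsonCorr(x, y)$r, r, tolerance = 1e-12)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    expect_equal(pearsonCorr(x, y)$p, 2 * pt(-abs(tt), n - 2),
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment reproduces the hand-enumerated step-up", {
  expect_equal(fdrBH(0.03), 0.03)
  expect_equal(fdrBH(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(fdrBH(rep(0.2, 5)), rep(0.2, 5))
  expect_error(fdrBH(c(0.1, 1.2)), "\\[0, 1\\]")

  base <- c(0.005, 0.01, 0.04, 0.2)
  for (k in 1:4) {
    combos <- combn(4, k)
    for (j in seq_len(ncol(combos))) {
      p <- base[combos[, j]]
      q <- fdrBH(p)
      expect_equal(q, bhStepUp(p))
      expect_true(all(q >= p - 1e-15) && all(q <= 1))
      # thresholding q reproduces the step-up rejection set
      for (alpha in c(0.01, 0.05, 0.1)) {
        m <- length(p)
        ps <- sort(p)
        kmax <- suppressWarnings(max(which(ps <= seq_len(m) / m * alpha)))
        rejected <- if (is.finite(kmax)) p <= ps[kmax] else rep(FALSE, m)
        expect_equal(q <= alpha, rejected)
      }
    }
  }
})

test_that("the OLS confidence band behaves like the textbook band", {
  x <- c(0, 1, 2, 4); y <- c(1, 3, 4, 9)
  fit <- linearFitWithBand(x, y)
  # normal equations by hand: slope = Sxy/Sxx, intercept = ybar - b xbar
  sxy <- sum((x - mean(x)) * (y - mean(y))); sxx <- sum((x - mean(x))^2)
  expect_equal(fit$slope, sxy / sxx, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(y) - sxy / sxx * mean(x),
               tolerance = 1e-12)
  # exact linear data -> zero-width band
  fit0 <- linearFitWithBand(c(1, 2, 3, 4), c(3, 5, 7, 9))
  expect_equal(max(fit0$grid$halfWidth), 0, tolerance = 1e-9)
  # band is narrowest at the mean of x
  set.seed(31)
  x <- runif(20); y <- 2 * x + rnorm(20, 0, 0.3)
  fit2 <- linearFitWithBand(x, y, gridN = 200)
  xmin <- fit2$grid$x[which.min(fit2$grid$halfWidth)]
  expect_lt(abs(xmin - mean(x)), diff(range(x)) / 50)
  expect_error(linearFitWithBand(rep(2, 5), rnorm(5)), "degenerate")
})

test_that("the study correlation design produces the expected families", {
  tab <- toySummary(nSubj = 4, regions = letters[1:6],
                    classes = rep(c("cortical", "subcortical"), each = 3))
  res <- runStudyCorrelations(tab)
  expect_equal(nrow(res), 3 * 4 + 2 * 4)
  expect_setequal(unique(res$group),
                  c("het-all", "het-cortical", "het-subcortical",
                    "avg-cortical", "avg-subcortical"))
  expect_true(all(res$n[res$group == "het-all"] == 24))
  expect_true(all(res$n[res$group == "avg-cortical"] == 12))
  # q-values are BH within each family
  for (g in unique(res$group)) {
    sel <- res$group == g
    expect_equal(res$q[sel], fdrBH(res$p[sel]))
  }
  resG <- runStudyCorrelations(tab, fdrScope = "global")
  expect_equal(resG$q, fdrBH(resG$p))
  # duplicated rows are rejected by the one-row-per-key invariant
  dup <- rbind(as(tab, "data.frame"), as(tab, "data.frame")[1, ])
  expect_error(regionalSummary(dup), "one row per")
})

test_that("the volume-effect check detects planted effects and rejects constants", {
  tab <- toySummary(nSubj = 3, regions = c("a", "b", "c"))
  vols <- expand.grid(subject = sprintf("s%d", 1:3),
                      region = c("a", "b", "c"),
                      stringsAsFactors = FALSE)
  vols$voxels <- 50
  expect_error(volumeEffectCheck(tab, vols), "not testable")
  # plant a linear dependence of average CAD on volume
  vols$voxels <- seq_len(nrow(vols)) * 10
  tab2 <- as(tab, "data.frame")
  key <- paste(tab2$subject, tab2$region)
  vkey <- paste(vols$subject, vols$region)
  tab2$average[tab2$measure == "CAD"] <-
    0.001 * vols$voxels[match(key[tab2$measure == "CAD"], vkey)]
  res <- volumeEffectCheck(regionalSummary(tab2), vols)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$n, 9)
})

test_that("correlation scatter plots are written to disk", {
  tmp <- withr::local_tempdir()
  set.seed(32)
  x <- runif(12); y <- x + rnorm(12, 0, 0.2)
  path <- file.path(tmp, "scatter.png")
  plotCorrelation(x, y, rep(letters[1:3], 4), path)
  expect_true(file.exists(path) && file.info(path)$size > 0)
})
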
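signalFromTensor <- function(D, gtab, S0 = 100) {
  b <- bvals(gtab); g <- bvecs(gtab)
  S0 * exp(-b * rowSums((g %*% D) * g))
}

test_that("noise-free tensors are recovered to numerical precision", {
  gt <- studyProtocol(nB0 = 3, dirsPerShell = 15)
  # isotropic
  D <- diag(3) * 1e-3
  vol <- diffusionVolume(array(signalFromTensor(D, gt), c(1, 1, 1, length(gt))), gt)
  fit <- fitDTI(vol)
  expect_equal(fit$eigenvalues[1, 1, 1, ], rep(1e-3, 3), tolerance = 1e-10)
  # anisotropic
  D <- diag(c(1.7, 0.3, 0.3)) * 1e-3
  vol <- diffusionVolume(array(signalFromTensor(D, gt), c(1, 1, 1, length(gt))), gt)
  fit <- fitDTI(vol)
  expect_equal(fit$eigenvalues[1, 1, 1, ], c(1.7, 0.3, 0.3) * 1e-3,
               tolerance = 1e-8)
  expect_equal(fit$S0[1, 1, 1], 100, tolerance = 1e-8)
})

test_that("the fit uses only the b <= 1000 shells and needs both b0 and DWIs", {
  gt0 <- gradientTable(rep(0, 8), matrix(0, 8, 3))
  vol0 <- diffusionVolume(array(100, c(1, 1, 1, 8)), gt0)
  expect_error(fitDTI(vol0), "diffusion-weighted")

  # altering the b = 3000 shell must not change the DTI fit
  gt <- studyProtocol(nB0 = 3, dirsPerShell = 10)
  D <- diag(c(1.2, 0.5, 0.4)) * 1e-3
  s <- signalFromTensor(D, gt)
  s2 <- s; s2[bvals(gt) > 1500] <- s2[bvals(gt) > 1500] * 5
  f1 <- fitDTI(diffusionVolume(array(s, c(1, 1, 1, length(gt))), gt))
  f2 <- fitDTI(diffusionVolume(array(s2, c(1, 1, 1, length(gt))), gt))
  expect_identical(f1$tensor, f2$tensor)
})

test_that("invalid voxels are flagged and excluded", {
  gt <- studyProtocol(nB0 = 2, dirsPerShell = 8)
  arr <- array(0, c(2, 1, 1, length(gt)))
  arr[1, 1, 1, ] <- signalFromTensor(diag(3) * 1e-3, gt)
  vol <- diffusionVolume(arr, gt)
  fit <- fitDTI(vol)
  expect_true(fit$valid[1, 1, 1])
  expect_false(fit$valid[2, 1, 1])   # all-zero voxel
  maps <- dtiScalarMaps(fit)
  expect_true(is.na(mapValues(maps$TR)[2, 1, 1]))
  lab <- labelVolume(array(1L, c(2, 1, 1)),
                     data.frame(label = 1, name = "r", class = "cortical"))
  expect_equal(regionalAverage(maps$TR, lab, 1),
               traceMeasure(fit$eigenvalues[1, 1, 1, ]))
})

test_that("fa matches its closed form on canonical eigenvalue sets", {
  d <- 1.4e-3
  expect_equal(fa(c(d, d, d)), 0)
  expect_equal(fa(c(d, 0, 0)), 1)
  expect_equal(fa(c(2, 1, 1)), 1 / sqrt(6))
  expect_equal(fa(c(0, 0, 0)), 0)      # all-zero convention
  m <- rbind(c(2, 1, 1), c(3, 3, 3))
  expect_equal(fa(m), c(1 / sqrt(6), 0))
})

test_that("trace is the eigenvalue sum and rotation invariant", {
  expect_equal(traceMeasure(c(1, 2, 3) * 1e-3), 6e-3)
  expect_equal(traceMeasure(c(0, 0, 0)), 0)
  set.seed(15)
  gt <- studyProtocol(nB0 = 3, dirsPerShell = 12)
  lam <- c(1.5, 0.7, 0.2) * 1e-3
  base <- NULL
  for (i in 1:5) {
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    D <- R %*% diag(lam) %*% t(R)
    fit <- fitDTI(diffusionVolume(array(signalFromTensor(D, gt),
                                        c(1, 1, 1, length(gt))), gt))
    tr <- traceMeasure(fit$eigenvalues[1, 1, 1, ])
    fav <- fa(fit$eigenvalues[1, 1, 1, ])
    if (is.null(base)) base <- c(tr, fav)
    expect_equal(c(tr, fav), base, tolerance = 1e-8)
  }
  expect_equal(base[1], sum(lam), tolerance = 1e-8)
})

test_that("clamped fits keep FA inside [0, 1]", {
  set.seed(16)
  gt <- studyProtocol(nB0 = 3, dirsPerShell = 10)
  s <- signalFromTensor(diag(c(0.25, 0.2, 0.02)) * 1e-3, gt)
  noisy <- pmax(s + rnorm(length(s), 0, 6), 1)  # drives eigenvalues negative
  fit <- fitDTI(diffusionVolume(array(noisy, c(1, 1, 1, length(gt))), gt))
  lam <- fit$eigenvalues[1, 1, 1, ]
  expect_true(all(lam >= 0))
  expect_true(fa(lam) >= 0 && fa(lam) <= 1)
})
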
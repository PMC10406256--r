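test_that("the forward model obeys normalization, nesting and closed form", {
  gt <- smallProtocol()
  p <- randomBiexpParams()
  s <- predictSignal(p, gt)
  expect_equal(s[bvals(gt) == 0], rep(p@S0, sum(bvals(gt) == 0)))

  # mono-exponential nesting: w = 1, fIso = 0, isotropic fast tensor
  d <- 0.9e-3
  pm <- biexpParams(S0 = 200, fIso = 0, w = 1, lambdaFast = rep(d, 3),
                    lambdaSlow = rep(d / 4, 3))
  expect_equal(predictSignal(pm, gt), 200 * 1 * exp(-bvals(gt) * d),
               tolerance = 1e-12)

  # scalar hand evaluation at b = 1000, g = (1, 0, 0)
  gt1 <- gradientTable(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
  ph <- biexpParams(S0 = 100, fIso = 0.1, w = 0.6,
                    lambdaFast = c(1.5, 1.0, 0.8) * 1e-3,
                    lambdaSlow = c(0.4, 0.3, 0.2) * 1e-3)
  hand <- 100 * (0.1 * exp(-1000 * 3e-3) +
                   0.9 * (0.6 * exp(-1000 * 1.5e-3) +
                            0.4 * exp(-1000 * 0.4e-3)))
  expect_equal(predictSignal(ph, gt1)[2], hand, tolerance = 1e-12)
})

test_that("msd follows the propagator second moment", {
  d <- 1.1e-3; tau <- 0.030
  p1 <- biexpParams(S0 = 1, fIso = 0, w = 1, lambdaFast = rep(d, 3),
                    lambdaSlow = rep(d / 4, 3), tau = tau)
  expect_equal(msd(p1), 6 * d * tau)
  set.seed(17)
  expect_lt(abs(msdMonteCarlo(1, rep(d, 3), rep(d, 3), tau, n = 2e5) -
                  6 * d * tau) / (6 * d * tau), 0.01)

  # mixture linearity
  p <- randomBiexpParams()
  pf <- biexpParams(p@S0, 0, 1, p@lambdaFast, p@lambdaFast / 10,
                    frame = p@frame, tau = p@tau)
  ps <- biexpParams(p@S0, 0, 1, p@lambdaSlow, p@lambdaSlow / 10,
                    frame = p@frame, tau = p@tau)
  expect_equal(msd(p), p@w * msd(pf) + (1 - p@w) * msd(ps),
               tolerance = 1e-12)

  pz <- biexpParams(1, 0, 0.5, rep(0, 3), rep(0, 3))
  expect_equal(msd(pz), 0)
})

test_that("rtop follows the zero-displacement propagator value", {
  d <- 0.8e-3; tau <- 0.030
  p1 <- biexpParams(S0 = 1, fIso = 0, w = 1, lambdaFast = rep(d, 3),
                    lambdaSlow = rep(d / 4, 3), tau = tau)
  pOnly <- biexpParams(S0 = 1, fIso = 0, w = 1, lambdaFast = rep(d, 3),
                       lambdaSlow = rep(d, 3), tau = tau)
  expect_equal(rtop(pOnly), (4 * pi * d * tau)^(-1.5), tolerance = 1e-12)
  expect_equal(rtop(pOnly), rtopQuadrature(rep(d, 3), tau),
               tolerance = 5e-3)

  # monotone decreasing in diffusivity
  p2 <- biexpParams(S0 = 1, fIso = 0, w = 1, lambdaFast = rep(2 * d, 3),
                    lambdaSlow = rep(2 * d, 3), tau = tau)
  expect_lt(rtop(p2), rtop(pOnly))

  # mixture value sits between the pure-compartment values
  p <- randomBiexpParams()
  rf <- (4 * pi * p@tau)^(-1.5) / sqrt(prod(p@lambdaFast))
  rs <- (4 * pi * p@tau)^(-1.5) / sqrt(prod(p@lambdaSlow))
  expect_true(rtop(p) >= min(rf, rs) && rtop(p) <= max(rf, rs))

  pz <- biexpParams(1, 0, 0.5, c(1e-3, 1e-3, 0), rep(0, 3))
  expect_true(is.na(rtop(pz)))
})

test_that("msd and rtop are rotation invariant", {
  set.seed(18)
  lamF <- c(1.8, 0.9, 0.6) * 1e-3; lamS <- c(0.5, 0.25, 0.15) * 1e-3
  vals <- t(replicate(5, {
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    p <- biexpParams(100, 0.1, 0.6, lamF, lamS, frame = R)
    c(msd(p), rtop(p))
  }))
  expect_equal(max(vals[, 1]) - min(vals[, 1]), 0, tolerance = 1e-15)
  expect_equal(max(vals[, 2]) - min(vals[, 2]), 0, tolerance = 1e-6)
})

test_that("noise-free signals are inverted to the generating parameters", {
  set.seed(19)
  gt <- studyProtocol(nB0 = 3, dirsPerShell = 20)
  for (i in 1:6) {
    p <- randomBiexpParams()
    # keep the compartments separated enough to be identifiable
    if (mean(p@lambdaFast) < 3 * mean(p@lambdaSlow)) next
    f <- fitBiexpVoxel(predictSignal(p, gt), gt,
                       biexpConfig(dIso = p@dIso, tau = p@tau))
    expect_equal(f$params@w, p@w, tolerance = 0.02)
    expect_equal(mean(f$params@lambdaFast), mean(p@lambdaFast),
                 tolerance = mean(p@lambdaFast) * 0.01)
    expect_equal(mean(f$params@lambdaSlow), mean(p@lambdaSlow),
                 tolerance = mean(p@lambdaSlow) * 0.02)
    expect_equal(f$params@fIso, p@fIso, tolerance = 0.01)
  }
})

test_that("fit preconditions and relabeling hold", {
  gt1 <- gradientTable(c(0, 0, rep(1000, 6)),
                       rbind(matrix(0, 2, 3), diag(3), -diag(3)))
  expect_error(fitBiexpVoxel(rep(100, 8), gt1, biexpConfig()),
               "3 distinct nonzero shells")
  # relabeling: a slow-labeled compartment with larger MD gets swapped
  p <- biexpParams(100, 0, 0.3, lambdaFast = rep(0.2e-3, 3),
                   lambdaSlow = rep(1.5e-3, 3))
  expect_gte(mean(p@lambdaFast), mean(p@lambdaSlow))
  expect_equal(p@w, 0.7)
})

test_that("volume-level fits populate maps and per-voxel parameters", {
  set.seed(20)
  gt <- smallProtocol()
  cp <- couplingSpec(kappa = 0, noiseSNR = 200)
  sp <- regionSpec("r", "cortical", targetDensity = 0.15)
  dr <- generateDiffusionRegion(sp, cp, gt, 4, seed = 21)
  arr <- array(t(dr$signals), c(length(gt), 2, 2, 1))
  vol <- diffusionVolume(aperm(arr, c(2, 3, 4, 1)), gt)
  cfg <- biexpConfig(compartments = "isotropic", fIsoFixed = 0, nStarts = 2)
  fit <- fitBiexp(vol, config = cfg)
  expect_true(all(fit$valid))
  maps <- biexpScalarMaps(fit)
  trueMSD <- 6 * 0.030 * (dr$truth$w * dr$truth$mdFast +
                            (1 - dr$truth$w) * dr$truth$mdSlow)
  expect_equal(as.vector(mapValues(maps$MSD)), trueMSD, tolerance = 0.05)
  p11 <- biexpParamsAt(fit, c(1, 1, 1))
  expect_s4_class(p11, "BiexpParams")
  expect_equal(msd(p11), mapValues(maps$MSD)[1, 1, 1], tolerance = 1e-12)
})

test_that("free-water contamination inflates the DTI trace above tissue trace", {
  set.seed(22)
  gt <- studyProtocol(nB0 = 3, dirsPerShell = 15)
  p <- biexpParams(100, 0.25, 0.6, lambdaFast = c(1.3, 0.9, 0.8) * 1e-3,
                   lambdaSlow = c(0.35, 0.25, 0.2) * 1e-3)
  s <- predictSignal(p, gt)
  dti <- fitDTI(diffusionVolume(array(s, c(1, 1, 1, length(gt))), gt))
  dtiTrace <- traceMeasure(dti$eigenvalues[1, 1, 1, ])
  tissueTrace <- p@w * sum(p@lambdaFast) + (1 - p@w) * sum(p@lambdaSlow)
  expect_gt(dtiTrace, tissueTrace)
})

test_that("biexp parameter maps serialize with a JSON sidecar", {
  tmp <- withr::local_tempdir()
  set.seed(23)
  gt <- smallProtocol()
  sp <- regionSpec("r", "cortical", targetDensity = 0.15)
  dr <- generateDiffusionRegion(sp, couplingSpec(), gt, 2, seed = 24)
  vol <- diffusionVolume(aperm(array(t(dr$signals), c(length(gt), 2, 1, 1)),
                               c(2, 3, 4, 1)), gt)
  fit <- fitBiexp(vol, config = biexpConfig(compartments = "isotropic",
                                            fIsoFixed = 0, nStarts = 1))
  stem <- file.path(tmp, "sub-01")
  writeBiexpFit(fit, stem)
  expect_true(file.exists(paste0(stem, "_params.nii.gz")))
  side <- jsonlite::read_json(paste0(stem, "_params.json"))
  expect_equal(unlist(side$volumes)[1:3], c("S0", "fIso", "w"))
})
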
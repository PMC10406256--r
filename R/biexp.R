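#' Construct biexponential model parameters for one voxel
#'
#' @param S0 b = 0 signal
#' @param fIso CSF (free-water) fraction
#' @param w fast-compartment weight within the tissue part
#' @param lambdaFast,lambdaSlow length-3 tissue eigenvalues (mm^2/s)
#' @param frame shared 3x3 orthonormal eigenvector frame (columns)
#' @param dIso CSF diffusivity (mm^2/s), default 3.0e-3 (free water at
#'   body temperature)
#' @param tau effective diffusion time (s)
#' @return a [BiexpParams-class]; the fast/slow labels are normalized so
#'   the fast compartment has the larger mean diffusivity
#' @export
biexpParams <- function(S0, fIso, w, lambdaFast, lambdaSlow,
                        frame = diag(3), dIso = 3.0e-3, tau = 0.030) {
  if (mean(lambdaSlow) > mean(lambdaFast)) {
    tmp <- lambdaFast; lambdaFast <- lambdaSlow; lambdaSlow <- tmp
    w <- 1 - w
  }
  new("BiexpParams", S0 = S0, fIso = fIso, dIso = dIso, w = w,
      frame = frame, lambdaFast = as.numeric(lambdaFast),
      lambdaSlow = as.numeric(lambdaSlow), tau = tau)
}

#' Predict the diffusion signal of the biexponential model
#'
#' S(b, g) = S0 \[ fIso exp(-b dIso) + (1 - fIso) ( w exp(-b g' Df g)
#' + (1 - w) exp(-b g' Ds g) ) \] with Df = R diag(lambdaFast) R' and
#' Ds = R diag(lambdaSlow) R'.
#'
#' @param params a [BiexpParams-class]
#' @param gtab a [GradientTable-class]
#' @return numeric signal vector, one value per measurement
#' @export
predictSignal <- function(params, gtab) {
  R <- params@frame
  Df <- R %*% diag(params@lambdaFast) %*% t(R)
  Ds <- R %*% diag(params@lambdaSlow) %*% t(R)
  b <- gtab@bvals
  g <- gtab@bvecs
  qf <- rowSums((g %*% Df) * g)
  qs <- rowSums((g %*% Ds) * g)
  params@S0 * (params@fIso * exp(-b * params@dIso) +
                 (1 - params@fIso) * (params@w * exp(-b * qf) +
                                        (1 - params@w) * exp(-b * qs)))
}

#' Tissue mean squared displacement
#'
#' Second moment of the Gaussian-mixture propagator over diffusion time
#' tau, restricted to the tissue compartments (the CSF term is excluded so
#' free-water contamination does not inflate the measure):
#' MSD = 2 tau \[ w tr(Df) + (1 - w) tr(Ds) \].
#'
#' @param params a [BiexpParams-class]
#' @param ... unused
#' @return MSD in mm^2
#' @export
setMethod("msd", "BiexpParams", function(params, ...) {
  2 * params@tau * (params@w * sum(params@lambdaFast) +
                      (1 - params@w) * sum(params@lambdaSlow))
})

#' Tissue return-to-origin probability
#'
#' Zero-displacement value of the Gaussian-mixture propagator, tissue
#' compartments only:
#' RTOP = w (4 pi tau)^(-3/2) det(Df)^(-1/2)
#'      + (1 - w) (4 pi tau)^(-3/2) det(Ds)^(-1/2).
#' Undefined (NA) when a tissue eigenvalue is zero (degenerate propagator).
#'
#' @param params a [BiexpParams-class]
#' @param ... unused
#' @return RTOP in mm^-3, or NA for a degenerate tensor
#' @export
setMethod("rtop", "BiexpParams", function(params, ...) {
  if (any(params@lambdaFast <= 0) || any(params@lambdaSlow <= 0))
    return(NA_real_)
  k <- (4 * pi * params@tau)^(-1.5)
  params@w * k / sqrt(prod(params@lambdaFast)) +
    (1 - params@w) * k / sqrt(prod(params@lambdaSlow))
})

# ---- fitting ---------------------------------------------------------------

#' Fitting configuration for the biexponential model
#'
#' @param compartments `"full"` (each tissue compartment gets its own three
#'   eigenvalues, both share one eigenvector frame parameterized by three
#'   angles) or `"isotropic"` (each compartment is a single scalar
#'   diffusivity; appropriate for nearly isotropic gray matter at reduced
#'   cost)
#' @param dIso CSF diffusivity; fixed at 3.0e-3 mm^2/s unless `fitDIso`
#' @param fitDIso fit dIso as a free parameter (default FALSE)
#' @param fIsoFixed if non-NULL, fix the CSF fraction at this value instead
#'   of fitting it
#' @param tau effective diffusion time (s)
#' @param nStarts number of optimization starts (DTI-seeded plus jittered)
#' @param lambdaBounds box constraints (mm^2/s) on tissue eigenvalues
#' @param maxIter Levenberg-Marquardt iteration cap per start
#' @return a list of class `biexpConfig`
#' @export
biexpConfig <- function(compartments = c("full", "isotropic"),
                        dIso = 3.0e-3, fitDIso = FALSE, fIsoFixed = NULL,
                        tau = 0.030, nStarts = 5L,
                        lambdaBounds = c(1e-6, 4e-3), maxIter = 200L) {
  structure(list(compartments = match.arg(compartments), dIso = dIso,
                 fitDIso = fitDIso, fIsoFixed = fIsoFixed, tau = tau,
                 nStarts = as.integer(nStarts), lambdaBounds = lambdaBounds,
                 maxIter = as.integer(maxIter)),
            class = "biexpConfig")
}

# ZYZ Euler angles of a rotation matrix (inverse of rotationFromAngles).
anglesFromRotation <- function(R) {
  if (det(R) < 0) R[, 3] <- -R[, 3]
  beta <- acos(pmin(pmax(R[3, 3], -1), 1))
  if (abs(sin(beta)) < 1e-9) return(c(atan2(R[2, 1], R[1, 1]), beta, 0))
  c(atan2(R[2, 3], R[1, 3]), beta, atan2(R[3, 2], -R[3, 1]))
}

rotationFromAngles <- function(a) {
  cz1 <- cos(a[1]); sz1 <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz2 <- cos(a[3]); sz2 <- sin(a[3])
  Rz1 <- matrix(c(cz1, sz1, 0, -sz1, cz1, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz2 <- matrix(c(cz2, sz2, 0, -sz2, cz2, 0, 0, 0, 1), 3, 3)
  Rz1 %*% Ry %*% Rz2
}

# Model prediction from the raw optimizer parameter vector.
.biexpPredict <- function(p, b, g, config) {
  if (config$compartments == "full") {
    fIso <- if (is.null(config$fIsoFixed)) p[2] else config$fIsoFixed
    off <- if (is.null(config$fIsoFixed)) 0 else -1
    w <- p[3 + off]
    R <- rotationFromAngles(p[(4:6) + off])
    lf <- p[(7:9) + off]; ls <- p[(10:12) + off]
    Df <- R %*% (t(R) * lf)
    Ds <- R %*% (t(R) * ls)
    qf <- rowSums((g %*% Df) * g)
    qs <- rowSums((g %*% Ds) * g)
  } else {
    fIso <- if (is.null(config$fIsoFixed)) p[2] else config$fIsoFixed
    off <- if (is.null(config$fIsoFixed)) 0 else -1
    w <- p[3 + off]
    qf <- p[4 + off]
    qs <- p[5 + off]
  }
  dIso <- if (config$fitDIso) p[length(p)] else config$dIso
  p[1] * (fIso * exp(-b * dIso) +
            (1 - fIso) * (w * exp(-b * qf) + (1 - w) * exp(-b * qs)))
}

.biexpStart <- function(config, s0, mdSeed, frameAngles = c(0, 0, 0),
                        lamSeed = NULL) {
  lb <- config$lambdaBounds
  clampL <- function(x) pmin(pmax(x, lb[1]), lb[2])
  if (is.null(lamSeed)) lamSeed <- rep(mdSeed, 3)
  p <- s0
  lo <- 1e-9 * max(s0, 1); hi <- Inf
  if (is.null(config$fIsoFixed)) { p <- c(p, 0.05); lo <- c(lo, 0); hi <- c(hi, 1) }
  p <- c(p, 0.5); lo <- c(lo, 0); hi <- c(hi, 1)   # w
  if (config$compartments == "full") {
    p <- c(p, frameAngles, clampL(1.5 * lamSeed), clampL(0.4 * lamSeed))
    lo <- c(lo, rep(-2 * pi, 3), rep(lb[1], 6))
    hi <- c(hi, rep(2 * pi, 3), rep(lb[2], 6))
  } else {
    p <- c(p, clampL(1.5 * mdSeed), clampL(0.4 * mdSeed))
    lo <- c(lo, lb[1], lb[1]); hi <- c(hi, lb[2], lb[2])
  }
  if (config$fitDIso) { p <- c(p, 3.0e-3); lo <- c(lo, 5e-4); hi <- c(hi, 6e-3) }
  list(par = p, lower = lo, upper = hi)
}

# Unpack a converged parameter vector into a named row (S0, fIso, w,
# lf1..3, ls1..3), applying the fast/slow relabeling. The shared frame is
# returned as an attribute.
.biexpUnpackRow <- function(p, config) {
  fIso <- if (is.null(config$fIsoFixed)) p[2] else config$fIsoFixed
  off <- if (is.null(config$fIsoFixed)) 0 else -1
  w <- p[3 + off]
  if (config$compartments == "full") {
    R <- rotationFromAngles(p[(4:6) + off])
    lf <- p[(7:9) + off]; ls <- p[(10:12) + off]
  } else {
    R <- diag(3)
    lf <- rep(p[4 + off], 3); ls <- rep(p[5 + off], 3)
  }
  if (mean(ls) > mean(lf)) { tmp <- lf; lf <- ls; ls <- tmp; w <- 1 - w }
  out <- c(S0 = unname(p[1]), fIso = unname(fIso), w = unname(w),
           lf1 = lf[1], lf2 = lf[2], lf3 = lf[3],
           ls1 = ls[1], ls2 = ls[2], ls3 = ls[3])
  attr(out, "frame") <- R
  out
}

# Unpack a converged parameter vector into a BiexpParams, applying the
# fast/slow relabeling.
.biexpUnpack <- function(p, config) {
  fIso <- if (is.null(config$fIsoFixed)) p[2] else config$fIsoFixed
  off <- if (is.null(config$fIsoFixed)) 0 else -1
  w <- p[3 + off]
  if (config$compartments == "full") {
    R <- rotationFromAngles(p[(4:6) + off])
    lf <- p[(7:9) + off]; ls <- p[(10:12) + off]
  } else {
    R <- diag(3)
    lf <- rep(p[4 + off], 3); ls <- rep(p[5 + off], 3)
  }
  dIso <- if (config$fitDIso) p[length(p)] else config$dIso
  biexpParams(S0 = p[1], fIso = fIso, w = w, lambdaFast = lf,
              lambdaSlow = ls, frame = R, dIso = dIso, tau = config$tau)
}

#' Fit the biexponential model to one voxel's signal
#'
#' Box-constrained nonlinear least squares on the linear signal (not the
#' log-signal), with multiple starts: a DTI-seeded start plus randomly
#' jittered copies; the start with the smallest residual sum of squares
#' wins. Fast/slow compartments are relabeled after the fit so the fast
#' compartment carries the larger mean diffusivity.
#'
#' @param signal numeric vector of measurements
#' @param gtab matching [GradientTable-class] (needs b = 0 plus at least 3
#'   distinct nonzero shells)
#' @param config a [biexpConfig()]
#' @param seedFrameAngles optional angles seeding the eigenvector frame
#'   (e.g. from a DTI fit)
#' @param mdSeed optional mean-diffusivity seed (mm^2/s)
#' @param materialize build the [BiexpParams-class] object (set FALSE in
#'   tight loops; the named `raw` vector is always returned)
#' @return list with `params` ([BiexpParams-class] or NULL), `raw` (named
#'   vector S0, fIso, w, lf1..3, ls1..3 with the shared frame as an
#'   attribute), `rss`, `converged`
#' @export
fitBiexpVoxel <- function(signal, gtab, config = biexpConfig(),
                          seedFrameAngles = NULL, mdSeed = NULL,
                          materialize = TRUE) {
  b <- gtab@bvals
  g <- gtab@bvecs
  shells <- unique(shellOf(b))
  if (sum(shells > 0) < 3L)
    stop("biexponential fit needs at least 3 distinct nonzero shells")
  if (!any(shells == 0))
    stop("biexponential fit needs b = 0 measurements")
  s0 <- mean(signal[shellOf(b) == 0])
  if (!is.finite(s0) || s0 <= 0)
    return(list(params = NULL, rss = Inf, converged = FALSE))
  if (is.null(seedFrameAngles) && config$compartments == "full") {
    # quick single-voxel log-linear tensor fit on the low-b shells for a
    # frame and MD seed
    sel <- shellOf(b) <= 1000 & signal > 0
    if (sum(sel) >= 7L) {
      bs <- b[sel]; gs <- g[sel, , drop = FALSE]
      X <- cbind(1, -bs * gs[, 1]^2, -bs * gs[, 2]^2, -bs * gs[, 3]^2,
                 -2 * bs * gs[, 1] * gs[, 2], -2 * bs * gs[, 1] * gs[, 3],
                 -2 * bs * gs[, 2] * gs[, 3])
      beta <- tryCatch(qr.solve(X, log(signal[sel])), error = function(e) NULL)
      if (!is.null(beta)) {
        D <- matrix(c(beta[2], beta[5], beta[6], beta[5], beta[3], beta[7],
                      beta[6], beta[7], beta[4]), 3, 3)
        e <- eigen(D, symmetric = TRUE)
        seedFrameAngles <- anglesFromRotation(e$vectors)
        if (is.null(mdSeed))
          mdSeed <- max(1e-4, min(3e-3, mean(pmax(e$values, 0))))
      }
    }
  }
  if (is.null(seedFrameAngles)) seedFrameAngles <- c(0, 0, 0)
  if (is.null(mdSeed)) {
    # crude ADC seed from the lowest nonzero shell
    b1 <- min(shells[shells > 0])
    m1 <- mean(signal[shellOf(b) == b1])
    mdSeed <- max(1e-4, min(3e-3, log(s0 / max(m1, 1e-12)) / b1))
  }
  wts <- NULL
  if (config$compartments == "isotropic") {
    # the isotropic model depends on b only, so least squares on all
    # measurements equals weighted least squares on shell means (weights =
    # sqrt(shell size)); compress for speed, identical optimum
    sh <- shellOf(b)
    us <- sort(unique(sh))
    ns <- vapply(us, function(x) sum(sh == x), integer(1))
    ym <- vapply(us, function(x) mean(signal[sh == x]), numeric(1))
    b <- us
    g <- matrix(0, length(us), 3)
    signal <- ym
    wts <- sqrt(ns)
  }
  .biexpLM(signal, b, g, wts, config, s0, mdSeed, seedFrameAngles,
           materialize)
}

# Core multi-start Levenberg-Marquardt loop on (possibly shell-compressed)
# data.
.biexpLM <- function(signal, b, g, wts, config, s0, mdSeed,
                     seedFrameAngles, materialize) {
  best <- list(par = NULL, rss = Inf, converged = FALSE)
  for (k in seq_len(config$nStarts)) {
    st <- .biexpStart(config, s0, mdSeed, seedFrameAngles)
    if (k > 1) {   # jitter all but the seeded start
      jit <- stats::runif(length(st$par), 0.6, 1.5)
      st$par <- pmin(pmax(st$par * jit, st$lower), st$upper)
      st$par[!is.finite(st$par)] <- 0
    }
    resid <- if (is.null(wts))
      function(p) signal - .biexpPredict(p, b, g, config)
    else
      function(p) wts * (signal - .biexpPredict(p, b, g, config))
    jac <- NULL
    if (config$compartments == "isotropic" &&
        !is.null(config$fIsoFixed) && !config$fitDIso) {
      # analytic Jacobian of the residual for the common reduced model:
      # m = k * S0 (w e^{-b df} + (1-w) e^{-b ds}) + S0 fIso e^{-b dIso}
      fi <- config$fIsoFixed
      ei <- exp(-b * config$dIso)
      jac <- function(p) {
        ef <- exp(-b * p[3]); es <- exp(-b * p[4])
        J <- cbind(fi * ei + (1 - fi) * (p[2] * ef + (1 - p[2]) * es),
                   p[1] * (1 - fi) * (ef - es),
                   -p[1] * (1 - fi) * p[2] * b * ef,
                   -p[1] * (1 - fi) * (1 - p[2]) * b * es)
        -J * wts
      }
    }
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(par = st$par, lower = st$lower, upper = st$upper,
                         fn = resid, jac = jac,
                         control = minpack.lm::nls.lm.control(
                           maxiter = config$maxIter, ftol = 1e-12,
                           ptol = 1e-12))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (rss < best$rss)
      best <- list(par = fit$par, rss = rss, converged = fit$info %in% 1:4)
  }
  if (is.null(best$par))
    return(list(params = NULL, raw = NULL, rss = Inf, converged = FALSE))
  out <- list(params = NULL, raw = .biexpUnpackRow(best$par, config),
              rss = best$rss, converged = best$converged)
  if (materialize) out$params <- .biexpUnpack(best$par, config)
  out
}

#' Fit the biexponential model over a volume
#'
#' @param volume a [DiffusionVolume-class]
#' @param mask logical 3D array of voxels to fit (default: all)
#' @param config a [biexpConfig()]
#' @param dtiSeed optional `DtiFit` used to seed S0/frame/MD per voxel
#' @return a `BiexpFit` list with `paramMatrix` (voxels x 9 matrix of S0,
#'   fIso, w and eigenvalues, NA rows where the fit failed), `valid`,
#'   `rss`, `config`; [biexpParamsAt()] materializes one voxel's
#'   [BiexpParams-class]
#' @export
fitBiexp <- function(volume, mask = NULL, config = biexpConfig(),
                     dtiSeed = NULL) {
  dims <- dim(volume@signal)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  nv <- prod(dims)
  sig <- matrix(volume@signal, nv, dim(volume@signal)[4])
  pm <- matrix(NA_real_, nv, 9,
               dimnames = list(NULL, c("S0", "fIso", "w", "lf1", "lf2",
                                       "lf3", "ls1", "ls2", "ls3")))
  frames <- vector("list", nv)
  vv <- rep(FALSE, nv); rv <- rep(NA_real_, nv)
  seedLam <- if (!is.null(dtiSeed)) matrix(dtiSeed$eigenvalues, nv, 3)
  seedVec <- if (!is.null(dtiSeed)) matrix(dtiSeed$eigenvectors, nv, 9)
  iso <- config$compartments == "isotropic"
  if (iso) {
    # compress the whole volume to shell means once (see fitBiexpVoxel)
    sh <- shellOf(volume@gtab@bvals)
    us <- sort(unique(sh))
    if (sum(us > 0) < 3L)
      stop("biexponential fit needs at least 3 distinct nonzero shells")
    if (!any(us == 0))
      stop("biexponential fit needs b = 0 measurements")
    ind <- outer(sh, us, "==")
    smean <- sig %*% (ind / rep(colSums(ind), each = length(sh)))
    wtsAll <- sqrt(colSums(ind))
    gz <- matrix(0, length(us), 3)
  }
  for (i in which(as.vector(mask))) {
    md <- NULL
    ang <- c(0, 0, 0)
    if (!is.null(seedLam) && all(is.finite(seedLam[i, ]))) {
      md <- mean(seedLam[i, ])
      if (!iso) ang <- anglesFromRotation(matrix(seedVec[i, ], 3, 3))
    }
    if (iso) {
      s0 <- smean[i, which(us == 0)]
      if (!is.finite(s0) || s0 <= 0) next
      if (is.null(md)) {
        b1 <- min(us[us > 0])
        md <- max(1e-4, min(3e-3,
                            log(s0 / max(smean[i, which(us == b1)], 1e-12)) / b1))
      }
      f <- .biexpLM(smean[i, ], us, gz, wtsAll, config, s0, md, ang, FALSE)
    } else {
      f <- fitBiexpVoxel(sig[i, ], volume@gtab, config, mdSeed = md,
                         seedFrameAngles = ang, materialize = FALSE)
    }
    if (!is.null(f$raw)) {
      pm[i, ] <- f$raw
      frames[[i]] <- attr(f$raw, "frame")
      vv[i] <- TRUE
      rv[i] <- f$rss
    }
  }
  structure(list(paramMatrix = pm, frames = frames,
                 valid = array(vv, dims), rss = array(rv, dims),
                 config = config, dims = dims),
            class = "BiexpFit")
}

#' Materialize one voxel's biexponential parameters from a fit
#'
#' @param fit a `BiexpFit` from [fitBiexp()]
#' @param i voxel index in array order (or a length-3 voxel coordinate)
#' @return a [BiexpParams-class], or NULL if the voxel was not fit
#' @export
biexpParamsAt <- function(fit, i) {
  if (length(i) == 3L)
    i <- i[1] + (i[2] - 1) * fit$dims[1] +
      (i[3] - 1) * fit$dims[1] * fit$dims[2]
  if (!fit$valid[i]) return(NULL)
  p <- fit$paramMatrix[i, ]
  biexpParams(S0 = unname(p["S0"]), fIso = unname(p["fIso"]),
              w = unname(p["w"]),
              lambdaFast = unname(p[c("lf1", "lf2", "lf3")]),
              lambdaSlow = unname(p[c("ls1", "ls2", "ls3")]),
              frame = fit$frames[[i]], dIso = fit$config$dIso,
              tau = fit$config$tau)
}

#' MSD and RTOP maps from a biexponential fit
#'
#' @param fit a `BiexpFit` from [fitBiexp()]
#' @return named list of [ScalarMap-class] objects `MSD` and `RTOP`
#' @export
biexpScalarMaps <- function(fit) {
  pm <- fit$paramMatrix
  tau <- fit$config$tau
  w <- pm[, "w"]
  trf <- pm[, "lf1"] + pm[, "lf2"] + pm[, "lf3"]
  trs <- pm[, "ls1"] + pm[, "ls2"] + pm[, "ls3"]
  msdv <- 2 * tau * (w * trf + (1 - w) * trs)
  k <- (4 * pi * tau)^(-1.5)
  detf <- pm[, "lf1"] * pm[, "lf2"] * pm[, "lf3"]
  dets <- pm[, "ls1"] * pm[, "ls2"] * pm[, "ls3"]
  rtopv <- ifelse(detf > 0 & dets > 0,
                  w * k / sqrt(detf) + (1 - w) * k / sqrt(dets), NA_real_)
  list(MSD = new("ScalarMap", values = array(msdv, fit$dims), measure = "MSD"),
       RTOP = new("ScalarMap", values = array(rtopv, fit$dims), measure = "RTOP"))
}

#' Write biexponential parameter maps as NIfTI plus a JSON sidecar
#'
#' One 4D NIfTI volume per parameter set (S0, fIso, w, eigenvalues) with a
#' JSON sidecar naming the volumes.
#'
#' @param fit a `BiexpFit`
#' @param stem output path stem; writes `<stem>_params.nii.gz` and
#'   `<stem>_params.json`
#' @param voxelMM voxel edge (mm)
#' @return invisibly, the NIfTI path
#' @export
writeBiexpFit <- function(fit, stem, voxelMM = 0.8) {
  nm <- colnames(fit$paramMatrix)
  arr <- array(fit$paramMatrix, c(fit$dims, length(nm)))
  path <- paste0(stem, "_params.nii.gz")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rep(voxelMM, 3), 1)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(volumes = nm, dIso = fit$config$dIso,
                            tau = fit$config$tau),
                       paste0(stem, "_params.json"), auto_unbox = TRUE)
  invisible(path)
}
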
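#' Coupling between local cell density and local diffusivity
#'
#' The generator links a voxel's latent cell area density d to its tissue
#' mean diffusivity via MD(d) = MD0 (1 + kappa (d - dbar)), where dbar is
#' the region's target density. kappa = 0 decouples the two modalities
#' (the null used for type-I checks); kappa > 0 makes denser tissue more
#' diffusive, inducing a positive histology-dMRI correlation downstream.
#'
#' @param kappa dimensionless coupling coefficient
#' @param noiseSNR Rician signal-to-noise ratio at b = 0
#' @param md0 baseline fast-compartment mean diffusivity (mm^2/s)
#' @param slowRatio slow-compartment MD as a fraction of the fast MD
#' @param wRange range the tissue fast-compartment weight is drawn from
#' @param fIsoRange range the CSF fraction is drawn from (default `c(0, 0)`:
#'   no CSF inside gray-matter blocks)
#' @param fieldScale standard deviation of the latent per-voxel density
#'   relative to `targetDensity * densityGradient` (matches the
#'   voxel-averaged spread of the section generator's smooth field)
#' @return a list of class `couplingSpec`
#' @export
couplingSpec <- function(kappa = 0, noiseSNR = 30, md0 = 0.8e-3,
                         slowRatio = 0.25, wRange = c(0.5, 0.8),
                         fIsoRange = c(0, 0), fieldScale = 0.35) {
  stopifnot(noiseSNR > 0, md0 > 0, slowRatio > 0, fieldScale >= 0)
  structure(list(kappa = kappa, noiseSNR = noiseSNR, md0 = md0,
                 slowRatio = slowRatio, wRange = wRange,
                 fIsoRange = fIsoRange, fieldScale = fieldScale),
            class = "couplingSpec")
}

# Latent per-voxel densities for a region: the same first- and
# second-moment structure as the section generator's smooth density field,
# clamped to a physical range.
latentDensities <- function(spec, coupling, nVoxels) {
  sdv <- spec$targetDensity * spec$densityGradient * coupling$fieldScale
  d <- stats::rnorm(nVoxels, spec$targetDensity, sdv)
  pmin(pmax(d, 0.005), 0.85)
}

#' Generate biexponential diffusion signals for one region
#'
#' Each voxel receives a latent cell density d drawn to match the section
#' generator's density-field statistics; its biexponential parameters are
#' set through the coupling link function (fast MD = MD(d), slow MD =
#' `slowRatio` x MD(d), isotropic compartments; weight and CSF fraction
#' drawn from the configured ranges); the noise-free signal comes from
#' [predictSignal()] and Rician noise is applied as |S + e1 + i e2| with
#' e ~ N(0, S0 / noiseSNR).
#'
#' @param spec a [regionSpec()]
#' @param coupling a [couplingSpec()]
#' @param gtab a [GradientTable-class]
#' @param nVoxels number of voxels to generate
#' @param S0 b = 0 signal level
#' @param tau effective diffusion time (s)
#' @param seed optional RNG seed
#' @param noiseFree skip the Rician noise (signals equal the forward model)
#' @param returnParams also materialize the per-voxel
#'   [BiexpParams-class] list (skip in tight loops)
#' @return list with `signals` (nVoxels x M matrix), `truth` (data.frame of
#'   per-voxel density, MD, w, fIso), and `params` (list of
#'   [BiexpParams-class], or NULL unless `returnParams`)
#' @export
generateDiffusionRegion <- function(spec, coupling, gtab, nVoxels,
                                    S0 = 500, tau = 0.030, seed = NULL,
                                    noiseFree = FALSE, returnParams = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nVoxels >= 1)
  d <- latentDensities(spec, coupling, nVoxels)
  mdf <- coupling$md0 * (1 + coupling$kappa * (d - spec$targetDensity))
  if (any(mdf <= 0))
    stop("density-diffusivity link yields non-positive diffusivity; ",
         "reduce kappa or the density spread")
  mds <- coupling$slowRatio * mdf
  w <- stats::runif(nVoxels, coupling$wRange[1], coupling$wRange[2])
  fIso <- stats::runif(nVoxels, coupling$fIsoRange[1], coupling$fIsoRange[2])
  M <- length(gtab)
  b <- gtab@bvals
  # isotropic compartments: the forward model depends on b only
  dIso <- 3.0e-3
  signals <- S0 * (fIso * outer(rep(1, nVoxels), exp(-b * dIso)) +
                     (1 - fIso) * (w * exp(-outer(mdf, b)) +
                                     (1 - w) * exp(-outer(mds, b))))
  if (!noiseFree) {
    sigma <- S0 / coupling$noiseSNR
    signals <- sqrt((signals + stats::rnorm(nVoxels * M, 0, sigma))^2 +
                      stats::rnorm(nVoxels * M, 0, sigma)^2)
  }
  params <- NULL
  if (returnParams)
    params <- lapply(seq_len(nVoxels), function(v)
      biexpParams(S0 = S0, fIso = fIso[v], w = w[v],
                  lambdaFast = rep(mdf[v], 3), lambdaSlow = rep(mds[v], 3),
                  dIso = dIso, tau = tau))
  list(signals = signals,
       truth = data.frame(density = d, mdFast = mdf, mdSlow = mds,
                          w = w, fIso = fIso),
       params = params)
}
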
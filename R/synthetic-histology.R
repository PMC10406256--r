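#' Specification of one synthetic gray-matter region
#'
#' Describes the cytoarchitecture the histology generator emulates for a
#' region: typical cell-body size and its spread, the area fraction
#' covered by cells, and how strongly local density is spatially modulated
#' (a homogeneous region has `densityGradient = 0`; larger values give a
#' patchier, more heterogeneous region).
#'
#' @param name region name
#' @param class `"cortical"` or `"subcortical"`
#' @param meanCellRadius median cell-body radius in micrometres
#' @param radiusCV coefficient of variation of the (lognormal) radius
#'   distribution
#' @param targetDensity cell area fraction aimed for, in \[0, 0.9)
#' @param densityGradient dimensionless strength of the smooth spatial
#'   modulation of local cell density (0 = spatially uniform)
#' @param sectionMM section edge length in mm (square sections)
#' @return a list of class `regionSpec`
#' @export
regionSpec <- function(name, class = c("cortical", "subcortical"),
                       meanCellRadius = 10, radiusCV = 0.3,
                       targetDensity = 0.15, densityGradient = 0,
                       sectionMM = 1.6) {
  class <- match.arg(class)
  stopifnot(targetDensity >= 0, targetDensity < 0.9,
            radiusCV >= 0, densityGradient >= 0,
            meanCellRadius > 0, sectionMM > 0)
  structure(list(name = name, class = class,
                 meanCellRadius = meanCellRadius, radiusCV = radiusCV,
                 targetDensity = targetDensity,
                 densityGradient = densityGradient, sectionMM = sectionMM),
            class = "regionSpec")
}

# Smooth standardized random field on an nr x nc pixel grid: white noise on
# a coarse grid with spacing ~ correlationPx, bilinearly interpolated, then
# standardized to mean 0 / sd 1.
smoothField <- function(nr, nc, correlationPx) {
  gr <- max(2L, ceiling(nr / correlationPx) + 1L)
  gc <- max(2L, ceiling(nc / correlationPx) + 1L)
  z <- matrix(stats::rnorm(gr * gc), gr, gc)
  # bilinear interpolation of the coarse grid onto the pixel grid
  ri <- (seq_len(nr) - 1) / (nr - 1) * (gr - 1) + 1
  ci <- (seq_len(nc) - 1) / (nc - 1) * (gc - 1) + 1
  r0 <- pmin(floor(ri), gr - 1); c0 <- pmin(floor(ci), gc - 1)
  fr <- ri - r0; fc <- ci - c0
  f <- outer(1 - fr, 1 - fc) * z[cbind(rep(r0, nc), rep(c0, each = nr))] +
    outer(fr, 1 - fc) * z[cbind(rep(r0 + 1, nc), rep(c0, each = nr))] +
    outer(1 - fr, fc) * z[cbind(rep(r0, nc), rep(c0 + 1, each = nr))] +
    outer(fr, fc) * z[cbind(rep(r0 + 1, nc), rep(c0 + 1, each = nr))]
  dim(f) <- c(nr, nc)
  (f - mean(f)) / max(stats::sd(f), 1e-12)
}

# Hard-core placement: dart throwing with a bin grid for neighbor lookup
# (compiled; see src/generator.cpp). Candidates are thinned by the density
# field; centers may overlap by at most 20% of the smaller radius.
placeCells <- function(n, radii, nr, nc, acceptProb = NULL,
                       maxAttemptsFactor = 60) {
  radii <- sort(radii, decreasing = TRUE)  # big cells first packs better
  out <- .placeCellsCpp(radii, nr, nc, acceptProb,
                        as.integer(maxAttemptsFactor * n))
  placed <- length(out$x)
  if (placed < n && placed < 0.8 * n)
    stop("infeasible packing: placed ", placed, " of ", n,
         " cells after ", out$attempts, " attempts")
  out[c("x", "y", "r")]
}

# Rasterize filled ellipses onto a logical nr x nc mask. Pixel (i, j)
# covers the point (i, j) (pixel-center convention). Compiled.
rasterizeEllipses <- function(nr, nc, cx, cy, r, axisRatio, theta) {
  .rasterizeEllipsesCpp(as.integer(nr), as.integer(nc), cx, cy, r,
                        axisRatio, theta)
}

#' Generate a synthetic Nissl-like histology section
#'
#' Cell bodies are drawn as filled dark ellipses (axis ratio uniform in
#' \[0.7, 1\], lognormal radii with median `meanCellRadius` and sigma set
#' from `radiusCV`) on a bright background. Centers follow a hard-core
#' point process (overlap at most 20% of the smaller radius) whose local
#' intensity is modulated by a smooth spatial field scaled by
#' `densityGradient`; additive Gaussian pixel noise is applied last. The
#' returned ground-truth mask is the exact rasterized union of the drawn
#' ellipses.
#'
#' @param spec a [regionSpec()]
#' @param pixelSize pixel edge in micrometres (default 4; the source
#'   microscopy resolution of 0.44 um is available but desk-scale runs use
#'   a coarser default)
#' @param noiseSD additive Gaussian noise standard deviation (image units)
#' @param correlationMM correlation length of the density field in mm
#'   (default 0.8, one diffusion voxel)
#' @param backgroundLevel,cellLevel mean intensities of background and
#'   cell pixels
#' @param seed optional RNG seed
#' @return list with `section` (a [HistologySection-class] whose single ROI
#'   mask `roi` covers the full frame), `truthMask` (logical ground-truth
#'   cell mask), `trueDensity` (ground-truth cell area fraction), and
#'   `cells` (data.frame of centers/radii)
#' @export
generateHistologySection <- function(spec, pixelSize = 4, noiseSD = 0.06,
                                     correlationMM = 0.8,
                                     backgroundLevel = 0.85,
                                     cellLevel = 0.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  npx <- max(8L, round(spec$sectionMM * 1000 / pixelSize))
  nr <- nc <- npx
  if (spec$targetDensity == 0) {
    truth <- matrix(FALSE, nr, nc)
    img <- pmin(pmax(backgroundLevel +
                       stats::rnorm(nr * nc, 0, noiseSD), 0), 1)
    dim(img) <- c(nr, nc)
    section <- new("HistologySection", image = img, pixelSize = pixelSize,
                   roiMasks = list(roi = matrix(TRUE, nr, nc)))
    return(list(section = section, truthMask = truth, trueDensity = 0,
                cells = data.frame(x = numeric(0), y = numeric(0),
                                   r = numeric(0))))
  }
  rpx <- spec$meanCellRadius / pixelSize
  sdlog <- sqrt(log(1 + spec$radiusCV^2))
  meanAxisRatio <- 0.85
  # E[r^2] for lognormal with median rpx: rpx^2 exp(2 sdlog^2)
  meanArea <- pi * rpx^2 * exp(2 * sdlog^2) * meanAxisRatio
  nCells <- max(1L, round(spec$targetDensity * nr * nc / meanArea))
  radii <- stats::rlnorm(nCells, meanlog = log(rpx), sdlog = sdlog)
  radii <- pmax(radii, 1)
  accept <- NULL
  if (spec$densityGradient > 0) {
    fld <- smoothField(nr, nc, correlationMM * 1000 / pixelSize)
    lam <- 1 + spec$densityGradient * fld
    lam[lam < 0] <- 0
    accept <- lam / max(lam)
  }
  pl <- placeCells(nCells, radii, nr, nc, acceptProb = accept)
  n <- length(pl$x)
  axisRatio <- stats::runif(n, 0.7, 1)
  theta <- stats::runif(n, 0, pi)
  truth <- rasterizeEllipses(nr, nc, pl$x, pl$y, pl$r, axisRatio, theta)
  img <- matrix(backgroundLevel, nr, nc)
  img[truth] <- cellLevel
  img <- img + stats::rnorm(nr * nc, 0, noiseSD)
  img <- pmin(pmax(img, 0), 1)
  section <- new("HistologySection", image = img, pixelSize = pixelSize,
                 roiMasks = list(roi = matrix(TRUE, nr, nc)))
  list(section = section, truthMask = truth,
       trueDensity = sum(truth) / (nr * nc),
       cells = data.frame(x = pl$x, y = pl$y, r = pl$r,
                          axisRatio = axisRatio, theta = theta))
}
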
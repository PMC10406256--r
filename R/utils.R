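#' Voxel edge lengths implied by an affine
#'
#' @param affine 4x4 grid-to-world matrix (mm)
#' @return length-3 numeric vector of voxel edge lengths in mm
#' @export
voxelSize <- function(affine) {
  stopifnot(all(dim(affine) == c(4L, 4L)))
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# Rescale finite values to [0,1]; constant input maps to 0.
rescale01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (r[2] - r[1] <= 0) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

# b-values at or below this are treated as b = 0 for shell grouping
# (scanners report small nonzero values on nominally unweighted volumes).
.B0_THRESHOLD <- 50

shellOf <- function(bvals) ifelse(bvals <= .B0_THRESHOLD, 0, round(bvals))

# Draw samples from a Rician distribution: magnitude of a complex signal
# with Gaussian noise of sd sigma on both channels.
rrice <- function(n, nu, sigma) {
  sqrt((nu + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

# Population variance (divides by N, not N-1).
popVar <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}
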
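#' @import methods
NULL

#' Gradient table for a diffusion MRI acquisition
#'
#' Holds the b-values (s/mm^2) and unit gradient directions of one
#' acquisition. Directions attached to diffusion-weighted measurements
#' (b > 0) are unit vectors; directions of b = 0 measurements are ignored
#' and stored as zero vectors.
#'
#' @slot bvals numeric vector of b-values in s/mm^2, all non-negative.
#' @slot bvecs numeric matrix with one row per measurement and 3 columns;
#'   rows with \code{bvals > 0} have unit Euclidean norm.
#'
#' @seealso [gradientTable()], [readGradientTable()]
#' @export
setClass("GradientTable",
         representation(bvals = "numeric", bvecs = "matrix"))

setValidity("GradientTable", function(object) {
  msg <- character()
  if (nrow(object@bvecs) != length(object@bvals))
    msg <- c(msg, "number of bvec rows must equal number of bvals")
  if (ncol(object@bvecs) != 3L)
    msg <- c(msg, "bvecs must have 3 columns")
  if (any(!is.finite(object@bvals)) || any(object@bvals < 0))
    msg <- c(msg, "bvals must be finite and non-negative")
  dw <- object@bvals > 0
  if (any(dw)) {
    nrm <- sqrt(rowSums(object@bvecs[dw, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "directions for b > 0 must be unit vectors (|g| = 1 within 1e-6)")
  }
  if (length(msg)) msg else TRUE
})

#' 4D diffusion-weighted volume
#'
#' A 4D signal array (X, Y, Z, measurement) together with its 4x4
#' grid-to-world affine (mm) and the matching [GradientTable-class].
#'
#' @slot signal 4D numeric array, non-negative, fourth dimension equal to
#'   the gradient-table length.
#' @slot affine 4x4 numeric grid-to-world transform in mm.
#' @slot gtab a [GradientTable-class].
#' @export
setClass("DiffusionVolume",
         representation(signal = "array", affine = "matrix",
                        gtab = "GradientTable"))

setValidity("DiffusionVolume", function(object) {
  msg <- character()
  if (length(dim(object@signal)) != 4L)
    msg <- c(msg, "signal must be a 4D array")
  else if (dim(object@signal)[4] != length(object@gtab@bvals))
    msg <- c(msg, "4th signal dimension must match gradient-table length")
  if (any(object@signal < 0, na.rm = TRUE))
    msg <- c(msg, "signal must be non-negative")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  if (length(msg)) msg else TRUE
})

#' Integer region-of-interest label volume
#'
#' A 3D integer label array on the diffusion grid plus a region table
#' mapping each nonzero label to a region name and a class
#' (\code{"cortical"} or \code{"subcortical"}). Label 0 is background.
#'
#' @slot labels 3D integer array; 0 = background.
#' @slot regionTable data.frame with columns \code{label}, \code{name},
#'   \code{class}; every nonzero label present in the array must appear.
#' @export
setClass("LabelVolume",
         representation(labels = "array", regionTable = "data.frame"))

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  need <- c("label", "name", "class")
  if (!all(need %in% names(object@regionTable)))
    msg <- c(msg, "regionTable needs columns label, name, class")
  else {
    if (!all(object@regionTable$class %in% c("cortical", "subcortical")))
      msg <- c(msg, "region class must be 'cortical' or 'subcortical'")
    present <- setdiff(unique(as.integer(object@labels)), 0L)
    missing <- setdiff(present, object@regionTable$label)
    if (length(missing))
      msg <- c(msg, paste0("labels present in volume but absent from region table: ",
                           paste(missing, collapse = ", ")))
    if (anyDuplicated(object@regionTable$label))
      msg <- c(msg, "duplicated labels in region table")
  }
  if (length(msg)) msg else TRUE
})

#' 3D scalar map of one diffusion measure
#'
#' @slot values 3D numeric array (NA where the fit was invalid).
#' @slot measure one of \code{"FA"}, \code{"TR"}, \code{"MSD"}, \code{"RTOP"}
#'   or any other short measure name.
#' @export
setClass("ScalarMap",
         representation(values = "array", measure = "character"))

setValidity("ScalarMap", function(object) {
  if (length(dim(object@values)) != 3L) "values must be a 3D array" else TRUE
})

#' Per-voxel biexponential model parameters
#'
#' Parameters of the two-compartment tissue model plus isotropic free-water
#' (CSF) term. Both tissue compartments share one orthonormal eigenvector
#' frame; the fast compartment has the larger mean diffusivity.
#'
#' @slot S0 non diffusion-weighted signal (scanner units).
#' @slot fIso CSF volume fraction in \[0, 1\].
#' @slot dIso isotropic CSF diffusivity (mm^2/s).
#' @slot w fast-compartment weight within the tissue part, in \[0, 1\].
#' @slot frame 3x3 orthonormal eigenvector matrix shared by both tissue
#'   tensors (columns are eigenvectors).
#' @slot lambdaFast,lambdaSlow length-3 eigenvalues (mm^2/s) of the fast and
#'   slow tissue tensors; \code{mean(lambdaFast) >= mean(lambdaSlow)}.
#' @slot tau effective diffusion time (s), fixed per study.
#' @export
setClass("BiexpParams",
         representation(S0 = "numeric", fIso = "numeric", dIso = "numeric",
                        w = "numeric", frame = "matrix",
                        lambdaFast = "numeric", lambdaSlow = "numeric",
                        tau = "numeric"))

setValidity("BiexpParams", function(object) {
  msg <- character()
  if (object@S0 < 0) msg <- c(msg, "S0 must be >= 0")
  if (object@fIso < 0 || object@fIso > 1) msg <- c(msg, "fIso must lie in [0,1]")
  if (object@w < 0 || object@w > 1) msg <- c(msg, "w must lie in [0,1]")
  if (object@dIso <= 0) msg <- c(msg, "dIso must be > 0")
  if (object@tau <= 0) msg <- c(msg, "tau must be > 0")
  if (length(object@lambdaFast) != 3L || length(object@lambdaSlow) != 3L)
    msg <- c(msg, "eigenvalues must be length-3")
  if (any(object@lambdaFast < 0) || any(object@lambdaSlow < 0))
    msg <- c(msg, "eigenvalues must be non-negative")
  if (mean(object@lambdaFast) < mean(object@lambdaSlow) - 1e-12)
    msg <- c(msg, "fast compartment must have mean diffusivity >= slow compartment")
  if (!all(dim(object@frame) == c(3L, 3L)))
    msg <- c(msg, "frame must be 3x3")
  else if (max(abs(crossprod(object@frame) - diag(3))) > 1e-6)
    msg <- c(msg, "frame must be orthonormal")
  if (length(msg)) msg else TRUE
})

#' Digitized histology section with ROI masks
#'
#' @slot image 2D grayscale matrix in \[0, 1\] (dark cells on a bright
#'   background, as in a Nissl stain).
#' @slot pixelSize pixel edge length in micrometres.
#' @slot roiMasks named list of logical masks, one per region, each the same
#'   shape as \code{image}.
#' @export
setClass("HistologySection",
         representation(image = "matrix", pixelSize = "numeric",
                        roiMasks = "list"))

setValidity("HistologySection", function(object) {
  msg <- character()
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  for (nm in names(object@roiMasks)) {
    m <- object@roiMasks[[nm]]
    if (!is.logical(m) || !all(dim(m) == dim(object@image)))
      msg <- c(msg, sprintf("roi mask '%s' must be logical and image-shaped", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Binary / labeled cell segmentation of a section
#'
#' @slot binary logical matrix, TRUE on cell-body pixels.
#' @slot labels integer matrix of connected components, nonzero exactly
#'   where \code{binary} is TRUE.
#' @slot nCells number of connected components.
#' @export
setClass("CellMask",
         representation(binary = "matrix", labels = "matrix",
                        nCells = "integer"))

setValidity("CellMask", function(object) {
  msg <- character()
  if (!all(dim(object@binary) == dim(object@labels)))
    msg <- c(msg, "binary and labels must share a shape")
  if (!identical(unname(object@labels > 0), unname(object@binary)))
    msg <- c(msg, "labels must be nonzero exactly where binary is TRUE")
  nlab <- length(setdiff(unique(as.integer(object@labels)), 0L))
  if (nlab != object@nCells)
    msg <- c(msg, "nCells must equal the number of distinct nonzero labels")
  if (length(msg)) msg else TRUE
})

.summaryMeasures <- c("FA", "TR", "MSD", "RTOP", "CAD")

#' Regional summary table
#'
#' Tidy table with one row per (subject, region, measure) carrying the
#' regional average and heterogeneity of that measure, plus the number of
#' voxels or grid squares it was computed from. Extends data.frame.
#'
#' @export
setClass("RegionalSummary", contains = "data.frame")

setValidity("RegionalSummary", function(object) {
  msg <- character()
  need <- c("subject", "region", "class", "measure", "average",
            "heterogeneity", "n")
  if (!all(need %in% names(object)))
    return(paste("columns required:", paste(need, collapse = ", ")))
  if (!all(object$class %in% c("cortical", "subcortical")))
    msg <- c(msg, "class must be 'cortical' or 'subcortical'")
  if (!all(object$measure %in% .summaryMeasures))
    msg <- c(msg, paste("measure must be one of",
                        paste(.summaryMeasures, collapse = ", ")))
  key <- paste(object$subject, object$region, object$measure)
  if (anyDuplicated(key))
    msg <- c(msg, "one row per (subject, region, measure) required")
  het <- object$heterogeneity
  if (any(is.finite(het) & het < 0))
    msg <- c(msg, "heterogeneity must be non-negative")
  if (any(is.finite(het) & object$n < 2))
    msg <- c(msg, "rows with finite heterogeneity need n >= 2")
  if (length(msg)) msg else TRUE
})
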
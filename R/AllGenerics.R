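#' Number of measurements in a gradient table
#' @param x a [GradientTable-class]
#' @return integer measurement count
#' @export
setMethod("length", "GradientTable", function(x) length(x@bvals))

#' @rdname GradientTable-accessors
#' @export
setGeneric("bvals", function(x) standardGeneric("bvals"))

#' @rdname GradientTable-accessors
#' @export
setGeneric("bvecs", function(x) standardGeneric("bvecs"))

#' Accessors for gradient tables
#'
#' @param x a [GradientTable-class]
#' @return `bvals()` the numeric b-value vector; `bvecs()` the M x 3
#'   direction matrix.
#' @name GradientTable-accessors
#' @export
setMethod("bvals", "GradientTable", function(x) x@bvals)

#' @rdname GradientTable-accessors
#' @export
setMethod("bvecs", "GradientTable", function(x) x@bvecs)

#' @rdname regionTable
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' Region table of a label volume
#' @param x a [LabelVolume-class]
#' @return data.frame with columns label, name, class
#' @name regionTable
#' @export
setMethod("regionTable", "LabelVolume", function(x) x@regionTable)

#' @rdname mapValues
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' Values array of a scalar map
#' @param x a [ScalarMap-class]
#' @return the 3D numeric array
#' @name mapValues
#' @export
setMethod("mapValues", "ScalarMap", function(x) x@values)

#' Tissue mean squared displacement of a propagator model
#'
#' @param params model parameters (a [BiexpParams-class])
#' @param ... unused
#' @return MSD in mm^2
#' @export
setGeneric("msd", function(params, ...) standardGeneric("msd"))

#' Tissue return-to-origin probability of a propagator model
#'
#' @param params model parameters (a [BiexpParams-class])
#' @param ... unused
#' @return RTOP in mm^-3
#' @export
setGeneric("rtop", function(params, ...) standardGeneric("rtop"))

setMethod("show", "GradientTable", function(object) {
  b <- round(object@bvals)
  shells <- table(factor(ifelse(b <= 50, 0, b)))
  cat("GradientTable with", length(object@bvals), "measurements\n")
  cat("  shells (b s/mm^2):",
      paste(sprintf("%s x%d", names(shells), as.integer(shells)),
            collapse = ", "), "\n")
})

setMethod("show", "DiffusionVolume", function(object) {
  d <- dim(object@signal)
  vx <- voxelSize(object@affine)
  cat(sprintf("DiffusionVolume %d x %d x %d, %d measurements\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size %.3g x %.3g x %.3g mm\n", vx[1], vx[2], vx[3]))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelVolume %d x %d x %d with %d regions\n",
              d[1], d[2], d[3], nrow(object@regionTable)))
  if (nrow(object@regionTable))
    print(object@regionTable, row.names = FALSE)
})

setMethod("show", "ScalarMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("ScalarMap [%s] %d x %d x %d (%d valid voxels)\n",
              object@measure, d[1], d[2], d[3],
              sum(is.finite(object@values))))
})

setMethod("show", "BiexpParams", function(object) {
  cat("BiexpParams\n")
  cat(sprintf("  S0 = %.4g, fIso = %.3f (dIso = %.3g mm^2/s), w = %.3f\n",
              object@S0, object@fIso, object@dIso, object@w))
  cat(sprintf("  fast eigenvalues: %s mm^2/s\n",
              paste(signif(object@lambdaFast, 4), collapse = ", ")))
  cat(sprintf("  slow eigenvalues: %s mm^2/s\n",
              paste(signif(object@lambdaSlow, 4), collapse = ", ")))
  cat(sprintf("  tau = %.4g s\n", object@tau))
})

setMethod("show", "HistologySection", function(object) {
  d <- dim(object@image)
  cat(sprintf("HistologySection %d x %d px at %.3g um/px (%d ROI masks)\n",
              d[1], d[2], object@pixelSize, length(object@roiMasks)))
})

setMethod("show", "CellMask", function(object) {
  cat(sprintf("CellMask: %d cells, %d cell pixels of %d\n",
              object@nCells, sum(object@binary), length(object@binary)))
})
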
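#' Construct a diffusion volume
#'
#' @param signal 4D array (X, Y, Z, measurement)
#' @param gtab matching [GradientTable-class]
#' @param affine 4x4 grid-to-world transform; default is a diagonal affine
#'   built from `voxelMM`
#' @param voxelMM isotropic voxel edge (mm) used when `affine` is missing
#' @return a [DiffusionVolume-class]
#' @export
diffusionVolume <- function(signal, gtab, affine = NULL, voxelMM = 0.8) {
  if (is.null(affine)) affine <- diag(c(rep(voxelMM, 3), 1))
  new("DiffusionVolume", signal = signal, affine = affine, gtab = gtab)
}

#' Read a 4D diffusion volume from NIfTI plus bval/bvec
#'
#' @param niftiPath path to a 4D NIfTI file
#' @param bvalPath,bvecPath FSL-style gradient table files
#' @return a [DiffusionVolume-class]
#' @export
readDiffusionVolume <- function(niftiPath, bvalPath, bvecPath) {
  img <- RNifti::readNifti(niftiPath)
  gtab <- readGradientTable(bvalPath, bvecPath)
  arr <- array(as.numeric(img), dim = dim(img))
  diffusionVolume(arr, gtab, affine = unclass(RNifti::xform(img)))
}

#' Write a diffusion volume to NIfTI (plus bval/bvec sidecars)
#'
#' @param volume a [DiffusionVolume-class]
#' @param niftiPath output NIfTI path (`.nii` or `.nii.gz`)
#' @param writeGradients also write `<stem>.bval` / `<stem>.bvec`
#' @return invisibly, the NIfTI path
#' @export
writeDiffusionVolume <- function(volume, niftiPath, writeGradients = TRUE) {
  vx <- voxelSize(volume@affine)
  img <- RNifti::asNifti(volume@signal)
  RNifti::pixdim(img) <- c(vx, 1)
  RNifti::writeNifti(img, niftiPath)
  if (writeGradients) {
    stem <- sub("\\.nii(\\.gz)?$", "", niftiPath)
    writeGradientTable(volume@gtab, paste0(stem, ".bval"), paste0(stem, ".bvec"))
  }
  invisible(niftiPath)
}

#' Construct a label volume
#'
#' @param labels 3D integer array (0 = background)
#' @param regionSpec data.frame with columns `label`, `name`, `class`
#' @return a [LabelVolume-class]
#' @export
labelVolume <- function(labels, regionSpec) {
  storage.mode(labels) <- "integer"
  regionSpec <- as.data.frame(regionSpec)
  new("LabelVolume", labels = labels,
      regionTable = regionSpec[, c("label", "name", "class")])
}

#' Read an ROI label volume from NIfTI
#'
#' Every nonzero label found in the volume must be declared in
#' `regionSpec`; an undeclared label is a validation error.
#'
#' @param niftiPath path to a 3D integer NIfTI volume
#' @param regionSpec data.frame with columns `label`, `name`, `class`
#' @return a [LabelVolume-class]
#' @export
readLabelVolume <- function(niftiPath, regionSpec) {
  img <- RNifti::readNifti(niftiPath)
  arr <- array(as.integer(round(as.numeric(img))), dim = dim(img)[1:3])
  labelVolume(arr, regionSpec)
}

#' Write an ROI label volume to NIfTI
#' @param labels a [LabelVolume-class]
#' @param niftiPath output path
#' @param voxelMM voxel edge (mm)
#' @return invisibly, the path
#' @export
writeLabelVolume <- function(labels, niftiPath, voxelMM = 0.8) {
  img <- RNifti::asNifti(labels@labels)
  RNifti::pixdim(img) <- rep(voxelMM, 3)
  RNifti::writeNifti(img, niftiPath)
  invisible(niftiPath)
}

#' Write a scalar map to NIfTI
#' @param map a [ScalarMap-class]
#' @param niftiPath output path
#' @param voxelMM voxel edge (mm)
#' @return invisibly, the path
#' @export
writeScalarMap <- function(map, niftiPath, voxelMM = 0.8) {
  img <- RNifti::asNifti(map@values)
  RNifti::pixdim(img) <- rep(voxelMM, 3)
  RNifti::writeNifti(img, niftiPath)
  invisible(niftiPath)
}

#' Read a scalar map from NIfTI
#' @param niftiPath input path
#' @param measure measure name to attach
#' @return a [ScalarMap-class]
#' @export
readScalarMap <- function(niftiPath, measure = "unknown") {
  img <- RNifti::readNifti(niftiPath)
  new("ScalarMap", values = array(as.numeric(img), dim = dim(img)[1:3]),
      measure = measure)
}
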
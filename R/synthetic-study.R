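#' Default region specifications for the nine-region study design
#'
#' Six cortical regions (anterior cingulate gyrus, precentral gyrus,
#' postcentral gyrus, superior temporal gyrus, insula, entorhinal cortex)
#' and three subcortical regions (caudate, putamen, thalamus). Target
#' densities sit in the 0.10-0.17 area-fraction range typical of
#' gray-level-index measurements; density gradients differ across regions
#' so regions span homogeneous (thalamus, putamen) to strongly
#' heterogeneous (entorhinal cortex, precentral gyrus) cytoarchitecture.
#'
#' @param meanCellRadius median cell-body radius (um) applied to all
#'   regions
#' @param sectionMM section edge length in mm
#' @return named list of [regionSpec()] objects
#' @export
defaultRegionSpecs <- function(meanCellRadius = 10, sectionMM = 1.6) {
  mk <- function(name, class, dens, grad)
    regionSpec(name, class, meanCellRadius = meanCellRadius,
               radiusCV = 0.3, targetDensity = dens,
               densityGradient = grad, sectionMM = sectionMM)
  specs <- list(
    mk("ACG",         "cortical",    0.12, 0.8),
    mk("precentral",  "cortical",    0.13, 1.8),
    mk("postcentral", "cortical",    0.12, 1.5),
    mk("STG",         "cortical",    0.11, 1.0),
    mk("insula",      "cortical",    0.12, 1.2),
    mk("entorhinal",  "cortical",    0.14, 2.4),
    mk("caudate",     "subcortical", 0.16, 1.1),
    mk("putamen",     "subcortical", 0.17, 0.3),
    mk("thalamus",    "subcortical", 0.10, 0.5))
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Study design presets
#'
#' Bundles the generator arguments for the two scales the package uses:
#' `"full"` mirrors the acquisition protocol (11 b = 0 + 3 x 60 directions,
#' 6 x 6 x 6-voxel region blocks, 4 um histology pixels), `"reduced"` is
#' the desk-scale design used for replicated end-to-end simulations
#' (6 b = 0 + 3 x 20 directions, 3 x 3 x 3-voxel blocks, 16 um pixels,
#' 4 mm sections giving a 5 x 5 grid of diffusion-voxel-sized squares).
#' Statistical conclusions depend on the coupling and noise settings, not
#' on these sizes; the reduced preset trades per-voxel precision for
#' replicate throughput while keeping enough voxels and grid squares per
#' region (27 and 25) that the regional heterogeneity estimates are not
#' sampling-noise dominated.
#'
#' @param scale `"reduced"` or `"full"`
#' @param kappa density-diffusivity coupling passed to [couplingSpec()]
#' @param noiseSNR Rician b = 0 SNR of the emulated (preprocessed) data
#' @return named list of arguments for [generateStudy()]
#' @export
studyDesign <- function(scale = c("reduced", "full"), kappa = 1.5,
                        noiseSNR = 60) {
  scale <- match.arg(scale)
  if (scale == "full") {
    list(regions = defaultRegionSpecs(meanCellRadius = 10, sectionMM = 1.6),
         coupling = couplingSpec(kappa = kappa, noiseSNR = noiseSNR),
         gtab = studyProtocol(),
         blockSize = c(6, 6, 6), pixelSize = 4)
  } else {
    list(regions = defaultRegionSpecs(meanCellRadius = 32, sectionMM = 4.0),
         coupling = couplingSpec(kappa = kappa, noiseSNR = noiseSNR),
         gtab = studyProtocol(nB0 = 6, dirsPerShell = 20),
         blockSize = c(3, 3, 3), pixelSize = 16)
  }
}

#' Generate a complete synthetic study
#'
#' Emulates the study design: `nSubjects` subjects, each with one
#' multi-shell diffusion volume containing one labeled block per region,
#' one label volume, and one histology section per region. Region
#' parameters receive per-subject multiplicative jitter so subjects
#' cluster by region. All randomness derives from `seed`; a fixed seed
#' reproduces the dataset exactly.
#'
#' @param nSubjects number of subjects (default 4)
#' @param regions named list of [regionSpec()] (default
#'   [defaultRegionSpecs()])
#' @param coupling a [couplingSpec()]
#' @param gtab a [GradientTable-class] (default [studyProtocol()])
#' @param blockSize region block dimensions in voxels (default 6 x 6 x 6)
#' @param pixelSize histology pixel edge (um)
#' @param noiseSD histology additive noise sd
#' @param subjectJitter sd of the per-subject lognormal jitter applied to
#'   each region's target density and density gradient
#' @param voxelMM diffusion voxel edge (mm)
#' @param tau effective diffusion time (s)
#' @param S0 b = 0 signal level
#' @param seed RNG seed (required for reproducibility)
#' @param outDir if non-NULL, write the dataset (NIfTI volumes and labels,
#'   PNG sections and ground-truth masks, CSV ground truth, JSON config
#'   echo) to this directory
#' @return list with `subjects` (per subject: `volume`, `labels`,
#'   `histology` = per region list(section, truthMask, trueDensity),
#'   `diffusionTruth`), `regionTable`, `gtab`, and the echoed generator
#'   configuration
#' @export
generateStudy <- function(nSubjects = 4, regions = defaultRegionSpecs(),
                          coupling = couplingSpec(kappa = 1.5),
                          gtab = studyProtocol(),
                          blockSize = c(6, 6, 6), pixelSize = 4,
                          noiseSD = 0.06, subjectJitter = 0.10,
                          voxelMM = 0.8, tau = 0.030, S0 = 500,
                          seed = 1, outDir = NULL) {
  set.seed(seed)
  subSeeds <- sample.int(.Machine$integer.max, nSubjects)
  nReg <- length(regions)
  regionTab <- data.frame(
    label = seq_len(nReg),
    name = vapply(regions, `[[`, "", "name"),
    class = vapply(regions, `[[`, "", "class"),
    row.names = NULL)
  # block layout: regions tiled on a 3 x 3 grid in-plane, 1-voxel gaps
  ncol3 <- ceiling(sqrt(nReg))
  nrow3 <- ceiling(nReg / ncol3)
  dims <- c(nrow3 * (blockSize[1] + 1) + 1,
            ncol3 * (blockSize[2] + 1) + 1,
            blockSize[3] + 2)
  nVox <- prod(blockSize)
  subjects <- vector("list", nSubjects)
  names(subjects) <- sprintf("sub-%02d", seq_len(nSubjects))
  for (s in seq_len(nSubjects)) {
    set.seed(subSeeds[s])
    labels <- array(0L, dims)
    signal <- array(0, c(dims, length(gtab)))
    histology <- vector("list", nReg)
    names(histology) <- regionTab$name
    truthList <- vector("list", nReg)
    for (k in seq_len(nReg)) {
      spec <- regions[[k]]
      jd <- stats::rlnorm(1, 0, subjectJitter)
      jg <- stats::rlnorm(1, 0, subjectJitter)
      spec$targetDensity <- min(0.85, spec$targetDensity * jd)
      spec$densityGradient <- spec$densityGradient * jg
      ri <- (k - 1) %/% ncol3
      ci <- (k - 1) %% ncol3
      x0 <- ri * (blockSize[1] + 1) + 2
      y0 <- ci * (blockSize[2] + 1) + 2
      z0 <- 2
      xs <- x0:(x0 + blockSize[1] - 1)
      ys <- y0:(y0 + blockSize[2] - 1)
      zs <- z0:(z0 + blockSize[3] - 1)
      labels[xs, ys, zs] <- k
      dr <- generateDiffusionRegion(spec, coupling, gtab, nVox,
                                    S0 = S0, tau = tau,
                                    returnParams = FALSE)
      sig5 <- array(t(dr$signals), c(length(gtab), blockSize))
      signal[xs, ys, zs, ] <- aperm(sig5, c(2, 3, 4, 1))
      hs <- generateHistologySection(spec, pixelSize = pixelSize,
                                     noiseSD = noiseSD,
                                     correlationMM = voxelMM)
      histology[[k]] <- list(section = hs$section,
                             truthMask = hs$truthMask,
                             trueDensity = hs$trueDensity,
                             spec = spec)
      dr$truth$region <- spec$name
      truthList[[k]] <- dr$truth
    }
    subjects[[s]] <- list(
      volume = diffusionVolume(signal, gtab, voxelMM = voxelMM),
      labels = labelVolume(labels, regionTab),
      histology = histology,
      diffusionTruth = do.call(rbind, truthList))
  }
  study <- list(subjects = subjects, regionTable = regionTab, gtab = gtab,
                config = list(nSubjects = nSubjects,
                              coupling = unclass(coupling),
                              blockSize = blockSize, pixelSize = pixelSize,
                              noiseSD = noiseSD,
                              subjectJitter = subjectJitter,
                              voxelMM = voxelMM, tau = tau, S0 = S0,
                              seed = seed,
                              regions = lapply(regions, unclass)))
  if (!is.null(outDir)) writeStudy(study, outDir)
  study
}

#' Write a generated study to disk
#'
#' Per subject: a 4D diffusion NIfTI with bval/bvec sidecars, a label
#' NIfTI, one PNG per histology section plus its ground-truth mask PNG,
#' and a ground-truth CSV; plus a JSON echo of the full generator
#' configuration at the top level.
#'
#' @param study output of [generateStudy()]
#' @param outDir target directory (created if needed)
#' @return invisibly, `outDir`
#' @export
writeStudy <- function(study, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  vx <- study$config$voxelMM
  for (subj in names(study$subjects)) {
    sd <- study$subjects[[subj]]
    writeDiffusionVolume(sd$volume, file.path(outDir, paste0(subj, "_dwi.nii.gz")))
    writeLabelVolume(sd$labels, file.path(outDir, paste0(subj, "_labels.nii.gz")),
                     voxelMM = vx)
    for (rn in names(sd$histology)) {
      h <- sd$histology[[rn]]
      png::writePNG(h$section@image,
                    file.path(outDir, sprintf("%s_%s_section.png", subj, rn)))
      png::writePNG(h$truthMask * 1,
                    file.path(outDir, sprintf("%s_%s_truthmask.png", subj, rn)))
    }
    utils::write.csv(sd$diffusionTruth,
                     file.path(outDir, paste0(subj, "_diffusion_truth.csv")),
                     row.names = FALSE)
  }
  utils::write.csv(study$regionTable, file.path(outDir, "regions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(study$config, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}
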
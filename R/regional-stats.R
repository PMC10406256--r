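#' Regional average of a scalar map
#'
#' Mean of the map over the region's valid voxels; voxels with an invalid
#' fit (NA in the map) are excluded.
#'
#' @param map a [ScalarMap-class] (or 3D array)
#' @param labels a [LabelVolume-class] (or integer 3D array)
#' @param region region label (integer) or region name
#' @return mean value, or NA (with a warning) if the region has no valid
#'   voxel
#' @export
regionalAverage <- function(map, labels, region) {
  vals <- regionValues(map, labels, region)
  if (length(vals) == 0) {
    warning("region has no valid voxels; average is NA")
    return(NA_real_)
  }
  mean(vals)
}

#' Extract a region's valid voxel values
#'
#' @inheritParams regionalAverage
#' @return numeric vector of finite values in the region
#' @export
regionValues <- function(map, labels, region) {
  values <- if (is(map, "ScalarMap")) map@values else map
  lab <- if (is(labels, "LabelVolume")) labels@labels else labels
  if (is.character(region)) {
    if (!is(labels, "LabelVolume"))
      stop("a region name requires a LabelVolume")
    rt <- labels@regionTable
    hit <- rt$label[rt$name == region]
    if (length(hit) != 1L) stop("unknown region name: ", region)
    region <- hit
  }
  v <- values[lab == region]
  v[is.finite(v)]
}

#' Regional heterogeneity: mean absolute pairwise difference
#'
#' The inter-voxel heterogeneity statistic
#' h = (1/N^2) sum_i sum_j |x_i - x_j|, the double sum running over all
#' ordered pairs including i = j (whose terms are zero but are counted in
#' the N^2 denominator). Although described as a "variance", the statistic
#' is a mean absolute difference (the Gini mean difference scaled by
#' (N-1)/N); it has the units of x, is translation invariant and
#' positively homogeneous. Computed via the sorted O(N log N) identity
#' h = (2/N^2) sum_i (2i - N - 1) x_(i), which equals the double loop
#' exactly.
#'
#' @param values numeric vector of N >= 2 region values
#' @return heterogeneity (same units as `values`), or NA for N < 2
#' @export
regionalHeterogeneity <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) return(NA_real_)
  xs <- sort(values)
  i <- seq_len(n)
  sum((2 * i - n - 1) * xs) * 2 / n^2
}

#' Grid-resampled cell area density and its heterogeneity
#'
#' Tiles the section with an axis-aligned grid of squares whose edge
#' matches the diffusion voxel size, anchored at the ROI bounding-box
#' origin. A square qualifies if at least `coverage` of its pixels lie
#' inside the ROI; its density is cell pixels / in-ROI pixels of the
#' square. The regional average is the whole-ROI cell area fraction (not
#' the mean of square densities); the heterogeneity is the population
#' variance of the qualifying squares' densities.
#'
#' @param section a [HistologySection-class]
#' @param mask a [CellMask-class] (or logical matrix)
#' @param region name of the ROI mask in the section (default the first)
#' @param gridMM grid square edge in mm (default 0.8, the diffusion voxel)
#' @param coverage minimum in-ROI fraction for a square to qualify
#' @return list with `average`, `heterogeneity` (NA if fewer than 2
#'   qualifying squares), `squareDensities`, `nSquares`
#' @export
gridCellAreaDensity <- function(section, mask, region = NULL, gridMM = 0.8,
                                coverage = 0.5) {
  binary <- if (is(mask, "CellMask")) mask@binary else mask
  if (is.null(region)) region <- names(section@roiMasks)[1]
  roi <- section@roiMasks[[region]]
  if (is.null(roi)) stop("no ROI mask named '", region, "'")
  sidePx <- round(gridMM * 1000 / section@pixelSize)
  if (sidePx < 2) stop("grid square side must be at least 2 px; ",
                       "pixelSize too coarse for gridMM")
  idx <- which(roi, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty ROI")
  r0 <- min(idx[, 1]); c0 <- min(idx[, 2])
  r1 <- max(idx[, 1]); c1 <- max(idx[, 2])
  dens <- numeric(0)
  for (rs in seq(r0, r1, by = sidePx)) {
    for (cs in seq(c0, c1, by = sidePx)) {
      re <- min(rs + sidePx - 1L, nrow(roi))
      ce <- min(cs + sidePx - 1L, ncol(roi))
      inRoi <- roi[rs:re, cs:ce]
      nIn <- sum(inRoi)
      if (nIn < coverage * sidePx^2) next
      dens <- c(dens, sum(binary[rs:re, cs:ce] & inRoi) / nIn)
    }
  }
  het <- if (length(dens) >= 2L) popVar(dens) else NA_real_
  list(average = cellAreaDensity(binary, roi), heterogeneity = het,
       squareDensities = dens, nSquares = length(dens))
}

#' Assemble the regional summary table for a study
#'
#' One row per (subject, region, measure) with measures FA and TR from the
#' DTI maps, MSD and RTOP from the biexponential maps, and CAD (cell area
#' density) from the segmented histology sections. A missing input flags
#' the affected rows (NA average/heterogeneity) and the run continues.
#'
#' @param maps named list (by subject) of named lists of
#'   [ScalarMap-class] objects (`FA`, `TR`, `MSD`, `RTOP`)
#' @param labels named list (by subject) of [LabelVolume-class]
#' @param histology named list (by subject) of named lists (by region) of
#'   lists with elements `section` ([HistologySection-class]) and `mask`
#'   ([CellMask-class])
#' @param gridMM histology grid square edge in mm
#' @param coverage qualifying-square coverage rule
#' @return a [RegionalSummary-class]
#' @export
buildSummary <- function(maps, labels, histology, gridMM = 0.8,
                         coverage = 0.5) {
  rows <- list()
  for (subj in names(maps)) {
    lv <- labels[[subj]]
    rt <- regionTable(lv)
    for (k in seq_len(nrow(rt))) {
      rn <- rt$name[k]; rc <- rt$class[k]; rl <- rt$label[k]
      for (meas in c("FA", "TR", "MSD", "RTOP")) {
        m <- maps[[subj]][[meas]]
        if (is.null(m) || !any(lv@labels == rl)) {
          rows[[length(rows) + 1L]] <- data.frame(
            subject = subj, region = rn, class = rc, measure = meas,
            average = NA_real_, heterogeneity = NA_real_, n = 0L)
          next
        }
        vals <- regionValues(m, lv, rl)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj, region = rn, class = rc, measure = meas,
          average = if (length(vals)) mean(vals) else NA_real_,
          heterogeneity = regionalHeterogeneity(vals),
          n = length(vals))
      }
      h <- histology[[subj]][[rn]]
      if (is.null(h)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj, region = rn, class = rc, measure = "CAD",
          average = NA_real_, heterogeneity = NA_real_, n = 0L)
      } else {
        g <- gridCellAreaDensity(h$section, h$mask, gridMM = gridMM,
                                 coverage = coverage)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj, region = rn, class = rc, measure = "CAD",
          average = g$average, heterogeneity = g$heterogeneity,
          n = g$nSquares)
      }
    }
  }
  regionalSummary(do.call(rbind, rows))
}
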
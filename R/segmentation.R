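#' Cell-segmentation configuration
#'
#' @param cellRadiusPx expected cell-body radius in pixels; sets the disk
#'   structuring-element radius for the top-hat/bottom-hat stage
#' @param stretchQuantiles lower/upper percentiles of the contrast stretch
#' @param threshold `"otsu"` (histogram-based) or a fixed quantile in
#'   (0, 1) of the enhanced image
#' @param polarity `"dark"` for dark cells on a bright background (Nissl),
#'   `"bright"` for the inverse
#' @param minAreaPx minimum component area in pixels; the default
#'   `pi * (0.25 * cellRadiusPx)^2` suppresses noise specks
#' @param connectivity 4 or 8 (component connectivity)
#' @param minBimodality minimum Otsu effectiveness (between-class over
#'   total variance, in \[0, 1\]) required to segment at all; below it the
#'   histogram shows no object/background separation (a unimodal Gaussian
#'   scores about 0.64) and an empty mask is returned
#' @return list of class `segConfig`
#' @export
segConfig <- function(cellRadiusPx = 3, stretchQuantiles = c(0.01, 0.99),
                      threshold = "otsu", polarity = c("dark", "bright"),
                      minAreaPx = NULL, connectivity = 8L,
                      minBimodality = 0.75) {
  polarity <- match.arg(polarity)
  if (is.null(minAreaPx)) minAreaPx <- pi * (0.25 * cellRadiusPx)^2
  stopifnot(connectivity %in% c(4L, 8L))
  structure(list(cellRadiusPx = cellRadiusPx,
                 stretchQuantiles = stretchQuantiles,
                 threshold = threshold, polarity = polarity,
                 minAreaPx = minAreaPx,
                 connectivity = as.integer(connectivity),
                 minBimodality = minBimodality),
            class = "segConfig")
}

# Otsu effectiveness of a grayscale image: between-class variance at the
# Otsu threshold divided by total variance.
otsuEffectiveness <- function(img) {
  x <- rescale01(img)
  thr <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  lo <- x[x < thr]; hi <- x[x >= thr]
  if (!length(lo) || !length(hi)) return(0)
  w0 <- length(lo) / length(x)
  w0 * (1 - w0) * (mean(hi) - mean(lo))^2 / stats::var(as.vector(x))
}

.brushCache <- new.env(parent = emptyenv())

diskBrush <- function(radiusPx) {
  size <- 2L * max(1L, round(radiusPx)) + 1L
  key <- as.character(size)
  if (is.null(.brushCache[[key]]))
    .brushCache[[key]] <- EBImage::makeBrush(size, shape = "disc")
  .brushCache[[key]]
}

#' Segment cell bodies in a histology section
#'
#' Morphological pipeline, in order: (1) enhancement
#' `image + tophat - bottomhat` with a disk structuring element sized to
#' the expected cell radius; (2) percentile contrast stretch to \[0, 1\];
#' (3) global histogram-based (Otsu) threshold with dark-object polarity;
#' (4) hole filling; (5) removal of components below the minimum area;
#' (6) connected-component labeling.
#'
#' @param section a [HistologySection-class] (or a plain grayscale matrix)
#' @param config a [segConfig()]
#' @return a [CellMask-class]
#' @export
segmentCells <- function(section, config = segConfig()) {
  img <- if (is(section, "HistologySection")) section@image else section
  if (!is.matrix(img)) stop("section image must be a 2D grayscale matrix")
  if (max(img) - min(img) <= 0) {
    warning("constant image: returning an empty cell mask")
    z <- matrix(FALSE, nrow(img), ncol(img))
    return(new("CellMask", binary = z,
               labels = matrix(0L, nrow(img), ncol(img)), nCells = 0L))
  }
  if (otsuEffectiveness(img) < config$minBimodality) {
    # no object/background separation in the histogram: background-only
    z <- matrix(FALSE, nrow(img), ncol(img))
    return(new("CellMask", binary = z,
               labels = matrix(0L, nrow(img), ncol(img)), nCells = 0L))
  }
  br <- diskBrush(config$cellRadiusPx)
  ei <- EBImage::Image(img)
  th <- ei - EBImage::opening(ei, br)          # top-hat (bright detail)
  bh <- EBImage::closing(ei, br) - ei          # bottom-hat (dark detail)
  enhanced <- EBImage::imageData(ei + th - bh)
  q <- stats::quantile(enhanced, config$stretchQuantiles, names = FALSE)
  if (q[2] <= q[1]) q <- range(enhanced)
  enhanced <- pmin(pmax((enhanced - q[1]) / (q[2] - q[1]), 0), 1)
  thr <- if (identical(config$threshold, "otsu"))
    EBImage::otsu(EBImage::Image(enhanced), range = c(0, 1))
  else
    stats::quantile(enhanced, config$threshold, names = FALSE)
  binary <- if (config$polarity == "dark") enhanced < thr else enhanced > thr
  filled <- EBImage::fillHull(EBImage::Image(binary)) > 0
  labels <- labelComponents(filled, config$connectivity)
  if (config$minAreaPx > 0 && max(labels) > 0) {
    sizes <- tabulate(labels[labels > 0], nbins = max(labels))
    drop <- which(sizes < config$minAreaPx)
    if (length(drop)) {
      labels[labels %in% drop] <- 0L
      keep <- sort(setdiff(unique(as.integer(labels)), 0L))
      relut <- integer(max(labels, 1L))
      relut[keep] <- seq_along(keep)
      labels[labels > 0] <- relut[labels[labels > 0]]
    }
  }
  labels <- matrix(as.integer(labels), nrow(img), ncol(img))
  binary <- labels > 0L
  new("CellMask", binary = binary, labels = labels,
      nCells = length(setdiff(unique(as.integer(labels)), 0L)))
}

#' Connected-component labeling with selectable connectivity
#'
#' 4-connected labeling comes from the image backend; 8-connectivity is
#' obtained by union-find merging of 4-connected labels that touch
#' diagonally.
#'
#' @param mask logical matrix
#' @param connectivity 4 or 8
#' @return integer matrix of component labels (0 = background),
#'   consecutively numbered
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (connectivity == 8L && nlab > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
    a2 <- lab[-1, -nc]; b2 <- lab[-nr, -1]    # up-right diagonal
    sel1 <- a1 > 0 & b1 > 0 & a1 != b1
    sel2 <- a2 > 0 & b2 > 0 & a2 != b2
    key <- unique(c(pmin(a1[sel1], b1[sel1]) + pmax(a1[sel1], b1[sel1]) * (nlab + 1),
                    pmin(a2[sel2], b2[sel2]) + pmax(a2[sel2], b2[sel2]) * (nlab + 1)))
    pairs <- cbind(as.integer(key %% (nlab + 1)),
                   as.integer(key %/% (nlab + 1)))
    if (nrow(pairs)) {
      parent <- seq_len(nlab)
      find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(nlab), find, integer(1))
      lab[lab > 0] <- root[lab[lab > 0]]
    }
  }
  keep <- sort(setdiff(unique(as.integer(lab)), 0L))
  if (length(keep) && !identical(keep, seq_along(keep))) {
    relut <- integer(max(keep))
    relut[keep] <- seq_along(keep)
    lab[lab > 0] <- relut[lab[lab > 0]]
  }
  lab
}

#' Laplacian-of-Gaussian edge contours for QC overlays
#'
#' Used only to draw cell-body outlines on overlay images; never alters
#' the segmentation mask.
#'
#' @param img grayscale matrix
#' @param sigma Gaussian scale in pixels
#' @return logical matrix of zero-crossing edge pixels
#' @export
logEdges <- function(img, sigma = 2) {
  sz <- 2L * ceiling(3 * sigma) + 1L
  x <- seq(-(sz %/% 2), sz %/% 2)
  g <- outer(x, x, function(u, v)
    (u^2 + v^2 - 2 * sigma^2) / sigma^4 * exp(-(u^2 + v^2) / (2 * sigma^2)))
  g <- g - mean(g)
  resp <- EBImage::imageData(EBImage::filter2(EBImage::Image(img), g))
  pos <- resp > 0
  edge <- matrix(FALSE, nrow(img), ncol(img))
  edge[-1, ] <- edge[-1, ] | (pos[-1, ] != pos[-nrow(img), ])
  edge[, -1] <- edge[, -1] | (pos[, -1] != pos[, -ncol(img)])
  edge
}

#' Cell area density inside an ROI
#'
#' Fraction of the ROI's pixels covered by segmented cell bodies.
#'
#' @param mask a [CellMask-class] (or logical matrix)
#' @param roi logical ROI mask of the same shape
#' @return fraction in \[0, 1\]
#' @export
cellAreaDensity <- function(mask, roi) {
  binary <- if (is(mask, "CellMask")) mask@binary else mask
  if (!all(dim(binary) == dim(roi))) stop("mask and roi shapes differ")
  nRoi <- sum(roi)
  if (nRoi == 0) stop("empty ROI: cell area density undefined")
  sum(binary & roi) / nRoi
}

#' Dice similarity coefficient of two binary masks
#'
#' 2 |A intersect B| / (|A| + |B|); defined as 1 when both masks are
#' empty.
#'
#' @param a,b logical masks of the same shape
#' @return Dice coefficient in \[0, 1\]
#' @export
dice <- function(a, b) {
  if (is(a, "CellMask")) a <- a@binary
  if (is(b, "CellMask")) b <- b@binary
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Absolute error between automated and manual cell area density
#'
#' @param autoDensity,manualDensity densities in \[0, 1\] (vectorized; the
#'   mean of the per-sample absolute errors is the study's QC statistic)
#' @return absolute difference(s)
#' @export
densityError <- function(autoDensity, manualDensity) {
  stopifnot(all(autoDensity >= 0 & autoDensity <= 1),
            all(manualDensity >= 0 & manualDensity <= 1))
  abs(autoDensity - manualDensity)
}
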
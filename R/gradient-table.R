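#' Construct a gradient table
#'
#' Directions attached to diffusion-weighted rows (b > 0) are renormalized
#' to unit length; directions of b = 0 rows are zeroed (they carry no
#' information).
#'
#' @param bvals numeric vector of b-values (s/mm^2)
#' @param bvecs M x 3 matrix of gradient directions
#' @return a [GradientTable-class]
#' @examples
#' gt <- gradientTable(c(0, 1000), rbind(c(0, 0, 0), c(2, 0, 0)))
#' bvecs(gt)[2, ]  # renormalized to (1, 0, 0)
#' @export
gradientTable <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != length(bvals))
    stop("gradient table length mismatch: ", length(bvals), " b-values vs ",
         nrow(bvecs), " directions")
  if (any(!is.finite(bvals)) || any(!is.finite(bvecs)))
    stop("gradient table contains non-numeric or non-finite entries")
  dw <- bvals > 0
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(dw & nrm == 0))
    stop("zero direction vector on a diffusion-weighted (b > 0) row")
  bvecs[dw, ] <- bvecs[dw, , drop = FALSE] / nrm[dw]
  bvecs[!dw, ] <- 0
  dimnames(bvecs) <- NULL
  new("GradientTable", bvals = bvals, bvecs = bvecs)
}

#' Read an FSL-style bval/bvec pair
#'
#' The bvec file may be laid out as 3 rows x M columns (the FSL dialect) or
#' M rows x 3 columns; the orientation is auto-detected from which axis has
#' length 3 (a 3 x 3 file is assumed to be FSL 3 x M).
#'
#' @param bvalPath path to a whitespace-separated b-value file
#' @param bvecPath path to the matching direction file
#' @return a [GradientTable-class]
#' @export
readGradientTable <- function(bvalPath, bvecPath) {
  parseNum <- function(path) {
    tok <- scan(path, what = character(), quiet = TRUE)
    x <- suppressWarnings(as.numeric(tok))
    if (any(is.na(x)))
      stop("non-numeric token in ", path, ": ",
           paste(utils::head(tok[is.na(x)], 3), collapse = " "))
    x
  }
  bvals <- parseNum(bvalPath)
  lines <- readLines(bvecPath)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    x <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    if (any(is.na(x))) stop("non-numeric token in ", bvecPath)
    x
  })
  ncols <- unique(vapply(rows, length, integer(1)))
  if (length(ncols) != 1L)
    stop("ragged bvec file: ", bvecPath)
  m <- do.call(rbind, rows)
  if (nrow(m) == 3L) {
    bvecs <- t(m)            # FSL 3 x M (also covers the ambiguous 3 x 3)
  } else if (ncols == 3L) {
    bvecs <- m               # M x 3
  } else {
    stop("bvec file must be 3 x M or M x 3, got ", nrow(m), " x ", ncols)
  }
  if (nrow(bvecs) != length(bvals))
    stop("gradient table length mismatch: ", length(bvals),
         " b-values vs ", nrow(bvecs), " directions")
  gradientTable(bvals, bvecs)
}

#' Write a gradient table as FSL bval/bvec files
#'
#' @param gtab a [GradientTable-class]
#' @param bvalPath,bvecPath output paths (bvec written in the FSL 3 x M
#'   layout)
#' @return invisibly, the gradient table
#' @export
writeGradientTable <- function(gtab, bvalPath, bvecPath) {
  writeLines(paste(format(gtab@bvals, trim = TRUE), collapse = " "), bvalPath)
  writeLines(apply(t(gtab@bvecs), 1, function(r)
    paste(format(r, trim = TRUE, digits = 12), collapse = " ")), bvecPath)
  invisible(gtab)
}

#' The multi-shell acquisition protocol used throughout the study
#'
#' Eleven b = 0 measurements plus three shells (b = 1000, 2000,
#' 3000 s/mm^2) of 60 directions each (191 measurements). Directions are
#' quasi-uniform points on the sphere from a deterministic Fibonacci
#' spiral, so the table is reproducible without a randomness source.
#'
#' @param nB0 number of b = 0 measurements (default 11)
#' @param dirsPerShell directions per nonzero shell (default 60)
#' @param shells nonzero b-values (default 1000, 2000, 3000)
#' @return a [GradientTable-class]
#' @export
studyProtocol <- function(nB0 = 11, dirsPerShell = 60,
                          shells = c(1000, 2000, 3000)) {
  dirs <- fibonacciSphere(dirsPerShell)
  bvals <- c(rep(0, nB0), rep(shells, each = dirsPerShell))
  bvecs <- rbind(matrix(0, nB0, 3),
                 do.call(rbind, rep(list(dirs), length(shells))))
  gradientTable(bvals, bvecs)
}

# Quasi-uniform unit vectors via the Fibonacci (golden-angle) spiral.
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}
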
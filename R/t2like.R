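#' Synthesize a T2-like contrast from a T1-like image
#'
#' Applies, in order: intensity reversal (`max(I) - I`), log enhancement
#' (`log(1 + I')` rescaled to \[0, 1\]), and discrete histogram
#' equalization. The output lives in \[0, 1\] and its intensity rank order
#' is the reverse of the input's, which makes a T1-weighted image resemble
#' a T2-weighted (and b = 0 diffusion) contrast for registration purposes.
#'
#' The equalization is the classic discrete CDF mapping: each gray level v
#' maps to the empirical cumulative probability of values <= v, so the
#' output histogram is as uniform as the input's tie structure allows.
#'
#' @param t1Image 2D or 3D array of finite, non-negative intensities
#' @param levels number of gray levels used to bin intensities for the
#'   equalization step (default 256)
#' @return array of the same shape with values in \[0, 1\]
#' @export
synthesizeT2Like <- function(t1Image, levels = 256L) {
  x <- t1Image
  if (any(!is.finite(x)) || any(x < 0))
    stop("input intensities must be finite and non-negative")
  if (max(x) - min(x) <= 0) {
    warning("constant input image: histogram equalization undefined, returning 0.5")
    return(x * 0 + 0.5)
  }
  rev <- max(x) - x                      # intensity reversal
  enh <- rescale01(log1p(rev))           # log enhancement, rescaled
  histEqualize(enh, levels = levels)
}

#' Discrete histogram equalization
#'
#' Maps each value to the empirical CDF of its (binned) gray level. An
#' image whose histogram is already uniform is (up to one gray level) a
#' fixed point.
#'
#' @param img array with values in \[0, 1\]
#' @param levels number of gray-level bins
#' @return array of the same shape, values in (0, 1\]
#' @export
histEqualize <- function(img, levels = 256L) {
  lv <- pmin(levels - 1L, as.integer(floor(img * levels)))  # 0 .. levels-1
  counts <- tabulate(lv + 1L, nbins = levels)
  cdf <- cumsum(counts) / length(lv)
  out <- cdf[lv + 1L]
  if (is.null(dim(img))) out else array(out, dim = dim(img))
}
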
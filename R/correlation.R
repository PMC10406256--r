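#' Pearson correlation with exact t-based p-value
#'
#' Sample Pearson r with a two-sided p-value from
#' t = r sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom (the exact
#' small-sample null distribution; study group sizes are 12-36 points, too
#' small for the Fisher-z approximation).
#'
#' @param x,y numeric vectors of equal length n >= 3, both non-constant
#' @return list with `r`, `p`, `n`
#' @export
pearsonCorr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("Pearson correlation needs at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Pearson correlation undefined for a constant input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values with monotonicity enforcement;
#' order-preserving in the sense that the step-up rejection set at any
#' threshold is reproduced by thresholding the q-values.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\]
#' @return q-values, same length and order
#' @export
fdrBH <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Ordinary least squares with a pointwise confidence band
#'
#' @param x,y numeric vectors, n >= 3, x non-degenerate
#' @param level confidence level for the mean-response band
#' @param gridN number of x grid points for the band
#' @return list with `slope`, `intercept`, `grid` (data.frame of x, fit,
#'   lower, upper, halfWidth)
#' @export
linearFitWithBand <- function(x, y, level = 0.95, gridN = 50L) {
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need n >= 3 paired points")
  if (stats::sd(x) == 0) stop("degenerate x: no spread")
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  xg <- seq(min(x), max(x), length.out = gridN)
  pr <- stats::predict(fit, newdata = data.frame(x = xg),
                       interval = "confidence", level = level)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       grid = data.frame(x = xg, fit = pr[, "fit"], lower = pr[, "lwr"],
                         upper = pr[, "upr"],
                         halfWidth = (pr[, "upr"] - pr[, "lwr"]) / 2))
}

widen <- function(table, measure, stat = c("heterogeneity", "average")) {
  stat <- match.arg(stat)
  sel <- table[table$measure == measure, ]
  data.frame(subject = sel$subject, region = sel$region, class = sel$class,
             value = sel[[stat]])
}

corRow <- function(pair, group, x, y) {
  res <- tryCatch(pearsonCorr(x, y), error = function(e) NULL)
  if (is.null(res))
    return(data.frame(pair = pair, group = group, n = sum(is.finite(x + y)),
                      r = NA_real_, p = NA_real_, q = NA_real_,
                      slope = NA_real_, intercept = NA_real_))
  lf <- linearFitWithBand(x[is.finite(x + y)], y[is.finite(x + y)])
  data.frame(pair = pair, group = group, n = res$n, r = res$r, p = res$p,
             q = NA_real_, slope = lf$slope, intercept = lf$intercept)
}

#' Run the study's correlation design on a regional summary table
#'
#' Heterogeneity family: heterogeneity of cell area density (hCAD) against
#' the heterogeneity of each dMRI measure (hFA, hTR, hMSD, hRTOP), pooled
#' over all (subject, region) points, plus the same pairs split by region
#' class. Average family: average CAD against each average dMRI measure,
#' computed separately within the cortical and subcortical groups (the two
#' classes differ too much cytoarchitecturally to pool). FDR is applied
#' within each (family, group) of four tests by default, or globally.
#'
#' @param table a [RegionalSummary-class]
#' @param fdrScope `"per-family"` (default) or `"global"`
#' @return data.frame with one row per (pair, group): n, r, p, q, slope,
#'   intercept
#' @export
runStudyCorrelations <- function(table, fdrScope = c("per-family", "global")) {
  fdrScope <- match.arg(fdrScope)
  validObject(table)
  dmri <- c("FA", "TR", "MSD", "RTOP")
  cad <- widen(table, "CAD", "heterogeneity")
  cadAvg <- widen(table, "CAD", "average")
  out <- list()
  for (grp in c("all", "cortical", "subcortical")) {
    for (m in dmri) {
      mv <- widen(table, m, "heterogeneity")
      stopifnot(identical(mv$region, cad$region),
                identical(mv$subject, cad$subject))
      keep <- if (grp == "all") rep(TRUE, nrow(cad)) else cad$class == grp
      out[[length(out) + 1L]] <-
        corRow(paste0("hCAD-h", m), paste0("het-", grp),
               cad$value[keep], mv$value[keep])
    }
  }
  for (grp in c("cortical", "subcortical")) {
    for (m in dmri) {
      mv <- widen(table, m, "average")
      keep <- cadAvg$class == grp
      out[[length(out) + 1L]] <-
        corRow(paste0("avgCAD-avg", m), paste0("avg-", grp),
               cadAvg$value[keep], mv$value[keep])
    }
  }
  res <- do.call(rbind, out)
  if (fdrScope == "global") {
    ok <- is.finite(res$p)
    res$q[ok] <- fdrBH(res$p[ok])
  } else {
    for (g in unique(res$group)) {
      ok <- res$group == g & is.finite(res$p)
      res$q[ok] <- fdrBH(res$p[ok])
    }
  }
  res
}

#' Check for an effect of regional volume on average cell area density
#'
#' Pearson correlation between per-(subject, region) voxel counts and the
#' regional average cell area density; a significant correlation would
#' mean region size confounds the density comparisons.
#'
#' @param table a [RegionalSummary-class]
#' @param volumes data.frame with columns `subject`, `region`, `voxels`
#' @return list with `r`, `p`, `n` (or an error if volumes are constant)
#' @export
volumeEffectCheck <- function(table, volumes) {
  cad <- widen(table, "CAD", "average")
  key <- paste(cad$subject, cad$region)
  vkey <- paste(volumes$subject, volumes$region)
  v <- volumes$voxels[match(key, vkey)]
  if (any(is.na(v))) stop("volumes missing for some (subject, region)")
  if (stats::sd(v) == 0)
    stop("not testable: regional volumes are constant")
  pearsonCorr(v, cad$value)
}

#' Scatter plot of one correlation with regression line and band
#'
#' Writes a PNG mirroring the study's presentation: per-region color
#' coding, OLS line, and a shaded pointwise 95% confidence band.
#'
#' @param x,y paired values
#' @param region factor/character of per-point region names (colors)
#' @param path output PNG path
#' @param xlab,ylab axis labels
#' @return invisibly, the path
#' @export
plotCorrelation <- function(x, y, region, path, xlab = "histology",
                            ylab = "dMRI") {
  lf <- linearFitWithBand(x, y)
  pc <- pearsonCorr(x, y)
  grDevices::png(path, width = 700, height = 600)
  on.exit(grDevices::dev.off())
  cols <- grDevices::rainbow(length(unique(region)))[as.integer(factor(region))]
  plot(x, y, pch = 19, col = cols, xlab = xlab, ylab = ylab)
  graphics::polygon(c(lf$grid$x, rev(lf$grid$x)),
                    c(lf$grid$lower, rev(lf$grid$upper)),
                    col = grDevices::adjustcolor("gray", 0.5), border = NA)
  graphics::abline(lf$intercept, lf$slope, lwd = 2)
  graphics::points(x, y, pch = 19, col = cols)
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("r = %.2f, p = %.2g", pc$r, pc$p))
  invisible(path)
}
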
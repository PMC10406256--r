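#' Fit the diffusion tensor model
#'
#' Fits the single-tensor (mono-exponential Gaussian) model to the b = 0
#' and b = 1000 s/mm^2 shells by weighted linear least squares on the
#' log-signal: an ordinary LLS pass followed by one reweighting pass with
#' weights equal to the squared predicted signal. Higher shells are
#' ignored. Negative eigenvalues are clamped to zero and the voxel flagged.
#'
#' @param volume a [DiffusionVolume-class]
#' @param mask logical 3D array of voxels to fit (default: all)
#' @param maxB largest b-value included in the fit (default 1000; values
#'   within 10% are accepted to absorb scanner rounding)
#' @return a `DtiFit` list with elements
#'   \describe{
#'     \item{S0}{3D array of fitted b = 0 signal}
#'     \item{tensor}{X x Y x Z x 6 array of (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)}
#'     \item{eigenvalues}{X x Y x Z x 3 array, sorted decreasing, clamped at 0}
#'     \item{eigenvectors}{X x Y x Z x 3 x 3 array (columns = eigenvectors)}
#'     \item{valid}{logical 3D array, FALSE where the fit failed}
#'     \item{clamped}{logical 3D array, TRUE where eigenvalues were clamped}
#'   }
#' @export
fitDTI <- function(volume, mask = NULL, maxB = 1000) {
  gtab <- volume@gtab
  sel <- shellOf(gtab@bvals) <= maxB * 1.1
  if (sum(sel) < 7L)
    stop("DTI needs at least 7 measurements with b <= ", maxB)
  if (!any(gtab@bvals[sel] > .B0_THRESHOLD))
    stop("DTI needs at least one diffusion-weighted (b > 0) measurement")
  if (!any(gtab@bvals[sel] <= .B0_THRESHOLD))
    stop("DTI needs at least one b = 0 measurement")
  b <- gtab@bvals[sel]
  g <- gtab@bvecs[sel, , drop = FALSE]
  # design matrix for log S = log S0 - b g' D g
  X <- cbind(1,
             -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2],
             -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  dims <- dim(volume@signal)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  nv <- prod(dims)
  sig <- matrix(volume@signal, nrow = nv, ncol = dim(volume@signal)[4])[, sel, drop = FALSE]
  idx <- which(as.vector(mask))

  S0 <- array(NA_real_, dims)
  tensor <- array(NA_real_, c(dims, 6))
  evals <- array(NA_real_, c(dims, 3))
  evecs <- array(NA_real_, c(dims, 3, 3))
  valid <- array(FALSE, dims)
  clamped <- array(FALSE, dims)

  tn <- matrix(tensor, nv, 6)
  ev <- matrix(evals, nv, 3)
  vc <- matrix(evecs, nv, 9)
  s0v <- as.vector(S0); vv <- as.vector(valid); cv <- as.vector(clamped)

  XtX <- crossprod(X)
  for (i in idx) {
    s <- sig[i, ]
    if (any(!is.finite(s)) || any(s <= 0)) next
    y <- log(s)
    beta <- tryCatch(solve(XtX, crossprod(X, y)), error = function(e) NULL)
    if (is.null(beta)) next
    # one reweighting pass: weights = squared predicted signal
    wts <- as.vector(exp(X %*% beta))^2
    Xw <- X * wts
    beta <- tryCatch(solve(crossprod(X, Xw), crossprod(Xw, y)),
                     error = function(e) beta)
    D <- matrix(c(beta[2], beta[5], beta[6],
                  beta[5], beta[3], beta[7],
                  beta[6], beta[7], beta[4]), 3, 3)
    e <- eigen(D, symmetric = TRUE)
    lam <- e$values
    if (any(lam < 0)) { cv[i] <- TRUE; lam <- pmax(lam, 0) }
    s0v[i] <- exp(beta[1])
    tn[i, ] <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
    ev[i, ] <- lam
    vc[i, ] <- as.vector(e$vectors)
    vv[i] <- TRUE
  }
  structure(list(S0 = array(s0v, dims),
                 tensor = array(tn, c(dims, 6)),
                 eigenvalues = array(ev, c(dims, 3)),
                 eigenvectors = array(vc, c(dims, 3, 3)),
                 valid = array(vv, dims),
                 clamped = array(cv, dims)),
            class = "DtiFit")
}

#' Fractional anisotropy from tensor eigenvalues
#'
#' FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||; 0 for an
#' all-zero tensor by convention.
#'
#' @param eigenvalues numeric length-3 vector, or an N x 3 matrix for many
#'   voxels
#' @return FA value(s) in \[0, 1\]
#' @export
fa <- function(eigenvalues) {
  lam <- if (is.matrix(eigenvalues)) eigenvalues else matrix(eigenvalues, 1)
  if (ncol(lam) != 3L) stop("eigenvalues must have 3 components")
  lbar <- rowMeans(lam)
  num <- sqrt(rowSums((lam - lbar)^2))
  den <- sqrt(rowSums(lam^2))
  out <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
  out <- pmin(out, 1)
  if (is.matrix(eigenvalues)) out else out[[1]]
}

#' Tensor trace from eigenvalues
#'
#' The sum of the three eigenvalues (equivalently Dxx + Dyy + Dzz), i.e.
#' three times the mean diffusivity; reported un-divided, as "trace".
#'
#' @param eigenvalues numeric length-3 vector or N x 3 matrix
#' @return trace in mm^2/s
#' @export
traceMeasure <- function(eigenvalues) {
  lam <- if (is.matrix(eigenvalues)) eigenvalues else matrix(eigenvalues, 1)
  if (ncol(lam) != 3L) stop("eigenvalues must have 3 components")
  out <- rowSums(lam)
  if (is.matrix(eigenvalues)) out else out[[1]]
}

#' FA and trace maps from a DTI fit
#'
#' @param fit a `DtiFit` from [fitDTI()]
#' @return named list of [ScalarMap-class] objects `FA` and `TR`; voxels
#'   with an invalid fit are NA
#' @export
dtiScalarMaps <- function(fit) {
  dims <- dim(fit$valid)
  lam <- matrix(fit$eigenvalues, prod(dims), 3)
  ok <- as.vector(fit$valid) & rowSums(is.finite(lam)) == 3
  fav <- trv <- rep(NA_real_, prod(dims))
  fav[ok] <- fa(lam[ok, , drop = FALSE])
  trv[ok] <- traceMeasure(lam[ok, , drop = FALSE])
  list(FA = new("ScalarMap", values = array(fav, dims), measure = "FA"),
       TR = new("ScalarMap", values = array(trv, dims), measure = "TR"))
}
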
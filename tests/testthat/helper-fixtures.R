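# Shared fixtures and independent oracles for the test suite.

# A small multi-shell gradient table (enough for both model fits).
smallProtocol <- function(nB0 = 3, dirsPerShell = 12)
  studyProtocol(nB0 = nB0, dirsPerShell = dirsPerShell)

# O(N^2) double-loop evaluation of the inter-voxel heterogeneity statistic,
# exactly as printed: (1/N^2) sum_i sum_j |x_i - x_j| including i = j.
heterogeneityDoubleLoop <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / n^2
}

# Faster but still independent oracle (outer, no sorting identity).
heterogeneityOuter <- function(x) mean(abs(outer(x, x, "-")))

# Closed-form mean of a Rician(nu, sigma) via the Laguerre polynomial
# L_{1/2}, using exponentially scaled Bessel functions for stability.
ricianMean <- function(nu, sigma) {
  x <- -nu^2 / (2 * sigma^2)
  z <- -x / 2
  l12 <- (1 - x) * besselI(z, 0, expon.scaled = TRUE) -
    x * besselI(z, 1, expon.scaled = TRUE)
  sigma * sqrt(pi / 2) * l12           # scaling: e^{x/2} * e^{z} = 1
}

# RTOP of one Gaussian compartment by numerical quadrature of its
# q-space characteristic function (product of three 1D integrals in the
# eigenframe).
rtopQuadrature <- function(lambda, tau) {
  prod(vapply(lambda, function(l)
    stats::integrate(function(q) exp(-4 * pi^2 * tau * l * q^2),
                     -Inf, Inf)$value, numeric(1)))
}

# Monte-Carlo MSD of a two-compartment Gaussian-mixture propagator.
msdMonteCarlo <- function(w, lambdaFast, lambdaSlow, tau, n = 1e5) {
  nf <- stats::rbinom(1, n, w)
  sf <- matrix(stats::rnorm(3 * nf), ncol = 3) %*%
    diag(sqrt(2 * tau * lambdaFast))
  ss <- matrix(stats::rnorm(3 * (n - nf)), ncol = 3) %*%
    diag(sqrt(2 * tau * lambdaSlow))
  (sum(sf^2) + sum(ss^2)) / n
}

# Hand-rolled Benjamini-Hochberg step-up: reject the largest k with
# p_(k) <= k/m * alpha; q_i is the smallest alpha at which i is rejected.
bhStepUp <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

randomBiexpParams <- function() {
  shape <- sort(stats::runif(3, 0.3, 2.2), decreasing = TRUE)
  shape <- 3 * shape / sum(shape)
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  biexpParams(S0 = stats::runif(1, 50, 500),
              fIso = stats::runif(1, 0, 0.3),
              w = stats::runif(1, 0.2, 0.8),
              lambdaFast = stats::runif(1, 0.8e-3, 2e-3) * shape,
              lambdaSlow = stats::runif(1, 0.1e-3, 0.5e-3) * shape,
              frame = R, tau = 0.030)
}

# A tiny valid regional summary table: ns subjects x regions (first 2/3
# cortical), all five measures.
toySummary <- function(nSubj = 2, regions = c("a", "b", "c"),
                       classes = c("cortical", "cortical", "subcortical"),
                       seed = 1) {
  set.seed(seed)
  rows <- expand.grid(subject = sprintf("s%d", seq_len(nSubj)),
                      region = regions,
                      measure = c("FA", "TR", "MSD", "RTOP", "CAD"),
                      stringsAsFactors = FALSE)
  rows$class <- classes[match(rows$region, regions)]
  rows$average <- stats::runif(nrow(rows))
  rows$heterogeneity <- stats::runif(nrow(rows))
  rows$n <- 10L
  regionalSummary(rows)
}
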
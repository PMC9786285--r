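# Small multivariate / heavy-tail density and sampling primitives used by
# the Poisson-lognormal sampler. Kept internal: parameterisations are
# documented here once and relied on throughout.
#
#   inverse-gamma(shape a, rate b):  p(x) = b^a/Gamma(a) x^{-a-1} e^{-b/x}
#   half-Cauchy(scale s), x > 0:     p(x) = 2 / (pi s (1 + (x/s)^2))
#   inverse-Wishart(Psi, nu):        E[X] = Psi / (nu - d - 1)

dinvgamma_log <- function(x, shape, rate) {
  ifelse(x > 0,
         shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x,
         -Inf)
}

dhalfcauchy_log <- function(x, scale) {
  ifelse(x > 0,
         log(2) - log(pi) - log(scale) - log1p((x / scale)^2),
         -Inf)
}

# log density of MVN via Cholesky; returns -Inf for non-PD sigma
dmvnorm_log <- function(x, mean, sigma) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  d <- length(x)
  z <- backsolve(ch, x - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# one MVN draw given mean and covariance (or precomputed upper Cholesky)
rmvnorm1 <- function(mean, sigma = NULL, chol_sigma = NULL) {
  if (is.null(chol_sigma)) chol_sigma <- chol(sigma)
  as.numeric(mean + crossprod(chol_sigma, stats::rnorm(length(mean))))
}

# draw from the conditional MVN with precision P and "shift" b, i.e.
# N(P^{-1} b, P^{-1}); the workhorse of every conjugate Gibbs block
rmvnorm_canonical <- function(P, b) {
  ch <- chol(P)                       # P = ch' ch
  m <- backsolve(ch, backsolve(ch, b, transpose = TRUE))
  as.numeric(m + backsolve(ch, stats::rnorm(length(b))))
}

log_multigamma <- function(a, d) {
  d * (d - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(d)) / 2))
}

# Wishart(df nu, scale V) draw via Bartlett decomposition
rwishart1 <- function(nu, V) {
  d <- nrow(V)
  A <- matrix(0, d, d)
  diag(A) <- sqrt(stats::rchisq(d, df = nu - seq_len(d) + 1))
  if (d > 1) A[upper.tri(A)] <- stats::rnorm(d * (d - 1) / 2)
  ch <- chol(V)
  W <- crossprod(A %*% ch)
  (W + t(W)) / 2
}

# inverse-Wishart(Psi, nu) draw: X^{-1} ~ Wishart(nu, Psi^{-1})
rinvwishart1 <- function(nu, Psi) {
  W <- rwishart1(nu, chol2inv(chol(Psi)))
  S <- chol2inv(chol(W))
  (S + t(S)) / 2
}

dinvwishart_log <- function(X, Psi, nu) {
  d <- nrow(X)
  chX <- tryCatch(chol(X), error = function(e) NULL)
  if (is.null(chX)) return(-Inf)
  ldX <- 2 * sum(log(diag(chX)))
  ldPsi <- 2 * sum(log(diag(chol(Psi))))
  tr <- sum(diag(Psi %*% chol2inv(chX)))
  nu / 2 * ldPsi - nu * d / 2 * log(2) - log_multigamma(nu / 2, d) -
    (nu + d + 1) / 2 * ldX - 0.5 * tr
}

# univariate slice sampler (Neal 2003, stepping out + shrinkage) on an
# unnormalised log density; used for the heavy-tailed tau hyper-scales
slice_sample1 <- function(x0, log_f, w = 1, max_steps = 50) {
  y <- log_f(x0) - stats::rexp(1)
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  j <- floor(max_steps * stats::runif(1))
  k <- max_steps - 1 - j
  while (j > 0 && y < log_f(L)) { L <- L - w; j <- j - 1 }
  while (k > 0 && y < log_f(R)) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (y < log_f(x1)) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}
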
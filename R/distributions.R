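# Distribution primitives used across the sampler and the evidence
# estimators: robust one-sided truncated-normal draws, Genz-style
# quasi-Monte-Carlo orthant probabilities for the truncated multivariate
# normal, and inverse-gamma density/draws. Hand-written because no installed
# package provides them.

#' Draw from a normal distribution truncated below
#'
#' Inverse-CDF sampling in the well-conditioned regime; Robert's translated
#' exponential rejection sampler in the deep lower tail (where the CDF
#' saturates numerically).
#'
#' @param n number of draws.
#' @param mean,sd normal parameters (scalars or vectors of length `n`).
#' @param lower truncation bound (draws satisfy `x >= lower`).
#' @return Numeric vector of length `n`.
#' @export
rtnorm_lower <- function(n, mean = 0, sd = 1, lower = 0) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  a <- (lower - mean) / sd
  x <- numeric(n)
  easy <- a < 5
  if (any(easy)) {
    pa <- stats::pnorm(a[easy])
    u <- stats::runif(sum(easy), pa, 1)
    # guard against u == 1 rounding
    u <- pmin(u, 1 - 1e-16)
    x[easy] <- stats::qnorm(u)
  }
  if (any(!easy)) {
    # Robert (1995): optimal translated exponential proposal
    ah <- a[!easy]
    lambda <- (ah + sqrt(ah^2 + 4)) / 2
    m <- sum(!easy)
    z <- numeric(m)
    todo <- rep(TRUE, m)
    while (any(todo)) {
      k <- sum(todo)
      cand <- ah[todo] + stats::rexp(k, rate = lambda[todo])
      acc <- stats::runif(k) <= exp(-(cand - lambda[todo])^2 / 2)
      z[todo][acc] <- cand[acc]
      todo[todo] <- !acc
    }
    x[!easy] <- z
  }
  mean + sd * x
}

#' Log density of a univariate normal truncated below
#' @noRd
dtnorm_lower_log <- function(x, mean, sd, lower = 0) {
  ifelse(x < lower, -Inf,
         stats::dnorm(x, mean, sd, log = TRUE) -
           stats::pnorm(lower, mean, sd, lower.tail = FALSE, log.p = TRUE))
}

# ---- quasi-Monte-Carlo orthant probability (Genz 1992 transform) ----------

.halton_cache <- new.env(parent = emptyenv())

# Halton sequence in [0,1)^d with a fixed random shift (Cranley-Patterson
# rotation) so the estimate is reproducible for a fixed scramble seed.
halton_matrix <- function(n, d, shift = NULL) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19)
  if (d > length(primes)) stop("Halton sequence limited to dimension 8")
  key <- paste0("h", n, "_", d)
  H <- get0(key, envir = .halton_cache)
  if (is.null(H)) {
    H <- vapply(seq_len(d), function(j) {
      b <- primes[j]
      k <- seq_len(n) + 20L  # drop leading points, standard burn
      r <- numeric(n)
      f <- 1 / b
      kk <- k
      while (any(kk > 0)) {
        r <- r + f * (kk %% b)
        kk <- kk %/% b
        f <- f / b
      }
      r
    }, numeric(n))
    assign(key, H, envir = .halton_cache)
  }
  if (!is.null(shift)) H <- (H + matrix(shift, n, d, byrow = TRUE)) %% 1
  H
}

#' Probability of the non-negative orthant under a multivariate normal
#'
#' \eqn{P(X \ge 0)} for \eqn{X \sim N(\mu, \Sigma)}, computed by the
#' separation-of-variables transform of Genz with a shifted Halton sequence
#' (fixed scramble seed, so the estimate is deterministic). Exact in
#' dimension 1 (normal tail) and 2 with diagonal covariance.
#'
#' @param mean mean vector.
#' @param sigma covariance matrix.
#' @param n number of quasi-Monte-Carlo points.
#' @param scramble_seed seed for the fixed Cranley-Patterson shift.
#' @return Scalar probability in \[0, 1\].
#' @export
orthant_prob <- function(mean, sigma, n = 4096L, scramble_seed = 17L) {
  d <- length(mean)
  sigma <- as.matrix(sigma)
  if (d == 1L)
    return(stats::pnorm(0, mean, sqrt(sigma[1, 1]), lower.tail = FALSE))
  if (all(abs(sigma[row(sigma) != col(sigma)]) < 1e-14))
    return(prod(stats::pnorm(0, mean, sqrt(diag(sigma)), lower.tail = FALSE)))
  L <- t(chol(sigma))
  # deterministic scramble shift (no interaction with the caller's RNG)
  shift <- (sqrt(c(2, 3, 5, 7, 11, 13, 17)[seq_len(d - 1)]) *
              scramble_seed) %% 1
  W <- halton_matrix(n, d - 1, shift = shift)

  # sequential conditioning: integrate over the first d-1 coordinates
  a <- -mean  # lower bounds of (X - mean) in the L-transformed space
  e1 <- stats::pnorm(a[1] / L[1, 1], lower.tail = FALSE)
  P <- rep(e1, n)
  Y <- matrix(0, n, d)
  lo <- stats::pnorm(a[1] / L[1, 1])
  Y[, 1] <- stats::qnorm(pmin(lo + W[, 1] * (1 - lo), 1 - 1e-16))
  if (d > 2) {
    for (i in 2:(d - 1)) {
      mu_i <- Y[, seq_len(i - 1), drop = FALSE] %*% L[i, seq_len(i - 1)]
      lo_i <- stats::pnorm((a[i] - mu_i) / L[i, i])
      P <- P * (1 - lo_i)
      Y[, i] <- stats::qnorm(pmin(lo_i + W[, i] * (1 - lo_i), 1 - 1e-16))
    }
  }
  mu_d <- Y[, seq_len(d - 1), drop = FALSE] %*% L[d, seq_len(d - 1)]
  P <- P * stats::pnorm((a[d] - mu_d) / L[d, d], lower.tail = FALSE)
  max(min(mean(P), 1), 0)
}

#' Log density of a multivariate normal truncated to the non-negative orthant
#'
#' Includes the orthant-probability normalization (via [orthant_prob()] for
#' non-diagonal covariances, closed form otherwise).
#' @noRd
dtmvnorm_orthant_log <- function(x, mean, sigma, qmc_n = 4096L) {
  if (any(x < 0)) return(-Inf)
  d <- length(x)
  sigma <- as.matrix(sigma)
  U <- chol(sigma)
  z <- forwardsolve(t(U), x - mean)
  logden <- -0.5 * sum(z^2) - sum(log(diag(U))) - d / 2 * log(2 * pi)
  logden - log(orthant_prob(mean, sigma, n = qmc_n))
}

#' Draw from a multivariate normal truncated to the non-negative orthant
#'
#' Gibbs sweeps of exact univariate truncated-normal full conditionals
#' (precision parameterization), with a rejection-sampling fast path when the
#' untruncated acceptance probability is high.
#'
#' @param mean,sigma parameters of the underlying normal.
#' @param init starting point (non-negative); defaults to the elementwise
#'   projection of `mean`.
#' @param sweeps number of Gibbs sweeps.
#' @return A draw (numeric vector) with all elements >= 0.
#' @export
rtmvnorm_orthant <- function(mean, sigma, init = NULL, sweeps = 20L) {
  d <- length(mean)
  sigma <- as.matrix(sigma)
  if (d == 1L) return(rtnorm_lower(1, mean, sqrt(sigma[1, 1])))
  # rejection fast path
  acc <- orthant_prob(mean, sigma, n = 512L)
  if (acc > 0.1) {
    U <- chol(sigma)
    for (i in seq_len(ceiling(10 / acc))) {
      x <- mean + drop(stats::rnorm(d) %*% U)
      if (all(x >= 0)) return(x)
    }
  }
  P <- chol2inv(chol(sigma))  # precision
  x <- if (is.null(init)) pmax(mean, 0) else init
  for (s in seq_len(sweeps)) {
    for (j in seq_len(d)) {
      cv <- 1 / P[j, j]
      cm <- mean[j] - cv * sum(P[j, -j] * (x[-j] - mean[-j]))
      x[j] <- rtnorm_lower(1, cm, sqrt(cv))
    }
  }
  x
}

#' Inverse-gamma density, distribution and draws
#'
#' Shape/rate parameterization: if `x ~ IG(a, b)` then `1/x ~ Gamma(a, rate = b)`
#' and `E[x] = b / (a - 1)` for `a > 1`.
#'
#' @param x quantiles.
#' @param n number of draws.
#' @param shape,rate inverse-gamma parameters.
#' @param log return the log density.
#' @return `dinvgamma` the (log) density; `rinvgamma` draws.
#' @export
dinvgamma <- function(x, shape, rate, log = FALSE) {
  ld <- ifelse(x > 0,
               shape * base::log(rate) - lgamma(shape) -
                 (shape + 1) * base::log(x) - rate / x,
               -Inf)
  if (log) ld else exp(ld)
}

#' @rdname dinvgamma
#' @export
rinvgamma <- function(n, shape, rate) 1 / stats::rgamma(n, shape, rate = rate)
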
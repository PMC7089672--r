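#' Finite-difference gradient estimation
#'
#' Estimates the temporal derivative of every species by difference quotients:
#' interior points of each condition segment use the central quotient
#' \eqn{(x(t+\delta_t) - x(t-\delta_t)) / (2\delta_t)}; the first and last
#' point of a segment use the corresponding one-sided quotient with step
#' \eqn{\delta_t}. The sampling grid of each segment must be compatible with
#' `dt` (uniform spacing equal to `dt`).
#'
#' @param ts an [timeseries()] object; every segment needs at least 3 points.
#' @param dt time step \eqn{\delta_t} in hours (default 2).
#' @return A [gradient_set()] with method tag `"numerical"`.
#' @export
finite_difference_gradient <- function(ts, dt = 2) {
  out <- ts$values
  for (idx in segment_indices(ts)) {
    if (length(idx) < 3L)
      stop("insufficient data: a condition segment has fewer than 3 points")
    tt <- ts$times[idx]
    if (max(abs(diff(tt) - dt)) > 1e-8)
      stop("sampling interval incompatible with dt = ", dt)
    for (j in seq_len(ncol(out))) {
      x <- ts$values[idx, j]
      m <- length(x)
      g <- numeric(m)
      g[1] <- (x[2] - x[1]) / dt
      g[m] <- (x[m] - x[m - 1]) / dt
      if (m > 2) g[2:(m - 1)] <- (x[3:m] - x[1:(m - 2)]) / (2 * dt)
      out[idx, j] <- g
    }
  }
  gradient_set(out, ts$times, ts$species, ts$condition, method = "numerical")
}

#' Fit a Gaussian process to one concentration series
#'
#' Maximizes the GP log marginal likelihood over the kernel hyperparameters
#' (signal variance, lengthscale, noise variance, and the period for the
#' periodic family) by multi-restart quasi-Newton optimization on the log
#' scale. The fitted object caches the Cholesky factorization of
#' \eqn{G + \sigma_n^2 I} (with escalating jitter if needed).
#'
#' @param times training time points (>= 4).
#' @param values training observations, same length as `times`.
#' @param family kernel family, see [kernel_spec()].
#' @param noise_variance optional fixed noise variance; when `NULL` the noise
#'   is optimized with the other hyperparameters.
#' @param restarts number of random restarts (the first start is
#'   data-driven).
#' @param seed optional seed for the restart draws.
#' @return An object of class `sm_gpfit` with elements `kernel`, `times`,
#'   `values`, `alpha` (the solve of the covariance against the data),
#'   `chol`, and `log_marginal`.
#' @export
fit_gp <- function(times, values, family = "rbf", noise_variance = NULL,
                   restarts = 5L, seed = NULL) {
  stopifnot(length(times) == length(values))
  if (length(times) < 4L) stop("need at least 4 points per segment to fit a GP")
  if (!is.null(seed)) set.seed(seed)
  fix_noise <- !is.null(noise_variance)
  span <- diff(range(times))
  sdv <- stats::sd(values)
  if (sdv == 0) sdv <- 1e-3

  make_kernel <- function(p) {
    sf2 <- exp(p[1]); ell <- exp(p[2])
    noise <- if (fix_noise) noise_variance else exp(p[3])
    period <- if (family == "per") exp(p[length(p)]) else NULL
    kernel_spec(family, sf2 = sf2, ell = ell, period = period, noise = noise)
  }
  negll <- function(p) {
    lml <- tryCatch({
      if (any(!is.finite(p)) || any(abs(p) > 40)) -Inf
      else gp_log_marginal(make_kernel(p), times, values)
    }, error = function(e) -Inf)
    if (!is.finite(lml)) 1e10 else -lml
  }
  base_start <- c(log(sdv^2), log(span / 4),
                  if (!fix_noise) log(0.05 * sdv^2 + 1e-8),
                  if (family == "per") log(span / 2))
  starts <- list(base_start)
  for (r in seq_len(max(restarts - 1L, 0L)))
    starts[[r + 1L]] <- base_start + stats::rnorm(length(base_start), 0, 1.2)

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, negll, method = "BFGS", control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("GP fit failed to converge from any restart")
  kern <- make_kernel(best$par)
  fact <- gp_factorization(kern, times)
  structure(
    list(kernel = kern, times = times, values = values,
         alpha = backsolve(fact$U, forwardsolve(t(fact$U), values)),
         chol = fact$U, jitter = fact$jitter,
         log_marginal = -best$value),
    class = "sm_gpfit"
  )
}

#' @export
print.sm_gpfit <- function(x, ...) {
  k <- x$kernel
  cat("<sm_gpfit> ", k$family, " kernel: sf2=", signif(k$sf2, 4),
      " ell=", signif(k$ell, 4),
      if (!is.null(k$period)) paste0(" period=", signif(k$period, 4)),
      " noise=", signif(k$noise, 4),
      "; log marginal ", signif(x$log_marginal, 6), "\n", sep = "")
  invisible(x)
}

# Cholesky of G + noise*I with escalating jitter (1e-8 upwards).
gp_factorization <- function(kern, times) {
  G <- kernel_gram(kern, times)
  n <- length(times)
  jitter <- 1e-8 * mean(diag(G))
  for (i in 0:6) {
    U <- tryCatch(chol(G + diag(kern$noise + jitter * 10^i, n)),
                  error = function(e) NULL)
    if (!is.null(U)) return(list(U = U, jitter = jitter * 10^i))
  }
  stop("covariance matrix singular even after jitter escalation")
}

gp_log_marginal <- function(kern, times, values) {
  fact <- gp_factorization(kern, times)
  a <- forwardsolve(t(fact$U), values)
  -0.5 * sum(a^2) - sum(log(diag(fact$U))) - length(values) / 2 * log(2 * pi)
}

#' Mean of the derivative Gaussian process
#'
#' A differentiable-kernel GP is closed under differentiation, so the
#' derivative of the latent function is again a GP. Its posterior mean at
#' query times is \eqn{C (G + \sigma_n^2 I)^{-1} x} with
#' \eqn{C_{pq} = \partial\kappa(t_p, t_q)/\partial t_p} (query point `p`,
#' training point `q`). This mean is used as the gradient estimate; it acts
#' as a low-pass filter that counteracts the noise amplification of
#' numerical differencing.
#'
#' @param fit an [fit_gp()] object.
#' @param times query times (default: the training times).
#' @return Numeric vector of derivative means at `times`.
#' @export
gp_derivative_mean <- function(fit, times = fit$times) {
  stopifnot(inherits(fit, "sm_gpfit"))
  C <- kernel_gram(fit$kernel, times, fit$times, deriv = TRUE)
  drop(C %*% fit$alpha)
}

#' GP-based gradient estimation for a whole time series
#'
#' Fits an independent GP per species and per condition segment (conditions
#' are independent experiments, so no smoothing crosses a segment boundary)
#' and evaluates the derivative-GP mean at the observed time points.
#'
#' @param ts an [timeseries()] object.
#' @param family kernel family (default `"rbf"`); for `"mat32"` a warning
#'   notes that its sample paths are only once differentiable.
#' @param noise_variance optional fixed noise variance passed to [fit_gp()].
#' @param restarts restarts per fit.
#' @param seed optional seed.
#' @return A [gradient_set()] with method tag `"analytical"`.
#' @export
gp_gradient <- function(ts, family = "rbf", noise_variance = NULL,
                        restarts = 5L, seed = NULL) {
  if (family == "mat32")
    warning("Matern 3/2 sample paths are only once differentiable; ",
            "the derivative mean exists but is rough")
  if (!is.null(seed)) set.seed(seed)
  out <- ts$values
  for (idx in segment_indices(ts)) {
    for (j in seq_len(ncol(out))) {
      fit <- fit_gp(ts$times[idx], ts$values[idx, j], family = family,
                    noise_variance = noise_variance, restarts = restarts)
      out[idx, j] <- gp_derivative_mean(fit)
    }
  }
  gradient_set(out, ts$times, ts$species, ts$condition, method = "analytical")
}
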
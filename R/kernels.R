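#' Gaussian-process kernel specification
#'
#' Supported families: radial basis function (`"rbf"`), periodic (`"per"`),
#' and Matern with smoothness 3/2 (`"mat32"`) or 5/2 (`"mat52"`). All scale
#' parameters are strictly positive; the period applies to the periodic
#' family only.
#'
#' @param family kernel family.
#' @param sf2 signal variance \eqn{\sigma_f^2}.
#' @param ell lengthscale \eqn{\ell}.
#' @param period period (periodic family only).
#' @param noise observation-noise variance \eqn{\sigma_n^2} (>= 0).
#' @return An object of class `sm_kernel`.
#' @export
kernel_spec <- function(family = c("rbf", "per", "mat32", "mat52"),
                        sf2 = 1, ell = 1, period = NULL, noise = 0) {
  family <- match.arg(family)
  stopifnot(sf2 > 0, ell > 0, noise >= 0)
  if (family == "per") {
    if (is.null(period) || period <= 0) stop("periodic kernel needs period > 0")
  } else if (!is.null(period)) {
    stop("`period` only applies to the periodic family")
  }
  structure(list(family = family, sf2 = sf2, ell = ell, period = period,
                 noise = noise),
            class = "sm_kernel")
}

#' Evaluate a kernel or its first derivative
#'
#' Returns \eqn{\kappa(t, t')} for `order = "value"` or
#' \eqn{\partial\kappa(t, t')/\partial t} for `order = "dt"`. Arguments are
#' recycled, so matrices of covariances can be built with `outer()`.
#'
#' Standard forms: RBF \eqn{\sigma_f^2 \exp(-(t-t')^2/(2\ell^2))}; periodic
#' \eqn{\sigma_f^2 \exp(-2\sin^2(\pi(t-t')/p)/\ell^2)}; Matern 3/2 and 5/2
#' with \eqn{a = \sqrt{3}/\ell} resp. \eqn{\sqrt{5}/\ell}.
#'
#' @param kern a [kernel_spec()].
#' @param t,tp evaluation points (numeric, recycled).
#' @param order `"value"` or `"dt"` (derivative with respect to `t`).
#' @return Numeric vector of covariances (or derivatives).
#' @export
kernel_eval <- function(kern, t, tp, order = c("value", "dt")) {
  order <- match.arg(order)
  stopifnot(inherits(kern, "sm_kernel"))
  r <- t - tp
  sf2 <- kern$sf2; ell <- kern$ell
  switch(kern$family,
    rbf = {
      v <- sf2 * exp(-r^2 / (2 * ell^2))
      if (order == "value") v else -r / ell^2 * v
    },
    per = {
      p <- kern$period
      v <- sf2 * exp(-2 * sin(pi * r / p)^2 / ell^2)
      if (order == "value") v
      else -(2 * pi / (p * ell^2)) * sin(2 * pi * r / p) * v
    },
    mat32 = {
      a <- sqrt(3) / ell
      ar <- a * abs(r)
      if (order == "value") sf2 * (1 + ar) * exp(-ar)
      else -sf2 * a^2 * r * exp(-ar)
    },
    mat52 = {
      a <- sqrt(5) / ell
      ar <- a * abs(r)
      if (order == "value") sf2 * (1 + ar + ar^2 / 3) * exp(-ar)
      else -(sf2 * a^2 / 3) * r * (1 + ar) * exp(-ar)
    },
    stop("unsupported kernel family: ", kern$family)
  )
}

#' Kernel Gram matrix (with noise on the diagonal)
#' @noRd
kernel_gram <- function(kern, t1, t2 = t1, deriv = FALSE) {
  ord <- if (deriv) "dt" else "value"
  outer(t1, t2, function(a, b) kernel_eval(kern, a, b, order = ord))
}
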
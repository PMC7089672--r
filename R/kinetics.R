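#' Regulator configuration for one target
#'
#' A parent set names the regulators of a target species, the sign of each
#' regulatory effect (activation or inhibition), and optionally pairs of
#' regulators whose Michaelis-Menten fractions act multiplicatively (complex
#' formation). The degradation term of the target is always part of the
#' model and is not listed among the regulators.
#'
#' @param target target species name.
#' @param regulators character vector of regulator names (may be empty); the
#'   target itself may not appear.
#' @param signs named or positional character vector, `"activator"` (default)
#'   or `"inhibitor"`, one per regulator.
#' @param complexes optional list of length-2 character vectors; both members
#'   of each pair must be in `regulators`.
#' @return An object of class `sm_parent_set`.
#' @export
parent_set <- function(target, regulators = character(),
                       signs = rep("activator", length(regulators)),
                       complexes = NULL) {
  regulators <- as.character(regulators)
  if (target %in% regulators)
    stop("target may not regulate itself; degradation is always included")
  if (anyDuplicated(regulators)) stop("duplicate regulator")
  if (length(signs) != length(regulators))
    stop("one sign per regulator required")
  if (length(regulators) && !all(signs %in% c("activator", "inhibitor")))
    stop("signs must be 'activator' or 'inhibitor'")
  names(signs) <- regulators
  if (!is.null(complexes)) {
    complexes <- lapply(complexes, as.character)
    for (pr in complexes) {
      if (length(pr) != 2L || !all(pr %in% regulators))
        stop("complex pair members must be two declared regulators")
    }
  }
  structure(list(target = target, regulators = regulators, signs = signs,
                 complexes = complexes),
            class = "sm_parent_set")
}

#' @export
print.sm_parent_set <- function(x, ...) {
  cat("<sm_parent_set> ", x$target, " <- {",
      paste(x$regulators, collapse = ", "), "}",
      if (length(x$complexes)) paste0(" + ", length(x$complexes), " complex pair(s)"),
      "\n", sep = "")
  invisible(x)
}

#' Regulator names whose Michaelis-Menten constant enters the model
#' @noRd
parent_set_k_names <- function(ps) ps$regulators

#' Number of rate parameters (degradation + additive terms + complex terms)
#' @noRd
parent_set_dim_v <- function(ps) 1L + length(ps$regulators) + length(ps$complexes)

#' Saturating Michaelis-Menten fraction
#'
#' Activation: \eqn{x / (x + k)}; inhibition: \eqn{k / (x + k)}. Both lie in
#' \[0, 1\] for non-negative concentration `x` and half-saturation constant
#' `k`, and are monotone in `x` (increasing for activators, decreasing for
#' inhibitors).
#'
#' @param x concentration(s), >= 0.
#' @param k half-saturation constant, >= 0; `x` and `k` must not both be 0.
#' @param sign `"activator"` or `"inhibitor"`.
#' @return Fraction(s) in \[0, 1\].
#' @export
michaelis_menten_term <- function(x, k, sign = c("activator", "inhibitor")) {
  sign <- match.arg(sign)
  if (any(x < 0) || any(k < 0)) stop("x and k must be non-negative")
  if (any(x + k == 0)) stop("undefined Michaelis-Menten term: x = k = 0")
  if (sign == "activator") x / (x + k) else k / (x + k)
}

#' Build the kinetic design matrix for a parent set
#'
#' Row \eqn{t^\star} is \eqn{(-x_i(t^\star),} one Michaelis-Menten fraction
#' per additive regulator, one product of two fractions per complex
#' pair\eqn{)}. The first column carries the degradation of the target; all
#' other entries lie in \[0, 1\]. Each complex pair contributes a single
#' column (the product of the two member fractions), multiplied downstream
#' by one effective rate parameter.
#'
#' @param ts an [timeseries()] object containing the target and all
#'   regulators.
#' @param ps a [parent_set()].
#' @param K named numeric vector of Michaelis-Menten constants, one per
#'   regulator in `ps`.
#' @return Numeric matrix, `T` rows and `1 + |regulators| + |complexes|`
#'   columns, with descriptive column names.
#' @export
build_design_matrix <- function(ts, ps, K) {
  vals <- if (inherits(ts, "sm_timeseries")) ts$values else as.matrix(ts)
  need <- c(ps$target, ps$regulators)
  if (!all(need %in% colnames(vals)))
    stop("configuration error: missing column(s): ",
         paste(setdiff(need, colnames(vals)), collapse = ", "))
  kn <- parent_set_k_names(ps)
  if (length(kn)) {
    if (is.null(names(K))) names(K) <- kn
    if (!all(kn %in% names(K))) stop("K must supply one constant per regulator")
  }
  D <- matrix(-vals[, ps$target], ncol = 1,
              dimnames = list(NULL, paste0("degr:", ps$target)))
  frac <- function(u) michaelis_menten_term(vals[, u], K[[u]], ps$signs[[u]])
  for (u in ps$regulators) {
    D <- cbind(D, frac(u))
    colnames(D)[ncol(D)] <- paste0(ps$signs[[u]], ":", u)
  }
  for (pr in ps$complexes) {
    D <- cbind(D, frac(pr[1]) * frac(pr[2]))
    colnames(D)[ncol(D)] <- paste0("complex:", pr[1], "*", pr[2])
  }
  D
}

#' Gaussian gradient-matching log likelihood
#'
#' \eqn{-\frac{T}{2}\log(2\pi\sigma^2) - \frac{(y - DV)^\top (y - DV)}{2\sigma^2}}.
#' The per-timepoint terms (needed by WAIC and CVIC) are returned as the
#' `"pointwise"` attribute and sum to the total.
#'
#' @param y gradient response vector.
#' @param D design matrix from [build_design_matrix()].
#' @param V rate vector.
#' @param sigma2 noise variance (> 0).
#' @return Scalar log density with attribute `pointwise`.
#' @export
log_likelihood <- function(y, D, V, sigma2) {
  stopifnot(length(y) == nrow(D), length(V) == ncol(D), sigma2 > 0)
  r <- y - drop(D %*% V)
  if (any(!is.finite(r))) stop("non-finite residuals in log likelihood")
  pw <- -0.5 * log(2 * pi * sigma2) - r^2 / (2 * sigma2)
  structure(sum(pw), pointwise = pw)
}

#' Joint log prior of the kinetic parameters
#'
#' Sum of: independent truncated-normal priors on the Michaelis-Menten
#' constants (mean 1, variance `nu`, truncated at 0, normalization
#' included); a truncated-normal prior on the rates V (ridge variant: mean 1,
#' covariance \eqn{\delta^2\sigma^2 I}; g-prior variant: mean 1, covariance
#' \eqn{T\sigma^2 (D^\top D)^{-1}}, normalization by orthant probability);
#' and inverse-gamma priors on \eqn{\sigma^2} and (ridge, unless fixed)
#' \eqn{\delta^2}. Any parameter outside the non-negative orthant gives
#' `-Inf`.
#'
#' @param V,K,sigma2,delta2 parameter values (`K` may be empty; `delta2` is
#'   ignored for the g-prior).
#' @param D design matrix at `K` (g-prior only; also sets `T`).
#' @param cfg an [run_config()] with the hyperparameters.
#' @param variant `"ridge"` or `"gprior"`.
#' @return Scalar log density.
#' @export
log_prior <- function(V, K, sigma2, delta2, D = NULL, cfg = run_config(),
                      variant = c("ridge", "gprior")) {
  variant <- match.arg(variant)
  if (any(V < 0) || (length(K) && any(K < 0)) || sigma2 <= 0) return(-Inf)
  lp <- 0
  if (length(K))
    lp <- lp + sum(dtnorm_lower_log(K, 1, sqrt(cfg$nu)))
  d <- length(V)
  if (variant == "ridge") {
    if (delta2 <= 0) return(-Inf)
    sd_v <- sqrt(delta2 * sigma2)
    lp <- lp + sum(stats::dnorm(V, 1, sd_v, log = TRUE)) -
      d * stats::pnorm(0, 1, sd_v, lower.tail = FALSE, log.p = TRUE)
    if (is.na(cfg$delta2_fixed))
      lp <- lp + dinvgamma(delta2, cfg$a_delta, cfg$b_delta, log = TRUE)
  } else {
    if (is.null(D)) stop("g-prior requires the design matrix D")
    Tn <- nrow(D)
    Sg <- Tn * sigma2 * chol2inv(chol(crossprod(D)))
    lp <- lp + dtmvnorm_orthant_log(V, rep(1, d), Sg, qmc_n = 1024L)
  }
  lp + dinvgamma(sigma2, cfg$a_sigma, cfg$b_sigma, log = TRUE)
}
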
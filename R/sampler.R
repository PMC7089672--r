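# Metropolis-within-Gibbs sampler for the gradient-matching regression
# model. One scan updates, in order: the rate vector V (truncated-normal
# Gibbs), the ridge scale delta^2, the noise variance sigma^2, and the
# Michaelis-Menten constants K (random-walk Metropolis with reflection).
#
# The hierarchical prior is kept fully normalized: the truncated V-prior's
# normalizing constant depends on (sigma^2, delta^2) (ridge) or on
# (sigma^2, K) (g-prior), so the conjugate inverse-gamma updates of sigma^2
# and delta^2 are used as Metropolis proposals and corrected by the ratio of
# truncation normalizers. This keeps the prior proper (as needed by the
# evidence estimators and the Geweke check) at negligible extra cost.
#
# A temperature tau in [0, 1] exponentiates the likelihood only, giving the
# power posteriors used by thermodynamic integration and WBIC; tau = 0
# samples the prior.

#' Internal model object for the sampler
#'
#' Couples a gradient response vector with a design-matrix builder. When the
#' parent set has regulators, the design depends on the Michaelis-Menten
#' constants `K`; a fixed design (e.g. ordinary Bayesian linear regression)
#' corresponds to `nK = 0`. `truncated = FALSE` drops all non-negativity
#' constraints (used by the conjugate oracle models).
#'
#' @param y response vector.
#' @param build_design `function(K)` returning the design matrix.
#' @param k_names names of the Michaelis-Menten constants (length 0 for a
#'   fixed design).
#' @param cfg an [run_config()].
#' @param variant `"ridge"` or `"gprior"`.
#' @param truncated enforce the non-negative orthant?
#' @return An object of class `sm_model`.
#' @keywords internal
#' @export
gm_model <- function(y, build_design, k_names = character(),
                     cfg = run_config(), variant = c("ridge", "gprior"),
                     truncated = TRUE) {
  variant <- match.arg(variant)
  D0 <- build_design(stats::setNames(rep(1, length(k_names)), k_names))
  stopifnot(nrow(D0) == length(y))
  structure(
    list(y = y, Tn = length(y), build_design = build_design,
         nK = length(k_names), k_names = k_names, dV = ncol(D0),
         v_names = colnames(D0), cfg = cfg, variant = variant,
         truncated = truncated),
    class = "sm_model"
  )
}

#' Build an `sm_model` from data and a parent set
#'
#' The response is the target's column of the gradient set; the design is
#' rebuilt from the concentration matrix whenever the Michaelis-Menten
#' constants move.
#'
#' @param ts concentrations ([timeseries()]).
#' @param grads gradients ([gradient_set()]); must contain the target.
#' @param ps a [parent_set()].
#' @param cfg an [run_config()].
#' @param variant prior variant.
#' @return An `sm_model`.
#' @export
model_from_data <- function(ts, grads, ps, cfg = run_config(),
                            variant = c("ridge", "gprior")) {
  variant <- match.arg(variant)
  if (!ps$target %in% colnames(grads$values))
    stop("no gradient column for target '", ps$target, "'")
  y <- grads$values[, ps$target]
  gm_model(y, function(K) build_design_matrix(ts, ps, K),
           k_names = parent_set_k_names(ps), cfg = cfg, variant = variant)
}

# ---- full-conditional building blocks -------------------------------------

#' Conditional mean and covariance of the rate vector
#'
#' For the ridge prior:
#' \eqn{\Sigma = \sigma^2\delta^2 (I + \delta^2 D^\top D)^{-1}} and
#' \eqn{\mu = \delta^2 (I + \delta^2 D^\top D)^{-1} (\delta^{-2} 1 + D^\top y)};
#' the conditional is this normal truncated to the non-negative orthant. A
#' temperature `tau` scales the likelihood contribution.
#'
#' @param D design matrix.
#' @param y response vector.
#' @param sigma2,delta2 current variance parameters.
#' @param tau likelihood temperature.
#' @return List with `mean` and `sigma` (covariance).
#' @export
v_conditional_params <- function(D, y, sigma2, delta2, tau = 1) {
  A <- tau * crossprod(D) + diag(1 / delta2, ncol(D))
  Ainv <- chol2inv(chol(A))
  mu <- drop(Ainv %*% (tau * crossprod(D, y) + rep(1 / delta2, ncol(D))))
  list(mean = mu, sigma = sigma2 * Ainv)
}

# g-prior analogue: prior covariance T sigma^2 (D'D)^-1, prior mean 1.
v_conditional_params_g <- function(D, y, sigma2, tau = 1) {
  DtD <- crossprod(D)
  A <- (tau + 1 / nrow(D)) * DtD
  Ainv <- chol2inv(chol(A))
  mu <- drop(Ainv %*% (tau * crossprod(D, y) + DtD %*% rep(1 / nrow(D), ncol(D))))
  list(mean = mu, sigma = sigma2 * Ainv)
}

#' Draw the rate vector from its full conditional
#'
#' Orthant-truncated multivariate normal draw (see [rtmvnorm_orthant()]);
#' with `truncated = FALSE` a plain multivariate normal draw.
#'
#' @param params list from [v_conditional_params()].
#' @param truncated enforce non-negativity?
#' @param init current value (used to start the Gibbs sweeps).
#' @param sweeps Gibbs sweeps for the truncated draw.
#' @return Rate vector draw.
#' @export
sample_v <- function(params, truncated = TRUE, init = NULL, sweeps = 8L) {
  if (!truncated) {
    U <- chol(params$sigma)
    return(params$mean + drop(stats::rnorm(length(params$mean)) %*% U))
  }
  rtmvnorm_orthant(params$mean, params$sigma, init = init, sweeps = sweeps)
}

# Coordinate-wise truncated-normal Gibbs sweep in precision form; a valid
# MCMC update of V starting from its current value (used in the main loop,
# where exact joint draws are unnecessary).
v_gibbs_sweep <- function(x, mu, prec, sweeps = 2L) {
  d <- length(x)
  if (d == 1L) return(rtnorm_lower(1, mu, sqrt(1 / prec[1, 1])))
  for (s in seq_len(sweeps)) {
    for (j in seq_len(d)) {
      cv <- 1 / prec[j, j]
      cm <- mu[j] - cv * sum(prec[j, -j] * (x[-j] - mu[-j]))
      x[j] <- rtnorm_lower(1, cm, sqrt(cv))
    }
  }
  x
}

#' Conjugate inverse-gamma update of the ridge scale
#'
#' Draws \eqn{\delta^2} from
#' \eqn{IG(a_\delta + d/2,\; b_\delta + (V-1)^\top(V-1)/(2\sigma^2))} where
#' `d = length(V)`. Within the full sampler this draw serves as a Metropolis
#' proposal that is corrected for the truncation normalizer of the V-prior.
#'
#' @param V rate vector.
#' @param sigma2 noise variance.
#' @param cfg an [run_config()].
#' @return A positive draw.
#' @export
sample_delta2 <- function(V, sigma2, cfg = run_config()) {
  shape <- cfg$a_delta + length(V) / 2
  rate <- cfg$b_delta + sum((V - 1)^2) / (2 * sigma2)
  rinvgamma(1, shape, rate)
}

#' Conjugate inverse-gamma update of the noise variance
#'
#' Ridge prior: draws \eqn{\sigma^2} from
#' \eqn{IG(a_\sigma + (\tau T + d)/2,\;
#'      b_\sigma + \frac{1}{2}[\tau\,(y-DV)^\top(y-DV) + (V-1)^\top(V-1)/\delta^2])}.
#' As with [sample_delta2()], the full sampler corrects this proposal for the
#' truncation normalizer.
#'
#' @param y response.
#' @param D design matrix.
#' @param V rate vector.
#' @param delta2 ridge scale.
#' @param cfg an [run_config()].
#' @param tau likelihood temperature.
#' @return A positive draw.
#' @export
sample_sigma2 <- function(y, D, V, delta2, cfg = run_config(), tau = 1) {
  rss <- sum((y - drop(D %*% V))^2)
  shape <- cfg$a_sigma + (tau * length(y) + length(V)) / 2
  rate <- cfg$b_sigma + 0.5 * (tau * rss + sum((V - 1)^2) / delta2)
  rinvgamma(1, shape, rate)
}

# g-prior sigma^2 proposal: prior quadratic form (V-1)' D'D (V-1) / T.
sample_sigma2_g <- function(y, D, V, cfg, tau = 1) {
  rss <- sum((y - drop(D %*% V))^2)
  q <- drop(crossprod(V - 1, crossprod(D) %*% (V - 1))) / nrow(D)
  shape <- cfg$a_sigma + (tau * length(y) + length(V)) / 2
  rate <- cfg$b_sigma + 0.5 * (tau * rss + q)
  rinvgamma(1, shape, rate)
}

# log truncation normalizer of the V-prior (Z = P(V >= 0) under the
# untruncated prior); 0 when the model is untruncated.
log_z_vprior <- function(model, sigma2, delta2 = NULL, DtD = NULL) {
  if (!model$truncated) return(0)
  d <- model$dV
  if (model$variant == "ridge") {
    d * stats::pnorm(0, 1, sqrt(delta2 * sigma2),
                     lower.tail = FALSE, log.p = TRUE)
  } else {
    Sg <- model$Tn * sigma2 * chol2inv(chol(DtD))
    log(orthant_prob(rep(1, d), Sg, n = 512L))
  }
}

#' Random-walk proposal for the Michaelis-Menten constants
#'
#' Adds zero-mean Gaussian noise with covariance `scale * I` and reflects
#' negative values into the positive domain, `K* = |K + u|`. The reflected
#' proposal density is symmetric, so the Hastings ratio is 1.
#'
#' @param K current constants.
#' @param scale proposal variance (default 0.1).
#' @return Proposed constants, all >= 0.
#' @export
propose_k <- function(K, scale = 0.1) {
  abs(K + stats::rnorm(length(K), 0, sqrt(scale)))
}

# density of the reflected Gaussian proposal q(K* | K)
dpropose_k_log <- function(Kstar, K, scale = 0.1) {
  sd <- sqrt(scale)
  sum(log(stats::dnorm(Kstar - K, 0, sd) + stats::dnorm(Kstar + K, 0, sd)))
}

#' Metropolis-Hastings ratio for a Michaelis-Menten move
#'
#' Likelihood ratio with the design matrix rebuilt at `Kstar`, times the
#' prior ratio. Ridge variant: ratio of the truncated-normal K-prior kernels
#' (the truncation normalizers cancel). G-prior variant: additionally the
#' ratio of the truncated g-prior densities of the current rate vector at
#' the two designs, including the orthant-probability normalizers.
#'
#' @param model an `sm_model`.
#' @param K,Kstar current and proposed constants.
#' @param V,sigma2 current rates and noise variance.
#' @param D design at `K` (rebuilt internally when omitted).
#' @param tau likelihood temperature.
#' @return List with `ratio`, `Dstar` (design at `Kstar`) and `llstar`.
#' @export
k_accept_ratio <- function(model, K, Kstar, V, sigma2, D = NULL, tau = 1) {
  if (is.null(D)) D <- model$build_design(K)
  Dstar <- model$build_design(Kstar)
  ll <- as.numeric(log_likelihood(model$y, D, V, sigma2))
  llstar <- as.numeric(log_likelihood(model$y, Dstar, V, sigma2))
  if (!is.finite(llstar)) return(list(ratio = 0, Dstar = Dstar, llstar = -Inf))
  nu <- model$cfg$nu
  lr <- tau * (llstar - ll) +
    (sum((K - 1)^2) - sum((Kstar - 1)^2)) / (2 * nu)
  if (model$variant == "gprior") {
    Sg <- function(Dm) model$Tn * sigma2 * chol2inv(chol(crossprod(Dm)))
    lr <- lr + dtmvnorm_orthant_log(V, rep(1, model$dV), Sg(Dstar),
                                    qmc_n = 512L) -
               dtmvnorm_orthant_log(V, rep(1, model$dV), Sg(D),
                                    qmc_n = 512L)
  }
  list(ratio = exp(lr), Dstar = Dstar, llstar = llstar)
}

# ---- the scan and the runner ----------------------------------------------

# Initial state: prior-mean-centred, mildly dispersed.
init_state <- function(model, overrides = NULL) {
  cfg <- model$cfg
  st <- list(
    V = rep(1, model$dV),
    K = stats::setNames(rep(1, model$nK), model$k_names),
    sigma2 = 1,
    delta2 = if (!is.na(cfg$delta2_fixed)) cfg$delta2_fixed else 1
  )
  for (nm in names(overrides)) st[[nm]] <- overrides[[nm]]
  st$D <- model$build_design(st$K)
  st
}

# One Metropolis-within-Gibbs scan; returns the updated state with an
# `accepted` flag for the K-move.
gibbs_scan <- function(model, state, tau = 1) {
  cfg <- model$cfg
  y <- model$y
  D <- state$D

  # (1) rates V
  if (model$variant == "ridge") {
    vp <- v_conditional_params(D, y, state$sigma2, state$delta2, tau = tau)
  } else {
    vp <- v_conditional_params_g(D, y, state$sigma2, tau = tau)
  }
  if (model$truncated) {
    prec <- chol2inv(chol(vp$sigma))
    state$V <- v_gibbs_sweep(pmax(state$V, 0), vp$mean, prec, sweeps = 2L)
  } else {
    state$V <- sample_v(vp, truncated = FALSE)
  }

  # (2) ridge scale delta^2 (conjugate proposal + normalizer correction)
  if (model$variant == "ridge" && is.na(cfg$delta2_fixed)) {
    prop <- sample_delta2(state$V, state$sigma2, cfg)
    if (!model$truncated) {
      state$delta2 <- prop
    } else {
      lacc <- log_z_vprior(model, state$sigma2, state$delta2) -
              log_z_vprior(model, state$sigma2, prop)
      if (log(stats::runif(1)) < lacc) state$delta2 <- prop
    }
  }

  # (3) noise variance sigma^2
  if (model$variant == "ridge") {
    prop <- sample_sigma2(y, D, state$V, state$delta2, cfg, tau = tau)
    if (!model$truncated) {
      state$sigma2 <- prop
    } else {
      lacc <- log_z_vprior(model, state$sigma2, state$delta2) -
              log_z_vprior(model, prop, state$delta2)
      if (log(stats::runif(1)) < lacc) state$sigma2 <- prop
    }
  } else {
    prop <- sample_sigma2_g(y, D, state$V, cfg, tau = tau)
    DtD <- crossprod(D)
    lacc <- log_z_vprior(model, state$sigma2, DtD = DtD) -
            log_z_vprior(model, prop, DtD = DtD)
    if (log(stats::runif(1)) < lacc) state$sigma2 <- prop
  }

  # (4) Michaelis-Menten constants (Metropolis with reflection)
  state$accepted <- FALSE
  if (model$nK > 0L) {
    Kstar <- propose_k(state$K, cfg$proposal_scale)
    ar <- k_accept_ratio(model, state$K, Kstar, state$V, state$sigma2,
                         D = state$D, tau = tau)
    if (stats::runif(1) < ar$ratio) {
      state$K <- stats::setNames(Kstar, model$k_names)
      state$D <- ar$Dstar
      state$accepted <- TRUE
    }
  }
  state
}

# Unnormalized log posterior (likelihood + normalized prior) of a state.
state_log_post <- function(model, state, tau = 1) {
  ll <- log_likelihood(model$y, state$D, state$V, state$sigma2)
  lp <- if (model$truncated) {
    log_prior(state$V, state$K, state$sigma2, state$delta2,
              D = state$D, cfg = model$cfg, variant = model$variant)
  } else {
    # untruncated oracle model: plain normal/IG prior
    sum(stats::dnorm(state$V, 1, sqrt(state$delta2 * state$sigma2), log = TRUE)) +
      dinvgamma(state$sigma2, model$cfg$a_sigma, model$cfg$b_sigma, log = TRUE) +
      (if (is.na(model$cfg$delta2_fixed))
         dinvgamma(state$delta2, model$cfg$a_delta, model$cfg$b_delta, log = TRUE)
       else 0)
  }
  tau * as.numeric(ll) + lp
}

#' Run the Metropolis-within-Gibbs sampler for one model
#'
#' Iterates the scan (rates, ridge scale, noise variance, Michaelis-Menten
#' move), storing post-burn-in thinned draws together with the per-timepoint
#' log-likelihood terms, the total log likelihood and the unnormalized log
#' posterior of every iteration (burn-in included; used by the pivot
#' selection of Chib's method).
#'
#' @param model an `sm_model` (see [model_from_data()]).
#' @param iterations,burnin,thin run lengths; default from the model config.
#' @param tau likelihood temperature in \[0, 1\] (1 = posterior, 0 = prior).
#' @param seed optional RNG seed.
#' @param init optional named list overriding the initial state.
#' @return A `sm_chain`: list with matrices `V`, `K`, vectors `sigma2`,
#'   `delta2`, `loglik`, `logpost`, matrix `pointwise`, the full-history
#'   `history` (for pivot selection), and `accept_rate`.
#' @export
run_chain <- function(model, iterations = model$cfg$iterations,
                      burnin = model$cfg$burnin, thin = model$cfg$thin,
                      tau = 1, seed = NULL, init = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state <- init_state(model, init)
  keep <- seq(burnin + 1L, iterations)
  keep <- keep[(seq_along(keep) - 1L) %% thin == 0L]
  keep_flag <- logical(iterations)
  keep_flag[keep] <- TRUE
  S <- length(keep)
  V <- matrix(NA_real_, S, model$dV, dimnames = list(NULL, model$v_names))
  K <- matrix(NA_real_, S, model$nK, dimnames = list(NULL, model$k_names))
  sigma2 <- delta2 <- loglik <- numeric(S)
  pointwise <- matrix(NA_real_, S, model$Tn)
  hist_lp <- numeric(iterations)
  hist_par <- vector("list", iterations)
  accepts <- 0L
  si <- 0L
  for (it in seq_len(iterations)) {
    state <- gibbs_scan(model, state, tau = tau)
    accepts <- accepts + state$accepted
    hist_lp[it] <- state_log_post(model, state, tau = tau)
    hist_par[[it]] <- state[c("V", "K", "sigma2", "delta2")]
    if (keep_flag[it]) {
      si <- si + 1L
      V[si, ] <- state$V
      if (model$nK) K[si, ] <- state$K
      sigma2[si] <- state$sigma2
      delta2[si] <- state$delta2
      ll <- log_likelihood(model$y, state$D, state$V, state$sigma2)
      loglik[si] <- ll
      pointwise[si, ] <- attr(ll, "pointwise")
    }
  }
  rate <- if (model$nK) accepts / iterations else NA_real_
  if (model$nK && (rate < 0.05 || rate > 0.95))
    warning("K-move acceptance rate ", signif(rate, 3),
            " outside [0.05, 0.95]; consider retuning the proposal scale")
  structure(
    list(V = V, K = K, sigma2 = sigma2, delta2 = delta2,
         loglik = loglik, pointwise = pointwise,
         logpost = hist_lp[keep],
         history = list(logpost = hist_lp, params = hist_par,
                        burnin = burnin, kept = keep),
         accept_rate = rate, tau = tau, model = model),
    class = "sm_chain"
  )
}

#' Run multiple chains for a parent set
#'
#' User-facing wrapper: builds the model from data and runs `cfg$chains`
#' independent chains (seeds derived from `seed`).
#'
#' @inheritParams model_from_data
#' @param seed base seed; chain `c` uses `seed + c - 1`.
#' @param tau likelihood temperature.
#' @return A `sm_samples` object: list of `sm_chain`s plus the model.
#' @export
run_mcmc <- function(ts, grads, ps, cfg = run_config(),
                     variant = c("ridge", "gprior"), seed = NULL, tau = 1) {
  variant <- match.arg(variant)
  model <- model_from_data(ts, grads, ps, cfg, variant)
  chains <- lapply(seq_len(cfg$chains), function(c)
    run_chain(model, tau = tau,
              seed = if (is.null(seed)) NULL else seed + c - 1L))
  structure(list(chains = chains, model = model), class = "sm_samples")
}

#' @export
print.sm_chain <- function(x, ...) {
  cat("<sm_chain> ", length(x$sigma2), " stored draws (tau = ", x$tau, ")",
      if (!is.na(x$accept_rate))
        paste0(", K acceptance ", signif(x$accept_rate, 3)),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.sm_samples <- function(x, ...) {
  cat("<sm_samples> ", length(x$chains), " chain(s) x ",
      length(x$chains[[1]]$sigma2), " stored draws\n", sep = "")
  invisible(x)
}

#' Potential scale reduction factor (Gelman-Rubin)
#'
#' Split-free PSRF per scalar parameter over two or more equal-length
#' chains; values near 1 indicate convergence (flagged at threshold 1.1).
#'
#' @param chains a `sm_samples` object or list of `sm_chain`s (>= 2).
#' @param threshold convergence flag threshold.
#' @return Data frame with columns `parameter`, `psrf`, `converged`.
#' @export
psrf <- function(chains, threshold = 1.1) {
  if (inherits(chains, "sm_samples")) chains <- chains$chains
  if (length(chains) < 2L) stop("psrf requires at least 2 chains")
  par_mat <- function(ch) {
    cbind(ch$V, if (NCOL(ch$K) > 0) ch$K, sigma2 = ch$sigma2,
          delta2 = ch$delta2)
  }
  mats <- lapply(chains, par_mat)
  n <- unique(vapply(mats, nrow, 1L))
  if (length(n) != 1L) stop("chains must have equal length")
  m <- length(mats)
  p <- ncol(mats[[1]])
  nm <- colnames(mats[[1]])
  out <- vapply(seq_len(p), function(j) {
    means <- vapply(mats, function(M) mean(M[, j]), 1)
    vars <- vapply(mats, function(M) stats::var(M[, j]), 1)
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W == 0 || B == 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 1)
  data.frame(parameter = nm, psrf = out, converged = out < threshold,
             row.names = NULL)
}
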
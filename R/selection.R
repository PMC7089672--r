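# Model-selection scores for a fitted parent set. Two families:
#  * predictive information criteria computed from posterior draws
#    (DIC, WAIC, CVIC) -- lower is better;
#  * log-evidence estimates (WBIC, Chib's method, thermodynamic
#    integration) -- higher is better.
# Every score carries an `orientation` field so that "difference favouring
# the true model" is positive when the true model is preferred.

new_score <- function(criterion, value, se = NA_real_,
                      orientation = c("higher", "lower"), diagnostics = NULL) {
  structure(list(criterion = criterion, value = value, se = se,
                 orientation = match.arg(orientation),
                 diagnostics = diagnostics),
            class = "sm_score")
}

#' @export
print.sm_score <- function(x, ...) {
  cat("<sm_score> ", x$criterion, " = ", signif(x$value, 6),
      if (is.finite(x$se)) paste0(" (se ", signif(x$se, 3), ")"),
      "  [", x$orientation, " is better]\n", sep = "")
  invisible(x)
}

#' Oriented score difference favouring the first model
#'
#' Positive when `a`'s model is preferred: `b - a` for lower-is-better
#' criteria, `a - b` for higher-is-better ones.
#' @param a,b `sm_score` objects with the same criterion.
#' @return Scalar difference.
#' @export
score_difference <- function(a, b) {
  stopifnot(a$criterion == b$criterion)
  if (a$orientation == "higher") a$value - b$value else b$value - a$value
}

pool_chains <- function(samples) {
  if (inherits(samples, "sm_chain")) return(samples)
  ch <- samples$chains
  list(V = do.call(rbind, lapply(ch, `[[`, "V")),
       K = do.call(rbind, lapply(ch, `[[`, "K")),
       sigma2 = unlist(lapply(ch, `[[`, "sigma2")),
       delta2 = unlist(lapply(ch, `[[`, "delta2")),
       loglik = unlist(lapply(ch, `[[`, "loglik")),
       pointwise = do.call(rbind, lapply(ch, `[[`, "pointwise")),
       model = ch[[1]]$model)
}

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

#' Divergence information criterion
#'
#' \eqn{DIC = \bar{D} + p_D} with deviance \eqn{D = -2\log p(y|\theta)},
#' \eqn{\bar{D}} its posterior mean and
#' \eqn{p_D = \bar{D} - D(\bar\theta)} evaluated at the posterior-mean
#' parameters (which lie in the non-negative orthant by construction). A
#' negative \eqn{p_D} triggers a warning (known DIC pathology) but the value
#' is still returned.
#'
#' @param samples `sm_samples` or `sm_chain` from [run_mcmc()]/[run_chain()].
#' @return An `sm_score` (lower is better).
#' @export
dic <- function(samples) {
  s <- pool_chains(samples)
  model <- s$model
  dbar <- mean(-2 * s$loglik)
  Kbar <- if (model$nK) stats::setNames(colMeans(s$K), model$k_names)
          else numeric()
  Vbar <- colMeans(s$V)
  s2bar <- mean(s$sigma2)
  Dhat <- -2 * as.numeric(
    log_likelihood(model$y, model$build_design(Kbar), Vbar, s2bar))
  p_d <- dbar - Dhat
  if (p_d < 0)
    warning("negative effective number of parameters (p_D = ",
            signif(p_d, 3), ")")
  new_score("dic", dbar + p_d, orientation = "lower",
            diagnostics = list(p_d = p_d, dbar = dbar))
}

#' Widely applicable information criterion
#'
#' \eqn{WAIC = -2(\mathrm{lppd} - p_\mathrm{waic})} with
#' \eqn{\mathrm{lppd} = \sum_j \log \mathrm{mean}_s\, e^{\ell_{sj}}}
#' (log-sum-exp stabilized) and
#' \eqn{p_\mathrm{waic} = \sum_j \mathrm{var}_s(\ell_{sj})}, where
#' \eqn{\ell_{sj}} is the log-likelihood of timepoint `j` under draw `s`.
#'
#' @param samples as in [dic()], or a plain draws-by-timepoints matrix of
#'   pointwise log-likelihood terms.
#' @return An `sm_score` (lower is better).
#' @export
waic <- function(samples) {
  pw <- if (is.matrix(samples)) samples else pool_chains(samples)$pointwise
  if (nrow(pw) < 2L) stop("WAIC needs at least 2 posterior draws")
  lppd <- sum(apply(pw, 2, log_mean_exp))
  p_w <- sum(apply(pw, 2, stats::var))
  new_score("waic", -2 * (lppd - p_w), orientation = "lower",
            diagnostics = list(lppd = lppd, p_waic = p_w))
}

#' Cross-validation information criterion
#'
#' Leave-one-out predictive density per timepoint by importance sampling
#' from the full posterior (harmonic-mean estimator):
#' \eqn{\mathrm{elpd}_j = -\log \mathrm{mean}_s\, e^{-\ell_{sj}}};
#' \eqn{CVIC = -2\sum_j \mathrm{elpd}_j}. A warning is issued when the
#' largest importance weight at any timepoint carries more than half the
#' total weight (infinite-variance symptom).
#'
#' @inheritParams waic
#' @return An `sm_score` (lower is better).
#' @export
cvic <- function(samples) {
  pw <- if (is.matrix(samples)) samples else pool_chains(samples)$pointwise
  if (nrow(pw) < 2L) stop("CVIC needs at least 2 posterior draws")
  elpd <- -apply(-pw, 2, log_mean_exp)
  wmax <- apply(-pw, 2, function(l) {
    w <- exp(l - max(l)); max(w) / sum(w)
  })
  if (any(wmax > 0.5))
    warning("dominant importance weight at ", sum(wmax > 0.5),
            " timepoint(s); CVIC estimate may have infinite variance")
  new_score("cvic", -2 * sum(elpd), orientation = "lower",
            diagnostics = list(max_weight = max(wmax)))
}

#' Widely applicable Bayesian information criterion
#'
#' Runs the power-posterior sampler at the single temperature
#' \eqn{\tau^* = 1/\log T} and returns the posterior mean of the
#' log-likelihood there as a log-evidence estimate (higher is better,
#' directly comparable to the marginal log-likelihood).
#'
#' @param model an `sm_model`.
#' @param iterations,burnin,thin run lengths.
#' @param seed optional seed.
#' @return An `sm_score` (higher is better).
#' @export
wbic <- function(model, iterations = model$cfg$iterations,
                 burnin = model$cfg$burnin, thin = model$cfg$thin,
                 seed = NULL) {
  if (model$Tn < 3L) stop("WBIC needs at least 3 observations")
  tau_star <- 1 / log(model$Tn)
  ch <- run_chain(model, iterations, burnin, thin, tau = tau_star, seed = seed)
  n_eff <- max(length(ch$loglik) / 5, 2)  # crude autocorrelation discount
  new_score("wbic", mean(ch$loglik), se = stats::sd(ch$loglik) / sqrt(n_eff),
            orientation = "higher",
            diagnostics = list(tau_star = tau_star))
}

#' Pivot selection for Chib's method
#'
#' `"naive"`: the state with the highest unnormalized log posterior over the
#' entire simulation, burn-in included. `"stabilized"`: the arg-max
#' restricted to post-burn-in states, which avoids the numerically fragile
#' extreme states the chain can traverse early under diffuse priors.
#'
#' @param chain an `sm_chain` (with its iteration history).
#' @param strategy `"stabilized"` or `"naive"`.
#' @return List with `params` (V, K, sigma2, delta2), `logpost`, `iteration`.
#' @export
select_pivot <- function(chain, strategy = c("stabilized", "naive")) {
  strategy <- match.arg(strategy)
  h <- chain$history
  idx <- if (strategy == "naive") seq_along(h$logpost)
         else seq(h$burnin + 1L, length(h$logpost))
  if (!length(idx)) stop("no post-burn-in states to select a pivot from")
  best <- idx[which.max(h$logpost[idx])]
  list(params = h$params[[best]], logpost = h$logpost[best], iteration = best)
}

# normalized log prior of a state (truncated hierarchical prior, or the
# plain normal-inverse-gamma prior of an untruncated oracle model)
state_log_prior <- function(model, st, D = NULL) {
  if (model$truncated) {
    log_prior(st$V, st$K, st$sigma2, st$delta2, D = D, cfg = model$cfg,
              variant = model$variant)
  } else {
    sum(stats::dnorm(st$V, 1, sqrt(st$delta2 * st$sigma2), log = TRUE)) +
      dinvgamma(st$sigma2, model$cfg$a_sigma, model$cfg$b_sigma, log = TRUE) +
      (if (is.na(model$cfg$delta2_fixed))
        dinvgamma(st$delta2, model$cfg$a_delta, model$cfg$b_delta, log = TRUE)
       else 0)
  }
}

# conditional density (log) of sigma2 = x given delta2 (ridge) / given K
# (g-prior), normalized by 1-D quadrature when the truncation normalizer
# makes the inverse-gamma form inexact.
sigma2_ordinate_log <- function(model, x, rss, V, delta2 = NULL, DtD = NULL) {
  cfg <- model$cfg
  d <- model$dV
  if (model$variant == "ridge") {
    shape <- cfg$a_sigma + (model$Tn + d) / 2
    rate <- cfg$b_sigma + 0.5 * (rss + sum((V - 1)^2) / delta2)
    if (!model$truncated)
      return(dinvgamma(x, shape, rate, log = TRUE))
    lker <- function(s2) dinvgamma(s2, shape, rate, log = TRUE) -
      d * stats::pnorm(0, 1, sqrt(delta2 * s2), lower.tail = FALSE, log.p = TRUE)
    lC <- log(stats::integrate(function(s2) exp(lker(s2)),
                               0, Inf, rel.tol = 1e-8)$value)
    lker(x) - lC
  } else {
    q <- drop(crossprod(V - 1, DtD %*% (V - 1))) / model$Tn
    shape <- cfg$a_sigma + (model$Tn + d) / 2
    rate <- cfg$b_sigma + 0.5 * (rss + q)
    lker <- function(s2) {
      vapply(s2, function(s) {
        Sg <- model$Tn * s * chol2inv(chol(DtD))
        dinvgamma(s, shape, rate, log = TRUE) -
          log(orthant_prob(rep(1, d), Sg, n = 1024L))
      }, 1)
    }
    lC <- log(stats::integrate(function(s2) exp(lker(s2)), 0, Inf,
                               rel.tol = 1e-6)$value)
    lker(x) - lC
  }
}

# conditional density (log) of delta2 = x given (V, sigma2), ridge prior
delta2_ordinate_log <- function(model, x, V, sigma2) {
  cfg <- model$cfg
  d <- model$dV
  shape <- cfg$a_delta + d / 2
  rate <- cfg$b_delta + sum((V - 1)^2) / (2 * sigma2)
  if (!model$truncated) return(dinvgamma(x, shape, rate, log = TRUE))
  lker <- function(d2) dinvgamma(d2, shape, rate, log = TRUE) -
    d * stats::pnorm(0, 1, sqrt(d2 * sigma2), lower.tail = FALSE, log.p = TRUE)
  lC <- log(stats::integrate(function(d2) exp(lker(d2)),
                             0, Inf, rel.tol = 1e-8)$value)
  lker(x) - lC
}

# model with the Michaelis-Menten constants frozen at Kfix
fix_k_model <- function(model, Kfix) {
  m2 <- model
  m2$nK <- 0L
  m2$k_names <- character()
  Dfix <- model$build_design(Kfix)
  m2$build_design <- function(K) Dfix
  m2
}

#' Marginal log-likelihood by Chib's method
#'
#' Uses the basic marginal identity
#' \eqn{\log p(y) = \log p(y|\tilde\theta) + \log p(\tilde\theta)
#'   - \log \hat p(\tilde\theta|y)} at a pivot \eqn{\tilde\theta} chosen by
#' [select_pivot()]. The posterior ordinate decomposes block-wise: the
#' Michaelis-Menten block by the Chib-Jeliazkov Metropolis-output estimator
#' (acceptance-weighted proposal densities toward the pivot over the main
#' run, against mean acceptance from the pivot over a reduced run); the rate
#' block as the Rao-Blackwellized truncated-normal conditional averaged over
#' the reduced run; the noise-variance block over a second reduced run; and
#' the ridge-scale block from its (quadrature-normalized) conditional.
#'
#' @param model an `sm_model`.
#' @param iterations,burnin,thin main-run lengths; reduced runs use
#'   `reduced_frac` of the main length.
#' @param pivot_strategy `"stabilized"` (default) or `"naive"`.
#' @param reduced_frac length of the reduced runs relative to the main run.
#' @param seed optional seed.
#' @param qmc_n quasi-Monte-Carlo points for orthant probabilities.
#' @return An `sm_score` (higher is better) with the ordinate decomposition
#'   in `diagnostics`.
#' @export
chib_mll <- function(model, iterations = model$cfg$iterations,
                     burnin = model$cfg$burnin, thin = model$cfg$thin,
                     pivot_strategy = c("stabilized", "naive"),
                     reduced_frac = 0.5, seed = NULL, qmc_n = 2048L) {
  pivot_strategy <- match.arg(pivot_strategy)
  if (!is.null(seed)) set.seed(seed)
  main <- run_chain(model, iterations, burnin, thin, tau = 1)
  chib_from_main(model, main, pivot_strategy, iterations, burnin, thin,
                 reduced_frac, qmc_n)
}

# ordinate computation given an existing main run (shared by the paired
# stabilized/naive evaluation in the spread-factor experiment)
chib_from_main <- function(model, main, pivot_strategy,
                           iterations, burnin, thin,
                           reduced_frac = 0.5, qmc_n = 2048L) {
  cfg <- model$cfg
  piv <- select_pivot(main, pivot_strategy)
  th <- piv$params
  Dt <- model$build_design(th$K)
  ll_t <- as.numeric(log_likelihood(model$y, Dt, th$V, th$sigma2))
  lp_t <- state_log_prior(model, th, D = Dt)

  red_iter <- max(200L, ceiling(iterations * reduced_frac))
  red_burn <- min(burnin, ceiling(red_iter / 3))

  # (i) Michaelis-Menten ordinate (Chib-Jeliazkov)
  ord_k <- 0
  if (model$nK > 0L) {
    S <- length(main$sigma2)
    num <- vapply(seq_len(S), function(s) {
      Ks <- main$K[s, ]
      ar <- k_accept_ratio(model, Ks, th$K, main$V[s, ], main$sigma2[s])
      min(0, log(ar$ratio)) + dpropose_k_log(th$K, Ks, cfg$proposal_scale)
    }, 1)
    red1 <- run_chain(fix_k_model(model, th$K), red_iter, red_burn, thin,
                      tau = 1, init = th)
    den <- vapply(seq_len(length(red1$sigma2)), function(s) {
      Kstar <- propose_k(th$K, cfg$proposal_scale)
      ar <- k_accept_ratio(model, th$K, Kstar, red1$V[s, ], red1$sigma2[s])
      min(0, log(ar$ratio))
    }, 1)
    if (all(!is.finite(den)))
      stop("Chib ordinate degenerate: all proposals from the pivot rejected")
    ord_k <- log_mean_exp(num) - log_mean_exp(den)
  } else {
    red1 <- main
  }

  # (ii) rate-vector ordinate (Rao-Blackwellized conditional at the pivot)
  ord_v_terms <- vapply(seq_along(red1$sigma2), function(s) {
    if (model$variant == "ridge") {
      vp <- v_conditional_params(Dt, model$y, red1$sigma2[s], red1$delta2[s])
    } else {
      vp <- v_conditional_params_g(Dt, model$y, red1$sigma2[s])
    }
    if (model$truncated)
      dtmvnorm_orthant_log(th$V, vp$mean, vp$sigma, qmc_n = qmc_n)
    else {
      U <- chol(vp$sigma)
      z <- forwardsolve(t(U), th$V - vp$mean)
      -0.5 * sum(z^2) - sum(log(diag(U))) - model$dV / 2 * log(2 * pi)
    }
  }, 1)
  ord_v <- log_mean_exp(ord_v_terms)

  # (iii) noise-variance ordinate over a second reduced run (V, K fixed)
  rss_t <- sum((model$y - drop(Dt %*% th$V))^2)
  DtDt <- crossprod(Dt)
  if (model$variant == "ridge" && is.na(cfg$delta2_fixed)) {
    n2 <- length(red1$sigma2)
    d2s <- numeric(n2)
    s2 <- th$sigma2; d2 <- th$delta2
    for (s in seq_len(n2)) {
      prop <- sample_delta2(th$V, s2, cfg)
      if (!model$truncated) d2 <- prop
      else {
        lacc <- log_z_vprior(model, s2, d2) - log_z_vprior(model, s2, prop)
        if (log(stats::runif(1)) < lacc) d2 <- prop
      }
      prop <- sample_sigma2(model$y, Dt, th$V, d2, cfg)
      if (!model$truncated) s2 <- prop
      else {
        lacc <- log_z_vprior(model, s2, d2) - log_z_vprior(model, prop, d2)
        if (log(stats::runif(1)) < lacc) s2 <- prop
      }
      d2s[s] <- d2
    }
    ord_s2 <- log_mean_exp(vapply(d2s, function(d2)
      sigma2_ordinate_log(model, th$sigma2, rss_t, th$V, delta2 = d2), 1))
    ord_d2 <- delta2_ordinate_log(model, th$delta2, th$V, th$sigma2)
  } else if (model$variant == "ridge") {
    ord_s2 <- sigma2_ordinate_log(model, th$sigma2, rss_t, th$V,
                                  delta2 = cfg$delta2_fixed)
    ord_d2 <- 0
  } else {
    ord_s2 <- sigma2_ordinate_log(model, th$sigma2, rss_t, th$V, DtD = DtDt)
    ord_d2 <- 0
  }

  value <- ll_t + lp_t - (ord_k + ord_v + ord_s2 + ord_d2)
  new_score(if (pivot_strategy == "naive") "chib-naive" else "chib",
            value, orientation = "higher",
            diagnostics = list(loglik = ll_t, logprior = lp_t,
                               ordinate_k = ord_k, ordinate_v = ord_v,
                               ordinate_sigma2 = ord_s2,
                               ordinate_delta2 = ord_d2,
                               pivot = piv, accept_rate = main$accept_rate))
}

#' Marginal log-likelihood by thermodynamic integration
#'
#' Power-posterior runs at the temperature ladder
#' \eqn{\tau_k = (k/K)^m, k = 0..K} (default `K = 10`, `m = 8`), each
#' yielding the mean \eqn{E_k} and variance \eqn{V_k} of the log-likelihood.
#' Plain trapezium: \eqn{\sum_k \Delta\tau_k (E_{k+1} + E_k)/2}; the
#' corrected variant subtracts \eqn{\sum_k \Delta\tau_k^2 (V_{k+1} - V_k)/12}.
#' Each temperature is an independent run initialized at the prior mean.
#'
#' @param model an `sm_model`.
#' @param ladder_k,ladder_m ladder size and power.
#' @param correction `"none"` (plain trapezium) or `"stab"` (corrected).
#' @param iterations,burnin,thin per-temperature run lengths.
#' @param seed optional seed.
#' @return An `sm_score` (higher is better) with per-temperature `E_k`,
#'   `V_k` diagnostics.
#' @export
ti_mll <- function(model, ladder_k = model$cfg$ladder_k,
                   ladder_m = model$cfg$ladder_m,
                   correction = c("none", "stab"),
                   iterations = model$cfg$iterations,
                   burnin = model$cfg$burnin, thin = model$cfg$thin,
                   seed = NULL) {
  correction <- match.arg(correction)
  if (ladder_k < 2) stop("ladder needs at least 2 intervals")
  if (!is.null(seed)) set.seed(seed)
  taus <- (seq(0, ladder_k) / ladder_k)^ladder_m
  E <- V <- SE <- numeric(length(taus))
  for (i in seq_along(taus)) {
    ch <- run_chain(model, iterations, burnin, thin, tau = taus[i])
    E[i] <- mean(ch$loglik)
    V[i] <- stats::var(ch$loglik)
    SE[i] <- stats::sd(ch$loglik) / sqrt(max(length(ch$loglik) / 5, 2))
  }
  dt <- diff(taus)
  value <- sum(dt * (E[-1] + E[-length(E)]) / 2)
  if (correction == "stab")
    value <- value - sum(dt^2 * (V[-1] - V[-length(V)]) / 12)
  se <- sqrt(sum((dt / 2)^2 * (SE[-1]^2 + SE[-length(SE)]^2)))
  new_score(if (correction == "stab") "ti-stab" else "ti", value, se = se,
            orientation = "higher",
            diagnostics = list(tau = taus, E = E, V = V))
}
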
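# Synthetic benchmark generators. Two kinds of data:
#  * a direct gradient-matching regression benchmark: iid Gaussian
#    regressors rescaled to min 0 / mean 1, with the target gradient built
#    from a degradation term plus one activating Michaelis-Menten term over
#    a 9-setting rate grid and four noise variances;
#  * a Michaelis-Menten ODE network simulator with additive Gaussian
#    observational noise, standing in for stochastically simulated
#    regulatory-network time courses.

#' The 9-setting rate grid of the regression benchmark
#'
#' Maximum reaction rates \eqn{(v_0, v_2)} with the Michaelis-Menten
#' constant fixed at \eqn{k_2 = 1}:
#' `v0 = 1, 0.5, 1.5, 2, 0.2, 2, 3, 0.2, 0.1` and
#' `v2 = 1, 1, 1, 1, 1, 0.2, 0.1, 2, 2`. Settings 8 and 9 are the
#' `v0 < 1 <= v2` regime in which the truncated g-prior is expected to
#' favour over-complex models.
#'
#' @return Data frame with columns `setting`, `v0`, `v2`, `k2`.
#' @export
table_grid <- function() {
  data.frame(setting = 1:9,
             v0 = c(1, 0.5, 1.5, 2, 0.2, 2, 3, 0.2, 0.1),
             v2 = c(1, 1, 1, 1, 1, 0.2, 0.1, 2, 2),
             k2 = 1)
}

#' Generate iid Gaussian regressor series rescaled to min 0 / mean 1
#'
#' Each species is an iid standard-normal draw per time point, shifted so
#' its minimum is 0 and rescaled so its mean is 1 (the same normalization
#' as [normalize_series()]). Time stamps are `0, 1, ..., T-1` hours; the
#' rows have no temporal structure by construction.
#'
#' @param n number of species (>= 2).
#' @param T_points number of time points (default 240).
#' @param seed optional seed.
#' @return An [timeseries()] with species `x1 ... xn`.
#' @export
generate_regressors <- function(n = 4L, T_points = 240L, seed = NULL) {
  stopifnot(n >= 2, T_points >= 2)
  if (!is.null(seed)) set.seed(seed)
  vals <- matrix(stats::rnorm(T_points * n), T_points, n,
                 dimnames = list(NULL, paste0("x", seq_len(n))))
  normalize_series(timeseries(vals, times = seq_len(T_points) - 1))
}

#' Generate a gradient-matching regression benchmark instance
#'
#' The observed gradient of the target is
#' \deqn{y(t_j) = -v_0 x_1(t_j) + v_2 \frac{x_2(t_j)}{x_2(t_j) + k_2}
#'       + \epsilon_j,\qquad \epsilon_j \sim N(0, \sigma^2),}
#' where `x1` plays the degradation role (it stands in for the target's own
#' concentration), `x2` is the true activating regulator, and `x3 ... xn`
#' are inactive decoys generated identically to `x2`.
#'
#' @param setting row of [table_grid()] to use (1-9).
#' @param sigma2 noise variance (0 allowed for noiseless checks); the
#'   benchmark uses 0.05, 0.1, 0.2 and 0.4.
#' @param T_points number of time points (default 240).
#' @param n number of species (default 4).
#' @param seed optional seed.
#' @return List with `ts` (regressors, target concentration in column
#'   `x1`), `grads` (a [gradient_set()] whose `x1` column holds the target
#'   gradient `y`), `truth` (the generating parameters) and `true_parents`
#'   (`"x2"`).
#' @export
generate_gradient_data <- function(setting = 1L, sigma2 = 0.05,
                                   T_points = 240L, n = 4L, seed = NULL) {
  grid <- table_grid()
  stopifnot(setting %in% grid$setting, sigma2 >= 0)
  if (!is.null(seed)) set.seed(seed)
  par <- grid[grid$setting == setting, ]
  ts <- generate_regressors(n, T_points)
  y0 <- -par$v0 * ts$values[, "x1"] +
    par$v2 * michaelis_menten_term(ts$values[, "x2"], par$k2, "activator")
  y <- y0 + if (sigma2 > 0) stats::rnorm(T_points, 0, sqrt(sigma2)) else 0
  gv <- matrix(y, ncol = 1, dimnames = list(NULL, "x1"))
  grads <- gradient_set(gv, ts$times, species = "x1",
                        condition = ts$condition, method = "analytical")
  list(ts = ts, grads = grads,
       truth = list(v0 = par$v0, v2 = par$v2, k2 = par$k2, sigma2 = sigma2,
                    noiseless = y0),
       true_parents = "x2")
}

#' Simulate a Michaelis-Menten ODE network with observational noise
#'
#' Integrates the kinetic system
#' \deqn{\frac{dx_i}{dt} = -v_{0,i} x_i + \sum_u v_{u,i}\,\mathrm{MM}(x_u, k_{u,i})
#'       + \sum_{(a,b)} v_{ab,i}\,\mathrm{MM}(x_a)\,\mathrm{MM}(x_b)}
#' with a stiff-capable adaptive integrator (rtol 1e-8), samples the
#' trajectory at the requested times, and adds iid Gaussian observational
#' noise. Noise perturbs observations only, never the dynamics.
#'
#' @param net an [network_spec()].
#' @param params list with `v0` (named per node), `edges` (data frame
#'   `regulator`, `target`, `v`, `k`) and optionally `complexes` (data
#'   frame `regulator_a`, `regulator_b`, `target`, `v`, `k_a`, `k_b`).
#'   [default_network_params()] builds a reasonable set.
#' @param times sampling times (default 2-h intervals over 24 h).
#' @param x0 named initial state (default 1 for every node).
#' @param noise_sd observational noise standard deviation.
#' @param conditions number of independent replicate conditions, each with
#'   its own noise (and its own randomized initial state after the first).
#' @param x0_jitter multiplicative range for the per-condition initial-state
#'   randomization; wide ranges decorrelate the species' trajectories
#'   across conditions.
#' @param seed optional seed.
#' @return List with `ts` (an [timeseries()]), `net`, `params`,
#'   `noise_sd`, and the noiseless `trajectories` (one matrix per
#'   condition).
#' @export
simulate_mm_network <- function(net, params = default_network_params(net),
                                times = seq(0, 24, by = 2), x0 = NULL,
                                noise_sd = 0.05, conditions = 1L,
                                x0_jitter = c(0.5, 1.5), seed = NULL) {
  stopifnot(all(diff(times) > 0), noise_sd >= 0, conditions >= 1)
  if (!is.null(seed)) set.seed(seed)
  nodes <- net$nodes
  if (is.null(x0)) x0 <- stats::setNames(rep(1, length(nodes)), nodes)
  deriv <- function(t, x, p) {
    dx <- -params$v0[nodes] * x
    ed <- params$edges
    if (!is.null(ed) && nrow(ed)) {
      for (r in seq_len(nrow(ed))) {
        sgn <- net$edges$sign[net$edges$regulator == ed$regulator[r] &
                                net$edges$target == ed$target[r]]
        dx[ed$target[r]] <- dx[ed$target[r]] +
          ed$v[r] * michaelis_menten_term(x[ed$regulator[r]], ed$k[r], sgn)
      }
    }
    cx <- params$complexes
    if (!is.null(cx) && nrow(cx)) {
      for (r in seq_len(nrow(cx))) {
        cc <- net$complexes[net$complexes$regulator_a == cx$regulator_a[r] &
                              net$complexes$regulator_b == cx$regulator_b[r] &
                              net$complexes$target == cx$target[r], ]
        dx[cx$target[r]] <- dx[cx$target[r]] + cx$v[r] *
          michaelis_menten_term(x[cx$regulator_a[r]], cx$k_a[r], cc$sign_a) *
          michaelis_menten_term(x[cx$regulator_b[r]], cx$k_b[r], cc$sign_b)
      }
    }
    list(dx)
  }
  vals <- NULL; tvec <- NULL; cond <- NULL; trajs <- list()
  for (cidx in seq_len(conditions)) {
    xinit <- if (cidx == 1) x0
             else pmax(x0 * stats::runif(length(x0), x0_jitter[1],
                                         x0_jitter[2]), 1e-3)
    sol <- deSolve::ode(y = xinit, times = times, func = deriv, parms = NULL,
                        method = "lsoda", rtol = 1e-8, atol = 1e-10)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE integration failed in condition ", cidx)
    traj <- unname(sol[, -1, drop = FALSE])
    colnames(traj) <- nodes
    trajs[[cidx]] <- traj
    obs <- traj + if (noise_sd > 0)
      matrix(stats::rnorm(length(traj), 0, noise_sd), nrow(traj)) else 0
    vals <- rbind(vals, obs)
    tvec <- c(tvec, times)
    cond <- c(cond, rep(paste0("c", cidx), length(times)))
  }
  list(ts = timeseries(pmax(vals, 0), tvec, nodes, cond),
       net = net, params = params, noise_sd = noise_sd,
       trajectories = trajs)
}

#' Default kinetic parameters for a network simulation
#'
#' Degradation rates, edge rates and Michaelis-Menten constants of order 1,
#' mildly jittered so the system is not symmetric.
#'
#' @param net an [network_spec()].
#' @param seed optional seed.
#' @return Parameter list as expected by [simulate_mm_network()].
#' @export
default_network_params <- function(net, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- list(v0 = stats::setNames(stats::runif(length(net$nodes), 0.6, 1.2),
                                 net$nodes))
  if (nrow(net$edges))
    p$edges <- data.frame(regulator = net$edges$regulator,
                          target = net$edges$target,
                          v = stats::runif(nrow(net$edges), 0.8, 1.5),
                          k = stats::runif(nrow(net$edges), 0.5, 1.5),
                          stringsAsFactors = FALSE)
  if (!is.null(net$complexes) && nrow(net$complexes))
    p$complexes <- data.frame(regulator_a = net$complexes$regulator_a,
                              regulator_b = net$complexes$regulator_b,
                              target = net$complexes$target,
                              v = stats::runif(nrow(net$complexes), 1, 2),
                              k_a = stats::runif(nrow(net$complexes), 0.5, 1.5),
                              k_b = stats::runif(nrow(net$complexes), 0.5, 1.5),
                              stringsAsFactors = FALSE)
  p
}

#' Conjugate linear-Gaussian oracle model with closed-form evidence
#'
#' An untruncated Bayesian linear regression instance used to validate the
#' evidence estimators: \eqn{y = X\beta + \epsilon} with
#' \eqn{\beta | \sigma^2 \sim N(1, g\,\sigma^2 I)} and
#' \eqn{\sigma^2 \sim IG(a, b)}. The marginal likelihood is available in
#' closed form (multivariate-t identity), so Chib's method and
#' thermodynamic integration can be checked against an exact value.
#'
#' @param T_points number of observations.
#' @param d number of regression coefficients.
#' @param g prior scale of the coefficients.
#' @param a,b inverse-gamma shape and rate of the noise variance.
#' @param seed optional seed.
#' @return List with `model` (an untruncated `sm_model` usable by
#'   [run_chain()], [chib_mll()], [ti_mll()], [wbic()]), `X`, `y`,
#'   and `log_evidence` (exact).
#' @export
conjugate_toy <- function(T_points = 50L, d = 2L, g = 1, a = 2, b = 1,
                          seed = NULL) {
  stopifnot(T_points >= 3, d >= 1, g > 0, a > 0, b > 0)
  if (!is.null(seed)) set.seed(seed)
  X <- cbind(1, matrix(stats::rnorm(T_points * (d - 1L)), T_points))
  colnames(X) <- paste0("b", seq_len(d))
  beta <- rep(1, d) + stats::rnorm(d, 0, sqrt(g))
  y <- drop(X %*% beta) + stats::rnorm(T_points)
  cfg <- run_config(a_sigma = a, b_sigma = b, delta2_fixed = g,
                    iterations = 4000L, burnin = 1000L, thin = 2L)
  model <- gm_model(y, function(K) X, k_names = character(), cfg = cfg,
                    variant = "ridge", truncated = FALSE)
  list(model = model, X = X, y = y,
       log_evidence = nig_log_evidence(X, y, m0 = rep(1, d),
                                       V0 = diag(g, d), a = a, b = b))
}

# exact log marginal likelihood of the normal-inverse-gamma regression
nig_log_evidence <- function(X, y, m0, V0, a, b) {
  Tn <- length(y)
  V0inv <- chol2inv(chol(V0))
  Vninv <- V0inv + crossprod(X)
  Vn <- chol2inv(chol(Vninv))
  mn <- drop(Vn %*% (V0inv %*% m0 + crossprod(X, y)))
  an <- a + Tn / 2
  bn <- b + 0.5 * (sum(y^2) + drop(crossprod(m0, V0inv %*% m0)) -
                     drop(crossprod(mn, Vninv %*% mn)))
  as.numeric(-Tn / 2 * log(2 * pi) +
    0.5 * (determinant(V0inv)$modulus - determinant(Vninv)$modulus) +
    a * log(b) - an * log(bn) + lgamma(an) - lgamma(a))
}
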
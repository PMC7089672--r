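#' Run configuration
#'
#' Bundles the tunable settings of the inference pipeline: MCMC run lengths,
#' prior hyperparameters, gradient-estimation settings and model-selection
#' settings. All hyperparameters must be strictly positive.
#'
#' @param iterations MCMC iterations per chain (including burn-in).
#' @param burnin burn-in iterations discarded from each chain.
#' @param thin thinning interval for stored draws.
#' @param chains number of independent chains.
#' @param proposal_scale variance of the Gaussian random-walk proposal for the
#'   Michaelis-Menten constants (the proposal covariance is
#'   `proposal_scale * I`).
#' @param nu prior variance of the Michaelis-Menten constants (truncated
#'   normal centred at 1).
#' @param a_sigma,b_sigma inverse-gamma shape/rate for the noise variance.
#' @param a_delta,b_delta inverse-gamma shape/rate for the ridge scale
#'   \eqn{\delta^2}.
#' @param delta2_fixed either `NA` (sample \eqn{\delta^2}) or a positive value
#'   at which \eqn{\delta^2} is held fixed ("spread factor" experiments).
#' @param gradient_method `"gp"` or `"fd"`.
#' @param kernel GP kernel family: `"rbf"`, `"per"`, `"mat32"`, `"mat52"`.
#' @param dt finite-difference time step in hours.
#' @param criterion default model-selection criterion.
#' @param ladder_k number of thermodynamic-integration ladder intervals.
#' @param ladder_m power of the temperature ladder \eqn{\tau_k = (k/K)^m}.
#' @param max_cardinality maximum number of regulators per parent set.
#' @param normalize whether pipelines rescale series to min 0 / mean 1.
#' @return An object of class `sm_config`.
#' @export
run_config <- function(iterations = 10000L, burnin = 5000L, thin = 5L,
                       chains = 2L, proposal_scale = 0.1,
                       nu = 0.5, a_sigma = 0.01, b_sigma = 0.01,
                       a_delta = 0.01, b_delta = 0.01, delta2_fixed = NA,
                       gradient_method = c("gp", "fd"),
                       kernel = c("rbf", "per", "mat32", "mat52"), dt = 2,
                       criterion = c("chib", "chib-naive", "ti", "ti-stab",
                                     "dic", "waic", "cvic", "wbic"),
                       ladder_k = 10L, ladder_m = 8, max_cardinality = 3L,
                       normalize = TRUE) {
  gradient_method <- match.arg(gradient_method)
  kernel <- match.arg(kernel)
  criterion <- match.arg(criterion)
  stopifnot(iterations > burnin, burnin >= 0, thin >= 1, chains >= 1,
            proposal_scale > 0, nu > 0, a_sigma > 0, b_sigma > 0,
            a_delta > 0, b_delta > 0, dt > 0, ladder_k >= 2, ladder_m > 0,
            max_cardinality >= 0)
  if (!is.na(delta2_fixed)) stopifnot(delta2_fixed > 0)
  structure(
    list(iterations = as.integer(iterations), burnin = as.integer(burnin),
         thin = as.integer(thin), chains = as.integer(chains),
         proposal_scale = proposal_scale, nu = nu,
         a_sigma = a_sigma, b_sigma = b_sigma,
         a_delta = a_delta, b_delta = b_delta, delta2_fixed = delta2_fixed,
         gradient_method = gradient_method, kernel = kernel, dt = dt,
         criterion = criterion, ladder_k = as.integer(ladder_k),
         ladder_m = ladder_m, max_cardinality = as.integer(max_cardinality),
         normalize = normalize),
    class = "sm_config"
  )
}

#' @export
print.sm_config <- function(x, ...) {
  cat("<sm_config> ", x$chains, " chain(s) x ", x$iterations,
      " iterations (burn-in ", x$burnin, ", thin ", x$thin, ")\n",
      "  priors: nu=", x$nu, ", IG(", x$a_sigma, ",", x$b_sigma, ") on sigma2, ",
      if (is.na(x$delta2_fixed))
        paste0("IG(", x$a_delta, ",", x$b_delta, ") on delta2")
      else paste0("delta2 fixed at ", x$delta2_fixed), "\n",
      "  gradient: ", x$gradient_method, " (kernel ", x$kernel, ", dt ",
      x$dt, " h); criterion: ", x$criterion, "\n", sep = "")
  invisible(x)
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys fall back to the [run_config()]
#' defaults.
#' @param path file path.
#' @return An `sm_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(doc), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, doc)
}
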
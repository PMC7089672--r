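#' Area under the ROC curve of an edge ranking
#'
#' Rank-based computation equivalent to the Mann-Whitney statistic; tied
#' scores contribute 1/2. Equals 1 iff every true edge outranks every
#' non-edge and 0.5 in expectation under random scores.
#'
#' @param scores numeric edge scores (higher = more confident).
#' @param truth 0/1 (or logical) true adjacency, same length.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, truth) {
  truth <- as.integer(as.logical(truth))
  stopifnot(length(scores) == length(truth))
  n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("undefined score: need at least one true edge and one non-edge")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve of an edge ranking
#'
#' Average-precision summation: precision is accumulated at each recall
#' step, with no linear interpolation between PR points (linear PR
#' interpolation is invalid). Tied scores are handled by averaging over the
#' tie group.
#'
#' @inheritParams auroc
#' @return AUPREC in \[0, 1\].
#' @export
auprec <- function(scores, truth) {
  truth <- as.integer(as.logical(truth))
  stopifnot(length(scores) == length(truth))
  n1 <- sum(truth == 1L)
  if (n1 == 0L) stop("undefined score: need at least one true edge")
  o <- order(-scores)
  s <- scores[o]; y <- truth[o]
  # within tie groups, credit the expected number of positives per position
  grp <- cumsum(!duplicated(s))
  y_adj <- stats::ave(y, grp)
  tp <- cumsum(y_adj)
  prec <- tp / seq_along(tp)
  sum(prec * y_adj) / n1
}

#' Main-effects ANOVA with sum-to-zero constraints
#'
#' Least-squares fit of the additive model
#' \eqn{y = \mu + A_i + B_j + \dots + \epsilon} with each effect's levels
#' constrained to sum to zero, plus t-based confidence intervals for every
#' level effect from the residual variance. Used to disentangle factors
#' (network structure, gradient type, method, ...) in benchmark score
#' tables; the design need not be balanced.
#'
#' @param table data frame containing the effect columns and the score.
#' @param effects character vector of effect column names (>= 2 levels
#'   each).
#' @param response name of the score column (default `"score"`).
#' @param level confidence level (default 0.95).
#' @return List of class `sm_anova` with `grand_mean`, a data frame
#'   `effects` (effect, level, estimate, lower, upper) and
#'   `residual_variance`.
#' @export
anova_effects <- function(table, effects, response = "score", level = 0.95) {
  stopifnot(all(c(effects, response) %in% names(table)))
  df <- table
  for (e in effects) {
    df[[e]] <- factor(df[[e]])
    if (nlevels(df[[e]]) < 2L) stop("effect '", e, "' needs >= 2 levels")
  }
  ctr <- stats::setNames(rep(list("contr.sum"), length(effects)), effects)
  fml <- stats::as.formula(paste(response, "~", paste(effects, collapse = " + ")))
  fit <- tryCatch(stats::lm(fml, data = df, contrasts = ctr),
                  error = function(e) e)
  if (inherits(fit, "error")) stop("ANOVA fit failed: ", conditionMessage(fit))
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased terms: ", paste(bad, collapse = ", "))
  }
  sig2 <- stats::sigma(fit)^2
  # zero-residual designs are legitimate here; silence lm's perfect-fit note
  vc <- suppressWarnings(stats::vcov(fit))
  cf <- stats::coef(fit)
  dfres <- fit$df.residual
  tq <- if (dfres > 0) stats::qt(1 - (1 - level) / 2, dfres) else 0
  rows <- list()
  for (e in effects) {
    lv <- levels(df[[e]])
    L <- length(lv)
    nms <- paste0(e, seq_len(L - 1))
    for (li in seq_len(L)) {
      w <- stats::setNames(rep(0, length(cf)), names(cf))
      if (li < L) w[nms[li]] <- 1 else w[nms] <- -1
      est <- sum(w * cf)
      se <- sqrt(drop(t(w) %*% vc %*% w))
      rows[[length(rows) + 1L]] <-
        data.frame(effect = e, level = lv[li], estimate = est,
                   lower = est - tq * se, upper = est + tq * se,
                   stringsAsFactors = FALSE)
    }
  }
  structure(list(grand_mean = unname(cf["(Intercept)"]),
                 effects = do.call(rbind, rows),
                 residual_variance = sig2, df_residual = dfres),
            class = "sm_anova")
}

#' @export
print.sm_anova <- function(x, ...) {
  cat("<sm_anova> grand mean ", signif(x$grand_mean, 5),
      ", residual variance ", signif(x$residual_variance, 5), "\n", sep = "")
  print(x$effects, row.names = FALSE)
  invisible(x)
}

#' Spread-factor sweep of the model-selection criteria
#'
#' For each spread factor `sf` the ridge scale \eqn{\delta^2} is fixed at
#' `sf` (and optionally \eqn{\nu} too), regression-benchmark data are
#' generated, and the true parent set `{x2}` and the over-complex set
#' `{x2, x3}` are scored with each requested criterion. Differences are
#' oriented so positive favours the true model. Increasingly diffuse priors
#' probe the Lindley-paradox regime in which the evidence increasingly
#' penalizes the over-complex model while plug-in criteria destabilize.
#'
#' @param sf_list spread factors to sweep.
#' @param criteria criteria to evaluate (names as in [run_config()]).
#' @param replicates independent data instantiations per spread factor.
#' @param settings,sigma2 generator conditions; when several are given, each
#'   replicate's difference is averaged across the full
#'   `settings x sigma2` condition grid (one fresh data instantiation per
#'   cell), the construction used for the benchmark's box plots.
#' @param T_points time points per instantiation.
#' @param vary_nu also set \eqn{\nu} = sf (second scenario).
#' @param cfg base [run_config()]; its `delta2_fixed` (and optionally `nu`)
#'   are overridden per cell, and its run lengths are used as-is.
#' @param seed base seed.
#' @return Long data frame with columns `sf`, `criterion`, `replicate`,
#'   `difference` (positive favours the true model, averaged over the
#'   condition grid).
#' @export
spread_factor_experiment <- function(sf_list = c(0.01, 1, 100, 1e4, 1e8),
                                     criteria = c("dic", "waic", "chib"),
                                     replicates = 10L, settings = 1L,
                                     sigma2 = 0.05, T_points = 240L,
                                     vary_nu = FALSE, cfg = run_config(),
                                     seed = 1L) {
  ic_crit <- intersect(criteria, c("dic", "waic", "cvic"))
  chib_crit <- intersect(criteria, c("chib", "chib-naive"))
  other_crit <- setdiff(criteria, c(ic_crit, chib_crit))
  cells <- expand.grid(setting = settings, s2 = sigma2)
  out <- list()
  add_row <- function(sf, crit, rep_i, diff)
    out[[length(out) + 1L]] <<-
      data.frame(sf = sf, criterion = crit, replicate = rep_i,
                 difference = diff, stringsAsFactors = FALSE)

  for (sfi in seq_along(sf_list)) {
    sf <- sf_list[sfi]
    cfg_c <- cfg
    cfg_c$delta2_fixed <- sf
    if (vary_nu) cfg_c$nu <- sf
    for (rep_i in seq_len(replicates)) {
      # per-criterion accumulator over the condition grid
      acc <- stats::setNames(rep(0, length(criteria)), criteria)
      for (ci in seq_len(nrow(cells))) {
        dat <- generate_gradient_data(cells$setting[ci], cells$s2[ci],
                                      T_points,
                                      seed = seed + 9973L * sfi +
                                        101L * rep_i + ci)
        models <- lapply(list(true = parent_set("x1", "x2"),
                              over = parent_set("x1", c("x2", "x3"))),
                         function(ps) model_from_data(dat$ts, dat$grads, ps,
                                                      cfg_c, "ridge"))
        # one posterior run per model serves all sample-based IC
        if (length(ic_crit)) {
          chains <- lapply(seq_along(models), function(i) {
            set.seed(seed + 89L * sfi + 5L * rep_i + 11L * ci + i)
            run_chain(models[[i]])
          })
          for (crit in ic_crit) {
            f <- switch(crit, dic = dic, waic = waic, cvic = cvic)
            acc[crit] <- acc[crit] +
              score_difference(f(chains[[1]]), f(chains[[2]]))
          }
        }
        # one main run per model serves both Chib pivot strategies
        if (length(chib_crit)) {
          sc <- lapply(seq_along(models), function(i) {
            m <- models[[i]]
            set.seed(seed + 211L * sfi + 5L * rep_i + 13L * ci + i)
            main <- run_chain(m)
            lapply(stats::setNames(chib_crit, chib_crit), function(crit)
              chib_from_main(m, main,
                             if (crit == "chib") "stabilized" else "naive",
                             m$cfg$iterations, m$cfg$burnin, m$cfg$thin))
          })
          for (crit in chib_crit)
            acc[crit] <- acc[crit] +
              score_difference(sc[[1]][[crit]], sc[[2]][[crit]])
        }
        for (crit in other_crit) {
          cfg_o <- cfg_c
          cfg_o$criterion <- crit
          s_true <- score_one_set(dat$ts, dat$grads, parent_set("x1", "x2"),
                                  cfg_o, "ridge",
                                  seed = seed + 31L * sfi + 7L * rep_i + ci)
          s_over <- score_one_set(dat$ts, dat$grads,
                                  parent_set("x1", c("x2", "x3")), cfg_o,
                                  "ridge",
                                  seed = seed + 31L * sfi + 7L * rep_i +
                                    ci + 3L)
          acc[crit] <- acc[crit] + score_difference(s_true, s_over)
        }
      }
      for (crit in criteria)
        add_row(sf, crit, rep_i, unname(acc[crit]) / nrow(cells))
    }
  }
  do.call(rbind, out)
}

#' Ridge-versus-g-prior comparison on the regression benchmark
#'
#' Scores the true parent set `{x2}` against the six wrong parent sets
#' under both prior variants with the stabilized-Chib marginal likelihood,
#' over a grid of generator settings and replicates. Differences are
#' oriented positive-favours-true. The `v0 < 1 <= v2` settings (8 and 9)
#' are the regime where the g-prior is expected to prefer over-complex
#' models.
#'
#' @param settings generator settings to include.
#' @param sigma2 noise variance.
#' @param replicates data instantiations per setting.
#' @param variants prior variants to run.
#' @param alternatives which wrong parent sets to score: `"all"` (six) or
#'   `"overcomplex"` (the three supersets of `{x2}`).
#' @param cfg base [run_config()] (run lengths).
#' @param T_points time points per instantiation.
#' @param seed base seed.
#' @return Long data frame: `variant`, `setting`, `replicate`,
#'   `alternative`, `difference` (positive favours the true model).
#' @export
gprior_comparison_experiment <- function(settings = c(1, 8, 9), sigma2 = 0.1,
                                         replicates = 5L,
                                         variants = c("ridge", "gprior"),
                                         alternatives = c("all", "overcomplex"),
                                         cfg = run_config(), T_points = 240L,
                                         seed = 1L) {
  alternatives <- match.arg(alternatives)
  alts <- list(c("x2", "x3"), c("x2", "x4"), c("x2", "x3", "x4"))
  if (alternatives == "all")
    alts <- c(alts, list("x3", "x4", c("x3", "x4")))
  out <- list()
  for (st in settings) {
    for (rep_i in seq_len(replicates)) {
      dat <- generate_gradient_data(st, sigma2, T_points,
                                    seed = seed + 991L * st + rep_i)
      for (variant in variants) {
        cfg_c <- cfg
        cfg_c$criterion <- "chib"
        s_true <- score_one_set(dat$ts, dat$grads, parent_set("x1", "x2"),
                                cfg_c, variant,
                                seed = seed + 13L * st + rep_i)
        for (al in alts) {
          s_alt <- score_one_set(dat$ts, dat$grads, parent_set("x1", al),
                                 cfg_c, variant,
                                 seed = seed + 17L * st + rep_i)
          out[[length(out) + 1L]] <-
            data.frame(variant = variant, setting = st, replicate = rep_i,
                       alternative = if (length(al))
                         paste(al, collapse = ",") else "{}",
                       difference = score_difference(s_true, s_alt),
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}
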
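#' Enumerate admissible parent sets for a target
#'
#' All subsets of the candidate regulators with size up to `max_card`, each
#' implicitly augmented with the always-present degradation term, in a
#' deterministic order (by size, then lexicographically). With 3 candidates
#' and maximum cardinality 3 this yields 8 candidate models. When
#' `complexes` are supplied (prior knowledge about complex formation), a
#' pair's product term is added to every set containing both members.
#'
#' @param target target species name.
#' @param candidates character vector of candidate regulators.
#' @param max_card maximum parent-set cardinality (>= 0).
#' @param signs named character vector of signs per candidate (default all
#'   activators).
#' @param complexes optional list of length-2 vectors of admissible
#'   multiplicative pairs.
#' @return List of [parent_set()] objects.
#' @export
enumerate_parent_sets <- function(target, candidates, max_card = 3L,
                                  signs = NULL, complexes = NULL) {
  stopifnot(max_card >= 0)
  candidates <- sort(as.character(candidates))
  if (is.null(signs))
    signs <- stats::setNames(rep("activator", length(candidates)), candidates)
  subsets <- list(character())
  for (k in seq_len(min(max_card, length(candidates)))) {
    combos <- utils::combn(candidates, k, simplify = FALSE)
    subsets <- c(subsets, combos)
  }
  lapply(subsets, function(regs) {
    prs <- NULL
    if (!is.null(complexes)) {
      prs <- Filter(function(pr) all(pr %in% regs), complexes)
      if (!length(prs)) prs <- NULL
    }
    parent_set(target, regs, signs = unname(signs[regs]), complexes = prs)
  })
}

parent_set_label <- function(ps) {
  if (!length(ps$regulators)) return("{}")
  paste0("{", paste(ps$regulators, collapse = ","), "}")
}

#' Score every candidate parent set of a target
#'
#' Runs the sampler and the configured selection criterion for each
#' enumerated parent set. Scores are returned on the log scale with a
#' common orientation (`higher` is better: IC values are negated and halved
#' so that exponentiating approximates a model weight). Per-set failures
#' are recorded and the set is dropped with a warning rather than aborting
#' the target.
#'
#' @param ts concentrations ([timeseries()]).
#' @param grads gradients ([gradient_set()]).
#' @param target target species.
#' @param candidates candidate regulators (default: every other species).
#' @param cfg an [run_config()]; `cfg$criterion` picks the score.
#' @param variant prior variant.
#' @param seed base seed; set `s` uses `seed + s`.
#' @param signs,complexes forwarded to [enumerate_parent_sets()].
#' @return Data frame with columns `parents`, `score` (log scale,
#'   higher-better), `criterion`, plus the `sm_score` objects in
#'   `attr(, "scores")` and the parent sets in `attr(, "parent_sets")`.
#' @export
score_parent_sets <- function(ts, grads, target,
                              candidates = setdiff(colnames(ts$values), target),
                              cfg = run_config(), variant = "ridge",
                              seed = NULL, signs = NULL, complexes = NULL) {
  sets <- enumerate_parent_sets(target, candidates, cfg$max_cardinality,
                                signs = signs, complexes = complexes)
  scores <- vector("list", length(sets))
  vals <- rep(NA_real_, length(sets))
  for (i in seq_along(sets)) {
    res <- tryCatch(
      score_one_set(ts, grads, sets[[i]], cfg, variant,
                    seed = if (is.null(seed)) NULL else seed + i),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("parent set ", parent_set_label(sets[[i]]), " failed: ",
              conditionMessage(res))
      next
    }
    scores[[i]] <- res
    vals[i] <- if (res$orientation == "higher") res$value else -res$value / 2
  }
  out <- data.frame(parents = vapply(sets, parent_set_label, ""),
                    score = vals, criterion = cfg$criterion,
                    stringsAsFactors = FALSE)
  attr(out, "scores") <- scores
  attr(out, "parent_sets") <- sets
  out
}

# one (parent set, criterion) evaluation
score_one_set <- function(ts, grads, ps, cfg, variant, seed = NULL) {
  model <- model_from_data(ts, grads, ps, cfg, variant)
  crit <- cfg$criterion
  if (crit %in% c("chib", "chib-naive")) {
    chib_mll(model, pivot_strategy = if (crit == "chib") "stabilized" else "naive",
             seed = seed)
  } else if (crit %in% c("ti", "ti-stab")) {
    ti_mll(model, correction = if (crit == "ti") "none" else "stab",
           seed = seed)
  } else if (crit == "wbic") {
    wbic(model, seed = seed)
  } else {
    ch <- run_chain(model, seed = seed)
    switch(crit, dic = dic(ch), waic = waic(ch), cvic = cvic(ch))
  }
}

#' Edge posteriors by Bayesian model averaging
#'
#' The marginal posterior probability that `u` regulates the target is the
#' normalized sum of model weights over all parent sets containing `u`:
#' \deqn{p(u \to i | D) = \frac{\sum_{\pi \ni u} e^{s(\pi)} p(\pi)}
#'                             {\sum_{\pi} e^{s(\pi)} p(\pi)}}
#' computed by log-sum-exp with a uniform parent-set prior by default.
#'
#' @param scores data frame from [score_parent_sets()] (or any data frame
#'   with `parents` labels and log `score`s plus a `parent_sets` attribute).
#' @param log_prior optional vector of log prior weights per set (uniform
#'   when omitted).
#' @return Named numeric vector of posterior probabilities, one per
#'   candidate regulator.
#' @export
edge_posterior <- function(scores, log_prior = NULL) {
  sets <- attr(scores, "parent_sets")
  s <- scores$score
  ok <- is.finite(s)
  if (!any(ok)) stop("undefined posterior: no finite parent-set scores")
  if (is.null(log_prior)) log_prior <- rep(0, length(s))
  lw <- s[ok] + log_prior[ok]
  lw <- lw - max(lw)
  total <- log(sum(exp(lw)))
  cand <- sort(unique(unlist(lapply(sets, function(p) p$regulators))))
  vapply(cand, function(u) {
    has <- vapply(sets[ok], function(p) u %in% p$regulators, TRUE)
    if (!any(has)) return(0)
    exp(log(sum(exp(lw[has]))) - total)
  }, 1)
}

#' Full edge-posterior matrix for all targets
#'
#' Applies [score_parent_sets()] and [edge_posterior()] to every node in
#' turn; candidates default to all other nodes.
#'
#' @inheritParams score_parent_sets
#' @return Matrix \[regulator x target\] of posterior probabilities with a
#'   `"provenance"` attribute naming the criterion.
#' @export
edge_posterior_matrix <- function(ts, grads, cfg = run_config(),
                                  variant = "ridge", seed = NULL) {
  nodes <- colnames(ts$values)
  M <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_along(nodes)) {
    sc <- score_parent_sets(ts, grads, nodes[i], cfg = cfg, variant = variant,
                            seed = if (is.null(seed)) NULL else seed + 100L * i)
    p <- edge_posterior(sc)
    M[names(p), nodes[i]] <- p
  }
  attr(M, "provenance") <- cfg$criterion
  M
}

#' Rank candidate networks by total marginal log-likelihood
#'
#' For each candidate network the parent set of every target is read off the
#' network's edges (and complex pairs), scored with the configured
#' criterion, and summed over targets; dense ranks are assigned (1 = best
#' total score). Intended for confusion-matrix protocols where data
#' simulated from one network are scored against several candidates.
#'
#' @param ts,grads data.
#' @param candidates list of [network_spec()] candidate networks.
#' @param cfg an [run_config()].
#' @param variant prior variant.
#' @param seed base seed.
#' @return Data frame with `network`, `total_score`, `rank`.
#' @export
rank_networks <- function(ts, grads, candidates, cfg = run_config(),
                          variant = "ridge", seed = NULL) {
  totals <- vapply(seq_along(candidates), function(ci) {
    net <- candidates[[ci]]
    tot <- 0
    for (tg in net$nodes) {
      ed <- net$edges[net$edges$target == tg, , drop = FALSE]
      prs <- NULL
      if (!is.null(net$complexes)) {
        cc <- net$complexes[net$complexes$target == tg, , drop = FALSE]
        if (nrow(cc))
          prs <- lapply(seq_len(nrow(cc)), function(r)
            c(cc$regulator_a[r], cc$regulator_b[r]))
      }
      ps <- parent_set(tg, ed$regulator, signs = ed$sign, complexes = prs)
      # seed from the parent-set content (not the candidate index) so that
      # identical candidate networks receive identical scores
      ps_hash <- sum(utf8ToInt(paste(tg, parent_set_label(ps)))) %% 9973L
      sc <- score_one_set(ts, grads, ps, cfg, variant,
                          seed = if (is.null(seed)) NULL
                                 else seed + ps_hash)
      tot <- tot + if (sc$orientation == "higher") sc$value else -sc$value / 2
    }
    tot
  }, 1)
  nm <- names(candidates)
  if (is.null(nm)) nm <- paste0("net", seq_along(candidates))
  rk <- match(-totals, sort(unique(-totals)))  # dense ranks, 1 = best
  data.frame(network = nm, total_score = totals, rank = rk,
             stringsAsFactors = FALSE)
}

#' Write a ranked edge table
#'
#' Tab-separated columns `target`, `regulator`, `posterior`, `rank` with
#' dense ranking by descending posterior (ties share a rank). An empty
#' matrix produces a header-only file.
#'
#' @param edges matrix \[regulator x target\] of posterior probabilities in
#'   \[0, 1\] (e.g. from [edge_posterior_matrix()]).
#' @param path output path.
#' @export
write_edge_table <- function(edges, path) {
  stopifnot(is.matrix(edges))
  if (length(edges) && (min(edges) < 0 || max(edges) > 1))
    stop("posteriors must lie in [0, 1]")
  df <- data.frame(target = character(), regulator = character(),
                   posterior = numeric(), rank = integer())
  if (length(edges)) {
    df <- expand.grid(regulator = rownames(edges), target = colnames(edges),
                      stringsAsFactors = FALSE)
    df <- df[df$regulator != df$target, , drop = FALSE]
    df$posterior <- edges[cbind(df$regulator, df$target)]
    df$rank <- match(-df$posterior, sort(unique(-df$posterior)))
    df <- df[order(df$rank, df$target, df$regulator),
             c("target", "regulator", "posterior", "rank")]
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed writing '", path, "': ", conditionMessage(ok))
  invisible(path)
}
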
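test_that("information criteria match hand recomputation from stored draws", {
  inst <- small_instance(seed = 51, T_points = 25)
  ch <- run_chain(inst$model, seed = 52)

  d <- suppressWarnings(dic(ch))
  dbar <- mean(-2 * ch$loglik)
  Kbar <- c(x2 = mean(ch$K[, 1]))
  Dhat <- -2 * as.numeric(log_likelihood(
    inst$model$y, inst$model$build_design(Kbar),
    colMeans(ch$V), mean(ch$sigma2)))
  expect_equal(d$value, 2 * dbar - Dhat, tolerance = 1e-10)
  # permutation invariance of the sample-based criteria
  perm <- sample(nrow(ch$pointwise))
  expect_equal(waic(ch$pointwise)$value, waic(ch$pointwise[perm, ])$value)
  expect_equal(cvic(ch$pointwise)$value, cvic(ch$pointwise[perm, ])$value)
})

test_that("degenerate posteriors collapse the criteria to their limits", {
  # constant pointwise matrix: p_waic = 0, WAIC = -2 sum(l), CVIC identical
  pw <- matrix(rep(c(log(0.3), log(0.6), log(0.9)), each = 4), nrow = 4)
  w <- waic(pw)
  expect_equal(w$diagnostics$p_waic, 0)
  expect_equal(w$value, -2 * sum(pw[1, ]))
  expect_equal(cvic(pw)$value, -2 * sum(pw[1, ]))
  # two-draw variance arithmetic: p_waic = (log 4)^2 / 2
  pw2 <- matrix(c(log(0.2), log(0.8)), ncol = 1)
  expect_equal(waic(pw2)$diagnostics$p_waic, log(4)^2 / 2)
  # one point, identical draws: elpd = log 0.5
  pw3 <- matrix(c(log(0.5), log(0.5)), ncol = 1)
  expect_equal(cvic(pw3)$value, -2 * log(0.5))
  expect_error(waic(pw2[1, , drop = FALSE]), "at least 2")
})

test_that("CVIC matches exact leave-one-out on a conjugate toy", {
  toy <- conjugate_toy(T_points = 5, d = 1, g = 1, a = 3, b = 2, seed = 53)
  ch <- run_chain(toy$model, iterations = 30000, burnin = 2000, thin = 2,
                  seed = 54)
  est <- cvic(ch)$value
  # exact LOO via evidence ratios: log p(y_j | y_-j) = log ev(all) - log ev(-j)
  loo <- vapply(seq_along(toy$y), function(j) {
    toy$log_evidence -
      semimech:::nig_log_evidence(toy$X[-j, , drop = FALSE], toy$y[-j],
                                  m0 = 1, V0 = matrix(1), a = 3, b = 2)
  }, 1)
  expect_within(est, -2 * sum(loo), 0.35)
})

test_that("WBIC runs at 1/log(T) and lands near the evidence on the toy", {
  toy <- conjugate_toy(T_points = 50, d = 2, seed = 55)
  wb <- wbic(toy$model, iterations = 3000, burnin = 800, thin = 2, seed = 56)
  expect_equal(wb$diagnostics$tau_star, 1 / log(50))
  expect_lt(abs(wb$value - toy$log_evidence), 2)
  expect_equal(wb$orientation, "higher")
})

test_that("pivot selection distinguishes naive from stabilized", {
  fake <- structure(list(history = list(
    logpost = c(-5, -2, -7),
    params = list(list(V = 1), list(V = 2), list(V = 3)),
    burnin = 1L, kept = 2:3)), class = "sm_chain")
  expect_equal(select_pivot(fake, "stabilized")$params$V, 2)
  expect_equal(select_pivot(fake, "naive")$params$V, 2)
  # burn-in state holds the global max: only naive picks it
  fake$history$logpost <- c(-1, -2, -7)
  expect_equal(select_pivot(fake, "naive")$params$V, 1)
  expect_equal(select_pivot(fake, "stabilized")$params$V, 2)
  # without burn-in the two strategies coincide
  fake$history$burnin <- 0L
  expect_equal(select_pivot(fake, "stabilized")$params$V, 1)
})

test_that("Chib's estimator matches quadrature on a degradation-only model", {
  dat <- generate_gradient_data(1, 0.1, T_points = 30, seed = 7)
  cfg <- run_config(iterations = 4000, burnin = 1000, thin = 2, chains = 1,
                    delta2_fixed = 2)
  model <- model_from_data(dat$ts, dat$grads, parent_set("x1", character()),
                           cfg)
  y <- model$y
  D <- model$build_design(numeric(0))
  f <- function(v0, s2) {
    vapply(seq_along(v0), function(i) {
      ll <- sum(dnorm(y, D %*% v0[i], sqrt(s2[i]), log = TRUE))
      lp <- dnorm(v0[i], 1, sqrt(2 * s2[i]), log = TRUE) -
        pnorm(0, 1, sqrt(2 * s2[i]), lower.tail = FALSE, log.p = TRUE) +
        dinvgamma(s2[i], 0.01, 0.01, log = TRUE)
      exp(ll + lp + 40)
    }, 1)
  }
  quad <- integrate(function(s2) vapply(s2, function(s)
    integrate(function(v0) f(v0, rep(s, length(v0))), 0, Inf,
              rel.tol = 1e-9)$value, 1), 0, Inf, rel.tol = 1e-8)
  lq <- log(quad$value) - 40
  ch <- chib_mll(model, seed = 8)
  expect_lt(abs(ch$value - lq), 0.1)
})

test_that("stabilized and naive pivots agree in the benign regime", {
  inst <- small_instance(seed = 57, T_points = 40,
                         cfg = run_config(iterations = 2500, burnin = 600,
                                          thin = 2, chains = 1,
                                          delta2_fixed = 1))
  set.seed(58)
  main <- run_chain(inst$model)
  s_stab <- semimech:::chib_from_main(inst$model, main, "stabilized",
                                      2500, 600, 2)
  s_naiv <- semimech:::chib_from_main(inst$model, main, "naive",
                                      2500, 600, 2)
  expect_lt(abs(s_stab$value - s_naiv$value), 0.5)
})

test_that("thermodynamic integration tracks the toy evidence and stays ordered", {
  toy <- conjugate_toy(T_points = 30, d = 2, seed = 59)
  ti <- ti_mll(toy$model, ladder_k = 8, ladder_m = 3, iterations = 1200,
               burnin = 300, thin = 2, seed = 60)
  expect_lt(abs(ti$value - toy$log_evidence), 1.5)
  # expected log-likelihood is non-decreasing along the ladder (MC slack)
  E <- ti$diagnostics$E
  expect_true(all(diff(E) > -2 * abs(E[1]) * 0.02 - 0.5))
  # ladder arithmetic: tau_1 = (1/10)^8, tau_10 = 1 under the default power
  taus <- (0:10 / 10)^8
  expect_equal(taus[2], 1e-8)
  expect_equal(taus[11], 1)
  # corrected trapezium subtracts the variance-difference term
  ti2 <- ti_mll(toy$model, ladder_k = 8, ladder_m = 3, iterations = 1200,
                burnin = 300, thin = 2, seed = 60, correction = "stab")
  V <- ti2$diagnostics$V
  dt <- diff(ti2$diagnostics$tau)
  expect_equal(ti2$value,
               sum(dt * (ti2$diagnostics$E[-1] + ti2$diagnostics$E[-9]) / 2) -
                 sum(dt^2 * (V[-1] - V[-9]) / 12),
               tolerance = 1e-10)
})

test_that("score differences orient every criterion the same way", {
  hi_a <- semimech:::new_score("chib", -10, orientation = "higher")
  hi_b <- semimech:::new_score("chib", -14, orientation = "higher")
  lo_a <- semimech:::new_score("waic", 20, orientation = "lower")
  lo_b <- semimech:::new_score("waic", 26, orientation = "lower")
  expect_equal(score_difference(hi_a, hi_b), 4)
  expect_equal(score_difference(hi_b, hi_a), -4)  # antisymmetry
  expect_equal(score_difference(lo_a, lo_b), 6)
  expect_error(score_difference(hi_a, lo_a))
})
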
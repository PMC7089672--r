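test_that("parent-set enumeration counts and ordering are deterministic", {
  sets <- enumerate_parent_sets("y", c("x2", "x3", "x4"), 3)
  expect_length(sets, 8L)
  sizes <- vapply(sets, function(p) length(p$regulators), 1L)
  expect_true(all(diff(sizes) >= 0))  # ordered by size
  labels <- vapply(sets, semimech:::parent_set_label, "")
  expect_equal(labels[1], "{}")
  expect_equal(labels[8], "{x2,x3,x4}")
  # binomial-sum oracle at 9 candidates: 1 + 9 + 36 + 84
  big <- enumerate_parent_sets("y", paste0("r", 1:9), 3)
  expect_length(big, 1 + 9 + choose(9, 2) + choose(9, 3))
  expect_length(enumerate_parent_sets("y", c("a", "b"), 0), 1L)
  # complex pairs attach only where both members are present
  cs <- enumerate_parent_sets("y", c("a", "b", "c"), 3,
                              complexes = list(c("a", "b")))
  with_pair <- vapply(cs, function(p) length(p$complexes) > 0, TRUE)
  both_in <- vapply(cs, function(p) all(c("a", "b") %in% p$regulators), TRUE)
  expect_equal(with_pair, both_in)
})

test_that("edge posteriors reduce to subset counting under equal scores", {
  sets <- enumerate_parent_sets("y", c("x2", "x3", "x4"), 3)
  sc <- data.frame(parents = vapply(sets, semimech:::parent_set_label, ""),
                   score = rep(-5, 8))
  attr(sc, "parent_sets") <- sets
  p <- edge_posterior(sc)
  expect_equal(unname(p), rep(0.5, 3))  # 4 of 8 subsets contain each node
  # dominance: one score 100 nats above the rest
  sc$score[2] <- 95   # the singleton {x2}
  p2 <- edge_posterior(sc)
  expect_gte(p2[["x2"]], 1 - 1e-15)
  expect_lt(p2[["x3"]], 1e-20)
  # normalization invariance under constant shifts
  sc$score <- sc$score + 123
  expect_equal(edge_posterior(sc), p2)
  # enumeration-order invariance
  perm <- sample(8)
  sc3 <- sc[perm, ]
  attr(sc3, "parent_sets") <- sets[perm]
  expect_equal(edge_posterior(sc3), p2)
  sc$score <- -Inf
  expect_error(edge_posterior(sc), "undefined posterior")
})

test_that("scoring recovers known truth and is seed-reproducible", {
  cfg <- run_config(iterations = 1200, burnin = 400, thin = 3, chains = 1,
                    criterion = "chib")
  # known-truth benchmark: {x2} must win
  dat <- generate_gradient_data(1, 0.05, T_points = 120, seed = 61)
  sc <- suppressWarnings(
    score_parent_sets(dat$ts, dat$grads, "x1", c("x2", "x3", "x4"),
                      cfg, seed = 62))
  expect_equal(sc$parents[which.max(sc$score)], "{x2}")
  sc2 <- suppressWarnings(
    score_parent_sets(dat$ts, dat$grads, "x1", c("x2", "x3", "x4"),
                      cfg, seed = 62))
  expect_identical(sc$score, sc2$score)

  # degradation-only data: the empty parent set should win in most seeds
  wins <- vapply(1:5, function(s) {
    reg <- generate_regressors(4, 100, seed = 70 + s)
    y <- -1.0 * reg$values[, "x1"] + rnorm(100, 0, sqrt(0.02))
    grads <- gradient_set(matrix(y, ncol = 1, dimnames = list(NULL, "x1")),
                          reg$times, "x1", reg$condition, "analytical")
    sc <- suppressWarnings(
      score_parent_sets(reg, grads, "x1", c("x2", "x3", "x4"), cfg,
                        seed = 80 + s))
    sc$parents[which.max(sc$score)] == "{}"
  }, TRUE)
  expect_gte(sum(wins), 4L)
})

test_that("product terms help when the dynamics contain complex formation", {
  # g3 is driven by the g1-g2 complex; a model with the product term should
  # outscore the additive-only model on such data in most seeds
  net <- network_spec(c("g1", "g2", "g3"),
                      edges = data.frame(regulator = c("g1", "g2"),
                                         target = c("g3", "g3"),
                                         sign = "activator"),
                      complexes = data.frame(regulator_a = "g1",
                                             regulator_b = "g2",
                                             target = "g3",
                                             sign_a = "activator",
                                             sign_b = "activator"))
  params <- list(v0 = c(g1 = 0.3, g2 = 0.4, g3 = 1),
                 complexes = data.frame(regulator_a = "g1",
                                        regulator_b = "g2", target = "g3",
                                        v = 3, k_a = 0.5, k_b = 0.5))
  cfg <- run_config(iterations = 1200, burnin = 400, thin = 3, chains = 1,
                    criterion = "chib")
  wins <- vapply(1:3, function(s) {
    # wide initial-state jitter decorrelates g1 and g2 across conditions,
    # otherwise the product surface is additively representable
    sim <- simulate_mm_network(net, params, times = seq(0, 24, by = 2),
                               x0 = c(g1 = 2, g2 = 1.5, g3 = 0.2),
                               noise_sd = 0.02, conditions = 6,
                               x0_jitter = c(0.15, 3), seed = 200 + s)
    grads <- gp_gradient(sim$ts, "rbf", restarts = 2, seed = 210 + s)
    ps_add <- parent_set("g3", c("g1", "g2"))
    ps_cpx <- parent_set("g3", c("g1", "g2"),
                         complexes = list(c("g1", "g2")))
    m_add <- model_from_data(sim$ts, grads, ps_add, cfg)
    m_cpx <- model_from_data(sim$ts, grads, ps_cpx, cfg)
    s_add <- suppressWarnings(chib_mll(m_add, seed = 220 + s))
    s_cpx <- suppressWarnings(chib_mll(m_cpx, seed = 220 + s))
    s_cpx$value > s_add$value
  }, TRUE)
  expect_gte(sum(wins), 2L)
})

test_that("network ranking identifies the generating topology", {
  netA <- network_spec(c("g1", "g2", "g3"),
                       edges = data.frame(
                         regulator = c("g1", "g2"), target = c("g2", "g3"),
                         sign = "activator"))
  netB <- network_spec(c("g1", "g2", "g3"),
                       edges = data.frame(
                         regulator = c("g3", "g3"), target = c("g1", "g2"),
                         sign = "activator"))
  paramsA <- default_network_params(netA, seed = 63)
  sim <- simulate_mm_network(netA, paramsA, times = seq(0, 24, by = 2),
                             x0 = c(g1 = 2, g2 = 0.3, g3 = 0.6),
                             noise_sd = 0.01, conditions = 4, seed = 64)
  grads <- gp_gradient(sim$ts, "rbf", restarts = 2, seed = 65)
  cfg <- run_config(iterations = 1200, burnin = 400, thin = 3, chains = 1,
                    criterion = "chib")
  rk <- suppressWarnings(
    rank_networks(sim$ts, grads, list(A = netA, B = netB), cfg, seed = 66))
  expect_equal(rk$rank[rk$network == "A"], 1L)
  # identical candidates tie, and totals are additive over targets
  rk2 <- suppressWarnings(
    rank_networks(sim$ts, grads, list(A = netA, A2 = netA), cfg, seed = 67))
  expect_equal(rk2$rank, c(1L, 1L))
  expect_equal(rk2$total_score[1], rk2$total_score[2])
})
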
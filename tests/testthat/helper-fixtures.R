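# Shared fixtures, all generated in code.

# small two-species table on an integer grid
tiny_ts <- function() {
  timeseries(matrix(c(1, 2, 3, 4, 5, 6), ncol = 2,
                    dimnames = list(NULL, c("a", "b"))),
             times = c(0, 2, 4))
}

# uniform-grid series of one function of time
fn_ts <- function(f, times = seq(0, 10, by = 1), name = "s") {
  timeseries(matrix(f(times), ncol = 1, dimnames = list(NULL, name)), times)
}

# short config for fast sampler tests
fast_cfg <- function(...) {
  run_config(iterations = 1200L, burnin = 400L, thin = 2L, chains = 1L, ...)
}

# a small benchmark instance plus its model
small_instance <- function(seed = 1, T_points = 40, setting = 1,
                           sigma2 = 0.05, regulators = "x2",
                           cfg = fast_cfg(), variant = "ridge") {
  dat <- generate_gradient_data(setting, sigma2, T_points, seed = seed)
  model <- model_from_data(dat$ts, dat$grads,
                           parent_set("x1", regulators), cfg, variant)
  list(dat = dat, model = model)
}

expect_within <- function(x, target, tol) {
  expect_true(abs(x - target) <= tol,
              label = sprintf("%.6g within %.3g of %.6g", x, tol, target))
}
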
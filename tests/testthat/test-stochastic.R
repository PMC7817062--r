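test_that("noise-free Langevin reproduces the deterministic run to O(dt)", {
  p <- std_params
  d <- simulate_switch("transition", p, k_X = 0.2, t_end = 15, dt_out = 0.1)
  # smooth (pre-jump) segment at dt = 1e-4
  l4 <- simulate_langevin("transition", p, k_X = 0.2, sigma = 0, dt = 1e-4,
                          t_end = 15, record_every = 1000)
  pre <- d$time < 10
  expect_lt(max(abs(l4$X[pre] - d$X[pre])), 1e-3)
  # full run including the jump at dt = 1e-5
  l5 <- simulate_langevin("transition", p, k_X = 0.2, sigma = 0, dt = 1e-5,
                          t_end = 15, record_every = 10000)
  expect_lt(max(abs(l5$X - d$X)), 1e-3)
})

test_that("transition times are measured by first crossing, with explicit no-transition", {
  tm <- seq(0, 10, by = 0.1)
  jump <- data.frame(time = tm, X = ifelse(tm >= 4.2, 2, 0.1))
  expect_equal(transition_time(jump, 1), 4.2, tolerance = 0.1)
  flat <- data.frame(time = tm, X = rep(0.1, length(tm)))
  expect_true(is.na(transition_time(flat, 1)))
  # deterministic transition happens when X_T reaches the right fold
  tr <- simulate_switch("transition", std_params, k_X = 1, t_end = 5)
  expect_equal(transition_time(tr, std_th$transition),
               max(std_folds$parameter), tolerance = 0.05 * 2.26)
})

test_that("cv_statistics implements the sample CV with its edge cases", {
  expect_equal(cv_statistics(c(2, 2, 2))$cv, 0)
  st <- cv_statistics(c(1, 3))
  expect_equal(st$mean, 2)
  expect_equal(st$sd, sqrt(2))
  expect_equal(st$cv, sqrt(2) / 2)
  expect_error(cv_statistics(3), "at least 2")
  expect_true(is.na(cv_statistics(c(-2, 0, 2))$cv))  # non-positive mean
})

test_that("stochastic runs are reproducible from their seed", {
  p <- std_params
  a <- simulate_ssa("transition", p, k_X = 1, omega = 20, t_end = 3, seed = 9)
  b <- simulate_ssa("transition", p, k_X = 1, omega = 20, t_end = 3, seed = 9)
  expect_identical(a$n_X, b$n_X)
  la <- simulate_langevin("transition", p, k_X = 1, sigma = 0.6, t_end = 3,
                          seed = 4)
  lb <- simulate_langevin("transition", p, k_X = 1, sigma = 0.6, t_end = 3,
                          seed = 4)
  expect_identical(la$X, lb$X)
})

test_that("SSA counts stay nonnegative integers and scale with omega", {
  p <- std_params
  s <- simulate_ssa("oscillator", p, k_X = 1.7, omega = 10, t_end = 30,
                    seed = 21)
  expect_true(all(s$n_X >= 0 & s$n_Y >= 0))
  expect_true(all(s$n_X == round(s$n_X)))
  expect_true(all(s$X <= s$X_T + 1e-12))
  # ensemble mean approaches the ODE as omega grows (full-window sup-norm)
  d <- simulate_switch("transition", p, k_X = 1, t_end = 4, dt_out = 0.01)
  err <- vapply(c(10, 50, 200), function(om) {
    ens <- vapply(1:25, function(r)
      simulate_ssa("transition", p, k_X = 1, omega = om, t_end = 4,
                   seed = 40 + r)$X, numeric(nrow(d)))
    max(abs(rowMeans(ens) - d$X))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("dynamic switching tightens Langevin transition timing", {
  p <- std_params
  ex <- run_timing_experiment("langevin", "transition",
                              conditions = data.frame(delta_a = c(0, 0.1,
                                                                  0.2, 0.3)),
                              params = p, replicates = 100, t_end = 6,
                              seed = 31)
  # sd monotone non-increasing in delta_a
  expect_true(all(diff(ex$sd) <= 0))
  expect_lt(ex$cv[ex$delta_a == 0.3], ex$cv[ex$delta_a == 0])
  # faster switch changes (kappa up) tighten timing further
  ek <- run_timing_experiment("langevin", "transition",
                              conditions = data.frame(delta_a = 0.3,
                                                      kappa = c(1, 5, 10)),
                              params = p, replicates = 100, t_end = 6,
                              seed = 32)
  expect_lt(ek$cv[ek$kappa == 10], ek$cv[ek$kappa == 1])
})
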
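test_that("constant production drives a sudden jump once X_T passes the right fold", {
  p <- std_params
  tr <- simulate_switch("transition", p, k_X = 0.2, t_end = 15)
  fold_XT <- max(std_folds$parameter)
  # X stays near the lower branch until the fold, then jumps
  before <- tr[tr$X_T < fold_XT - 0.1, ]
  expect_true(all(before$X < std_th$down))
  expect_gt(max(tr$X), std_th$up)
  tc <- transition_time(tr, std_th$transition)
  expect_equal(tc, fold_XT / 0.2, tolerance = 0.05)
})

test_that("delay tau = 0 coincides with the instantaneous modulation run", {
  p <- std_params
  m0 <- switch_modulation(0.3, 0.2, 5, X_c = std_Xc, tau = 0)
  mt <- switch_modulation(0.3, 0.2, 5, X_c = std_Xc, tau = 1e-9)
  t0 <- simulate_switch("transition", p, mod = m0, k_X = 0.2, t_end = 12)
  tt <- simulate_switch("transition", p, mod = mt, k_X = 0.2, t_end = 12)
  expect_lt(max(abs(t0$X - tt$X)), 1e-4)
  # a real delay changes the trajectory
  td <- simulate_switch("transition", p,
                        mod = switch_modulation(0.3, 0.2, 5, X_c = std_Xc,
                                                tau = 0.5),
                        k_X = 0.2, t_end = 12)
  expect_gt(max(abs(td$X - t0$X)), 1e-3)
})

test_that("period detector scores a square wave and rejects degenerate traces", {
  # square wave with up-crossings at t = 1, 3, 5
  tm <- seq(0, 6, by = 0.001)
  x <- ifelse((tm %% 2) >= 1, 2, 0)
  ps <- detect_period(data.frame(time = tm, X = x), up = 1.5, down = 0.5)
  expect_true(ps$oscillatory)
  expect_equal(ps$values, rep(2, length(ps$values)), tolerance = 1e-2)
  # monotone trace: non-oscillatory
  mono <- detect_period(data.frame(time = tm, X = tm), up = 4, down = 2)
  expect_equal(mono$n, 0)
  expect_lt(length(mono$up_times), 2)
  # wiggle around the up threshold only: crossings deduplicate, no cycle
  wig <- data.frame(time = tm, X = 1.5 + 0.3 * sin(2 * pi * tm))
  pw <- detect_period(wig, up = 1.5, down = 0.5)
  expect_lt(length(pw$up_times), 2)
  expect_equal(pw$n, 0)
})

test_that("amplitude detector recovers known envelopes", {
  tm <- seq(0, 20, by = 0.01)
  s <- data.frame(time = tm, X = sin(2 * pi * tm / 2))  # peak-to-trough 2
  as <- detect_amplitude(s)
  expect_true(as$oscillatory)
  expect_equal(mean(as$values), 2, tolerance = 0.02)
  # constant signal: none
  cs <- detect_amplitude(data.frame(time = tm, X = rep(1, length(tm))))
  expect_false(cs$oscillatory)
  # small noise leaves the envelope within 5%
  set.seed(2)
  ns <- data.frame(time = tm, X = sin(2 * pi * tm / 2) +
                     rnorm(length(tm), sd = 0.05))
  an <- detect_amplitude(ns)
  expect_equal(mean(an$values), 2, tolerance = 0.05)
})

test_that("deterministic oscillator has a cycle-to-cycle constant period", {
  tr <- simulate_switch("oscillator", std_params, k_X = 1.7, t_end = 100)
  ps <- detect_period(tr, std_th$up, std_th$down)
  per <- ps$values[-1]  # first cycle carries the start-up transient
  expect_gt(length(per), 20)
  expect_lt((max(per) - min(per)) / mean(per), 1e-4)
})

test_that("dropping the X^2 term changes the period only at O(epsilon)", {
  per <- function(params, full) {
    tr <- simulate_switch("oscillator", params, k_X = 1.7, t_end = 60,
                          full_model = full)
    mean(detect_period(tr, std_th$up, std_th$down)$values[-1])
  }
  d1 <- abs(per(feedback_params(epsilon = 0.05), TRUE) -
              per(feedback_params(epsilon = 0.05), FALSE))
  d2 <- abs(per(feedback_params(epsilon = 0.005), TRUE) -
              per(feedback_params(epsilon = 0.005), FALSE))
  expect_lt(d2, d1)        # difference shrinks with epsilon
  expect_lt(d1, 0.05)      # and is small already at 0.05
})

test_that("the slowly relaxing switch interpolates between its limits", {
  p <- std_params
  mod <- switch_modulation(0.3, 0.2, 5, X_c = std_Xc)
  per <- function(tr) mean(detect_period(tr, std_th$up, std_th$down)$values[-1])
  two <- simulate_switch("oscillator", p, mod = mod, k_X = 1.7, t_end = 60)
  fast <- simulate_switch("three_eq", p, mod = mod, k_X = 1.7, t_end = 60,
                          delta = 1e-3)
  expect_equal(per(fast), per(two), tolerance = 0.01)
  # very slow a stays nearly constant over a cycle
  slow <- simulate_switch("three_eq", p, mod = mod, k_X = 1.7, t_end = 100,
                          delta = 10)
  late <- slow[slow$time > 50, ]
  expect_lt(diff(range(late$a)), 0.1 * 2 * 0.2)
})

test_that("the oscillatory k_X interval widens with delta_a and with delay", {
  p <- std_params
  kg <- seq(0.8, 3, length.out = 12)
  reg <- oscillatory_region(p, kg, c(0, 0.3), t_end = 120)
  expect_true(all(diff(reg$intervals$width) >= 0))
  regt <- oscillatory_region(p, kg, 0.3, tau = 0.2, t_end = 120)
  expect_gt(regt$intervals$width, reg$intervals$width[2])
})
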
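test_that("brute-force steady states match limiting forms and root counts", {
  p <- std_params
  # X_T = 0: the only nonnegative root is 0
  ss0 <- steady_states(p, 0.3, 0)
  expect_equal(ss0$X, 0)
  # low-X_T limit: single stable root near a X_T / (a + a' + b')
  ss <- steady_states(p, 0.3, 0.1)
  expect_equal(nrow(ss), 1)
  expect_true(ss$stable)
  expect_equal(ss$X, 0.3 * 0.1 / (0.3 + 0.1 + 1), tolerance = 0.02)
  expect_equal(ss$X, 0.021429, tolerance = 1e-4)
  # inside the bistable band: stable / unstable / stable
  ssb <- steady_states(p, 0.3, 2)
  expect_equal(nrow(ssb), 3)
  expect_equal(ssb$stable, c(TRUE, FALSE, TRUE))
})

test_that("every continuation point satisfies the steady-state equation to 1e-8", {
  p <- std_params
  rc <- trace_response_curve(p, "X_T", c(0, 4), a_value = 0.3)
  res <- activation_rate(rc$X, p, 0.3) * (rc$parameter - rc$X) -
    inactivation_rate(rc$X, p) * rc$X
  expect_lt(max(abs(res)), 1e-8)
})

test_that("continuation agrees with brute force on random slices", {
  p <- std_params
  set.seed(7)
  for (i in 1:12) {
    a <- runif(1, 0.1, 0.6); xt <- runif(1, 0.1, 4)
    bf <- steady_states(p, a, xt)
    rc <- trace_response_curve(p, "X_T", c(0, 12), a_value = a)
    xs <- slice_response_curve(rc, xt)
    expect_equal(length(xs), nrow(bf))
    expect_lt(max(abs(xs - bf$X)), 1e-6)
  }
})

test_that("fold counts are 0 or 2 and fold residuals vanish", {
  p <- std_params
  for (a in c(0.05, 0.15, 0.3, 0.45, 0.6, 0.9)) {
    rc <- trace_response_curve(p, "X_T", c(0, 12), a_value = a)
    sn <- attr(rc, "saddle_nodes")
    expect_true(nrow(sn) %in% c(0, 2))
    if (nrow(sn) == 2) {
      res <- abs(activation_rate(sn$X, p, a) * (sn$parameter - sn$X) -
                   inactivation_rate(sn$X, p) * sn$X)
      expect_lt(max(res), 1e-8)
    }
  }
  # monotone (high-a) response has no folds and X increases with X_T
  rc <- trace_response_curve(p, "X_T", c(0, 4), a_value = 0.9)
  expect_equal(nrow(attr(rc, "saddle_nodes")), 0)
  expect_true(all(diff(rc$X) > -1e-12))
})

test_that("saddle-node coordinates agree with the brute-force fold scan", {
  p <- std_params
  bf <- sort(bruteforce_folds(p, 0.3))
  sn <- std_folds[order(std_folds$parameter), ]
  expect_equal(nrow(sn), 2)
  expect_equal(sn$parameter, bf, tolerance = 1e-4)
})

test_that("X_c is the mean of the fold coordinates and errors when undefined", {
  expect_equal(std_Xc, mean(std_folds$parameter), tolerance = 1e-10)
  expect_equal(std_Xc, mean(bruteforce_folds(std_params, 0.3)),
               tolerance = 1e-4)
  expect_error(midpoint_Xc(std_params, a_bar = 0.9), "not bistable")
})

test_that("event thresholds follow the saddle-node convention (up above down)", {
  th <- std_th
  sn <- std_folds[order(std_folds$parameter), ]
  expect_equal(th$up, sn$X[1])    # left fold: upper knee
  expect_equal(th$down, sn$X[2])  # right fold: lower knee
  expect_gt(th$up, th$down)
  expect_equal(th$transition, (th$up + th$down) / 2)
  expect_error(event_thresholds(std_params, 0.9), "not bistable")
})

test_that("varying a at fixed high total protein puts the left fold at a < 0", {
  rc <- trace_response_curve(std_params, "a", c(-0.8, 1), X_T = 2.5)
  sn <- attr(rc, "saddle_nodes")
  expect_equal(nrow(sn), 2)
  expect_lt(min(sn$parameter), 0)  # irreversible switch
  expect_gt(max(sn$parameter), 0)
})

test_that("two-parameter region boundary agrees with brute-force root counts", {
  p <- std_params
  reg <- bistable_region_2d(p, a_grid = c(0.1, 0.2, 0.3, 0.5, 0.9),
                            X_T_max = 12)
  # high-a slices are monostable and contribute nothing
  expect_false(0.9 %in% reg$a)
  expect_true(all(c(0.1, 0.2, 0.3) %in% reg$a))
  for (i in seq_len(nrow(reg))) {
    mid <- (reg$X_T_lo[i] + reg$X_T_hi[i]) / 2
    expect_equal(nrow(steady_states(p, reg$a[i], mid)), 3)
    expect_equal(nrow(steady_states(p, reg$a[i], reg$X_T_hi[i] + 0.2)), 1)
  }
  # the a = 0.3 slice reproduces the standard thresholds
  i <- which(reg$a == 0.3)
  expect_equal(c(reg$X_T_lo[i], reg$X_T_hi[i]), sort(std_folds$parameter),
               tolerance = 1e-6)
})
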
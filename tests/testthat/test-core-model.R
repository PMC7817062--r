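test_that("activation and inactivation rate laws match their closed forms", {
  p <- std_params
  # basal, half-saturation and saturation values of f
  expect_equal(activation_rate(0, p, a_value = 0.3), 0.3)
  expect_equal(activation_rate(1, p, a_value = 0.3), 0.8)  # X = K
  expect_equal(activation_rate(1e6, p, a_value = 0.3), 1.3, tolerance = 1e-6)
  # g at zero, half-saturation and saturation
  expect_equal(inactivation_rate(0, p), 1.1)
  expect_equal(inactivation_rate(1, p), 0.6)  # X = K'
  expect_equal(inactivation_rate(1e6, p), 0.1, tolerance = 1e-6)
  expect_error(activation_rate(-0.1, p), "X must be")
  expect_error(inactivation_rate(-0.1, p), "X must be")
})

test_that("f is increasing and g decreasing on a grid, with stated bounds", {
  p <- std_params
  xs <- seq(0, 10, length.out = 500)
  f <- activation_rate(xs, p, a_value = 0.3)
  g <- inactivation_rate(xs, p)
  expect_true(all(diff(f) > 0))
  expect_true(all(diff(g) < 0))
  expect_true(all(f <= 0.3 + p$b))
  expect_true(all(g >= p$a_prime))
})

test_that("the modulation law is centred, bounded and monotone", {
  mod <- switch_modulation(a_bar = 0.3, delta_a = 0.2, kappa = 5, X_c = 1.9)
  expect_equal(modulated_a(1.9, mod), 0.3)           # tanh(0) = 0
  expect_equal(modulated_a(100, mod), 0.5, tolerance = 1e-10)
  mod0 <- switch_modulation(a_bar = 0.3, delta_a = 0, kappa = 5, X_c = 1.9)
  expect_equal(modulated_a(c(0, 1, 5), mod0), rep(0.3, 3))  # static switch
  xts <- seq(0, 5, length.out = 200)
  av <- modulated_a(xts, mod)
  expect_true(all(av >= 0.3 - 0.2 & av <= 0.3 + 0.2))
  expect_true(all(diff(av) > 0))
  neg <- switch_modulation(a_bar = 0.3, delta_a = -0.2, kappa = 5, X_c = 1.9)
  expect_true(all(diff(modulated_a(xts, neg)) < 0))
})

test_that("transition right-hand side matches hand computation and vanishes at roots", {
  p <- std_params
  d <- rhs_transition(c(X = 0, X_T = 1), p, k_X = 0.5)
  expect_equal(unname(d["X"]), 0.3 * 1 / 0.05)  # eps^-1 a X_T = 6
  expect_equal(unname(d["X_T"]), 0.5)
  # fully active: first term vanishes, dX = -eps^-1 g(X) X
  d2 <- rhs_transition(c(X = 1.5, X_T = 1.5), p, k_X = 0)
  expect_equal(unname(d2["X"]),
               -inactivation_rate(1.5, p) * 1.5 / p$epsilon)
  # at a bisection root of the scalar kinetics the derivative is zero
  r <- uniroot(function(x) activation_rate(x, p, 0.3) * (2 - x) -
                 inactivation_rate(x, p) * x, c(0, 0.5), tol = 1e-14)$root
  d3 <- rhs_transition(c(X = r, X_T = 2), p, k_X = 0.2)
  expect_equal(unname(d3["X"]), 0, tolerance = 1e-9)
})

test_that("oscillator variants differ by exactly the X^2 degradation term", {
  p <- std_params
  for (st in list(c(X = 0.2, X_T = 1), c(X = 1.2, X_T = 2.5),
                  c(X = 0.7, X_T = 1.8))) {
    s <- rhs_oscillator(st, p, k_X = 1.7)
    f <- rhs_oscillator(st, p, k_X = 1.7, full_model = TRUE)
    expect_equal(unname(f["X"]), unname(s["X"] - st[["X"]]^2))
    expect_equal(unname(f["X_T"]), unname(s["X_T"]))
  }
  # on the second nullcline X = k_X / X_T the slow variable is stationary
  st <- c(X = 1.7 / 2, X_T = 2)
  expect_equal(unname(rhs_oscillator(st, p, k_X = 1.7)["X_T"]), 0)
  # pure accumulation at X = 0
  expect_equal(unname(rhs_oscillator(c(X = 0, X_T = 1), p, k_X = 1.7)["X_T"]),
               1.7)
})

test_that("three-equation model is at rest when a sits at H(X_T)", {
  p <- std_params
  mod <- switch_modulation(0.3, 0.2, 5, X_c = 1.9)
  H <- modulated_a(2.2, mod)
  d <- rhs_three_equation(c(X = 0.5, X_T = 2.2, a = H), p, mod,
                          k_X = 1.7, delta = 0.01)
  expect_equal(unname(d["a"]), 0)
  d2 <- rhs_three_equation(c(X = 0.5, X_T = 2.2, a = H + 0.1), p, mod,
                           k_X = 1.7, delta = 0.1)
  expect_equal(unname(d2["a"]), -1)  # (H - a)/delta
})

test_that("parameter validation enforces the documented invariants", {
  expect_error(feedback_params(a = -0.1), "'a'")
  expect_error(feedback_params(b = 0), "'b'")
  expect_error(feedback_params(n = 0.5), "Hill exponents")
  expect_error(feedback_params(epsilon = 1.5), "epsilon")
  expect_error(switch_modulation(a_bar = -1))
  expect_error(switch_modulation(tau = -0.1))
  # non-integer Hill exponents are allowed
  expect_s3_class(feedback_params(n = 2.5, m = 3.7), "feedback_params")
})

test_that("deterministic trajectories preserve 0 <= X <= X_T", {
  p <- std_params
  for (kx in c(0.2, 1)) {
    tr <- simulate_switch("transition", p, k_X = kx, t_end = 8)
    expect_true(all(tr$X >= -1e-6))
    expect_true(all(tr$X <= tr$X_T + 1e-6))
  }
  tr <- simulate_switch("oscillator", p, k_X = 1.7, t_end = 50)
  expect_true(all(tr$X >= -1e-6 & tr$X <= tr$X_T + 1e-6))
})
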
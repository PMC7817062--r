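#' Activation and inactivation rate laws
#'
#' `activation_rate()` evaluates the positive-feedback activation rate
#' \eqn{f(X) = a + b X^n / (K^n + X^n)}; `inactivation_rate()` the inhibited
#' inactivation rate \eqn{g(X) = a' + b' K'^m / (K'^m + X^m)}. Both are
#' vectorised over `X`. The basal rate can be overridden through `a_value`,
#' so a static, instantaneously modulated, delayed or slowly relaxing `a`
#' all share this code path.
#'
#' @param X active protein concentration(s), \eqn{\ge 0}.
#' @param params a [feedback_params()] object.
#' @param a_value basal activation rate to use; defaults to `params$a`.
#' @return Rate(s), 1/time. `f` is strictly increasing in `X` and bounded by
#'   `a_value + b`; `g` strictly decreasing and bounded below by `a_prime`.
#' @examples
#' p <- feedback_params()
#' activation_rate(c(0, 1), p, a_value = 0.3)  # 0.3, 0.8
#' inactivation_rate(c(0, 1), p)               # 1.1, 0.6
#' @export
activation_rate <- function(X, params, a_value = params$a) {
  if (any(X < 0)) stop("activation_rate: X must be >= 0")
  Xn <- X^params$n
  a_value + params$b * Xn / (params$K^params$n + Xn)
}

#' @rdname activation_rate
#' @export
inactivation_rate <- function(X, params) {
  if (any(X < 0)) stop("inactivation_rate: X must be >= 0")
  Km <- params$K_prime^params$m
  params$a_prime + params$b_prime * Km / (Km + X^params$m)
}

#' Evaluate the dynamic-switch law a(X_T)
#'
#' @param X_T total protein concentration(s).
#' @param mod a [switch_modulation()] object with a concrete `X_c`.
#' @return Basal rate(s) in `[a_bar - |delta_a|, a_bar + |delta_a|]`,
#'   monotone in `X_T` with the sign of `delta_a`.
#' @export
modulated_a <- function(X_T, mod) {
  if (is.null(mod$X_c)) {
    stop("modulated_a: X_c is unset; resolve it first (see midpoint_Xc)")
  }
  mod$a_bar + mod$delta_a * tanh(mod$kappa * (X_T - mod$X_c))
}

# Scalar steady-state residual F(X) = f(X)(X_T - X) - g(X) X and its
# partial derivatives. The whole continuation/threshold machinery rests on
# this one function. X is clipped at 0 before powers so tiny negative
# integrator overshoot cannot produce NaN from non-integer exponents.
switch_residual <- function(X, X_T, params, a_value = params$a) {
  X <- pmax(X, 0)
  activation_rate(X, params, a_value) * (X_T - X) -
    inactivation_rate(X, params) * X
}

switch_residual_dX <- function(X, X_T, params, a_value = params$a) {
  X <- pmax(X, 0)
  n <- params$n; m <- params$m
  Kn <- params$K^n; Km <- params$K_prime^m
  Xn <- X^n; Xm <- X^m
  f <- a_value + params$b * Xn / (Kn + Xn)
  g <- params$a_prime + params$b_prime * Km / (Km + Xm)
  fp <- ifelse(X > 0, params$b * n * Kn * Xn / (X * (Kn + Xn)^2),
               ifelse(n == 1, params$b / Kn, 0))
  gp <- ifelse(X > 0, -params$b_prime * Km * m * Xm / (X * (Km + Xm)^2),
               ifelse(m == 1, -params$b_prime / Km, 0))
  fp * (X_T - X) - f - gp * X - g
}

# dF/dX_T = f(X); dF/da = X_T - X (since df/da = 1)
switch_residual_dXT <- function(X, X_T, params, a_value = params$a) {
  activation_rate(pmax(X, 0), params, a_value)
}
switch_residual_da <- function(X, X_T, params, a_value = params$a) {
  X_T - pmax(X, 0)
}

#' Right-hand sides of the deterministic model variants
#'
#' Reference R implementations of the time derivatives of the three
#' non-spatial deterministic models:
#' \describe{
#'   \item{`rhs_transition()`}{\eqn{dX/dt = \epsilon^{-1}(f(X)(X_T-X) -
#'     g(X)X)}, \eqn{dX_T/dt = k_X}: protein produced at a constant rate
#'     drives the system across the activation threshold.}
#'   \item{`rhs_oscillator()`}{production and degradation,
#'     \eqn{dX_T/dt = k_X - X_T X}; by default the \eqn{-X^2} self-degradation
#'     term is dropped from the `X` equation so the static response curve is
#'     exactly a nullcline (`full_model = TRUE` restores it; the two differ
#'     by absorbing \eqn{\epsilon X} into \eqn{g}).}
#'   \item{`rhs_three_equation()`}{adds \eqn{da/dt = \delta^{-1}(H(X_T)-a)}
#'     so the switch shape relaxes towards the modulation law on its own
#'     timescale \eqn{\delta}.}
#' }
#' When `mod` is supplied (and the state carries no slow `a`), the basal
#' rate is evaluated instantaneously as `modulated_a(X_T, mod)`.
#'
#' These R versions are the definitional forms used in tests; the
#' integrators call compiled equivalents.
#'
#' @param state named numeric vector: `X`, `X_T` (and `a` for the
#'   three-equation model).
#' @param params a [feedback_params()] object.
#' @param mod optional [switch_modulation()] (with concrete `X_c`);
#'   `NULL` means a static switch at `params$a`.
#' @param k_X protein production rate (1/time).
#' @param full_model include the \eqn{-X^2} term in the `X` equation.
#' @param delta relaxation timescale of `a` (three-equation model only).
#' @return Named numeric vector of time derivatives.
#' @export
rhs_transition <- function(state, params, mod = NULL, k_X) {
  a <- if (is.null(mod)) params$a else modulated_a(state[["X_T"]], mod)
  dX <- switch_residual(state[["X"]], state[["X_T"]], params, a) / params$epsilon
  c(X = unname(dX), X_T = k_X)
}

#' @rdname rhs_transition
#' @export
rhs_oscillator <- function(state, params, mod = NULL, k_X, full_model = FALSE) {
  X <- state[["X"]]; X_T <- state[["X_T"]]
  a <- if (is.null(mod)) params$a else modulated_a(X_T, mod)
  dX <- switch_residual(X, X_T, params, a) / params$epsilon
  if (full_model) dX <- dX - X^2
  c(X = unname(dX), X_T = k_X - X_T * X)
}

#' @rdname rhs_transition
#' @export
rhs_three_equation <- function(state, params, mod, k_X, delta) {
  stopifnot(delta > 0)
  X <- state[["X"]]; X_T <- state[["X_T"]]; a <- state[["a"]]
  dX <- switch_residual(X, X_T, params, a) / params$epsilon
  H <- modulated_a(X_T, mod)
  c(X = unname(dX), X_T = k_X - X_T * X, a = unname((H - a) / delta))
}
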
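#' Kinetic parameters of the two-feedback switch
#'
#' Constructs and validates the parameter set of the activation/inactivation
#' kinetics \eqn{dX/dt = f(X)(X_T - X) - g(X) X}, where
#' \eqn{f(X) = a + b X^n / (K^n + X^n)} is the positive-feedback activation
#' rate and \eqn{g(X) = a' + b' K'^m / (K'^m + X^m)} the inhibited
#' inactivation rate. The defaults are the standard set used throughout the
#' package: \code{b = 1}, \code{K = 1}, \code{n = 5}, \code{a_prime = 0.1},
#' \code{b_prime = 1}, \code{K_prime = 1}, \code{m = 5},
#' \code{epsilon = 0.05}. The basal activation rate \code{a} is the
#' parameter that shapes the switch and is varied (or dynamically modulated)
#' in most experiments; its default here is 0.3.
#'
#' @param a basal activation rate (1/time, \eqn{\ge 0}).
#' @param b maximal feedback activation rate (1/time).
#' @param K activation half-saturation constant (concentration).
#' @param n activation Hill exponent (\eqn{\ge 1}).
#' @param a_prime residual inactivation rate (1/time).
#' @param b_prime maximal inactivation rate (1/time).
#' @param K_prime inactivation half-saturation constant (concentration).
#' @param m inactivation Hill exponent (\eqn{\ge 1}).
#' @param epsilon timescale separation factor (dimensionless, \eqn{\le 1});
#'   activation/inactivation run a factor \eqn{1/\epsilon} faster than
#'   production/degradation.
#'
#' @return An object of class \code{"feedback_params"} (a named list).
#' @examples
#' p <- feedback_params()
#' activation_rate(1, p)   # a + b/2 at half-saturation
#' @export
feedback_params <- function(a = 0.3, b = 1, K = 1, n = 5,
                            a_prime = 0.1, b_prime = 1, K_prime = 1, m = 5,
                            epsilon = 0.05) {
  p <- list(a = a, b = b, K = K, n = n,
            a_prime = a_prime, b_prime = b_prime, K_prime = K_prime, m = m,
            epsilon = epsilon)
  lapply(p, function(v) stopifnot(is.numeric(v), length(v) == 1L, is.finite(v)))
  if (p$a < 0) stop("'a' must be >= 0")
  pos <- c("b", "K", "a_prime", "b_prime", "K_prime", "epsilon")
  for (nm in pos) if (p[[nm]] <= 0) stop(sprintf("'%s' must be > 0", nm))
  if (p$n < 1 || p$m < 1) stop("Hill exponents 'n' and 'm' must be >= 1")
  if (p$epsilon > 1) stop("'epsilon' must be <= 1")
  structure(p, class = "feedback_params")
}

#' @export
print.feedback_params <- function(x, ...) {
  cat("Feedback kinetics parameters\n")
  cat(sprintf("  f(X) = %g + %g X^%g / (%g^%g + X^%g)\n",
              x$a, x$b, x$n, x$K, x$n, x$n))
  cat(sprintf("  g(X) = %g + %g * %g^%g / (%g^%g + X^%g)\n",
              x$a_prime, x$b_prime, x$K_prime, x$m, x$K_prime, x$m, x$m))
  cat(sprintf("  timescale separation epsilon = %g\n", x$epsilon))
  invisible(x)
}

#' Dynamic-switch modulation law
#'
#' Describes how the basal activation rate \eqn{a} is coupled to the total
#' protein level: \eqn{a(X_T) = \bar a + \Delta a \tanh(\kappa (X_T - X_c))}.
#' With \code{delta_a = 0} the switch is static. A positive \code{delta_a}
#' lowers the activation threshold as \eqn{X_T} rises (the threshold moves
#' towards the approaching system); a negative one moves it away. The
#' midpoint \code{X_c} is, by convention, the centre of the two saddle-node
#' \eqn{X_T}-coordinates of the static switch at \eqn{a = \bar a}; leave it
#' \code{NULL} to have it computed by \code{\link{midpoint_Xc}} when the
#' modulation is first used with a concrete parameter set. An optional lag
#' \code{tau} makes the coupling read the past:
#' \eqn{a(t) = a(X_T(t - \tau))}.
#'
#' @param a_bar centre value of \eqn{a} (1/time, > 0).
#' @param delta_a modulation amplitude (1/time; may be negative).
#' @param kappa modulation steepness (1/concentration).
#' @param X_c modulation midpoint (concentration), or \code{NULL} for the
#'   saddle-node-midpoint convention.
#' @param tau time delay (\eqn{\ge 0}).
#'
#' @return An object of class \code{"switch_modulation"}.
#' @examples
#' mod <- switch_modulation(a_bar = 0.3, delta_a = 0.2, kappa = 5, X_c = 1.9)
#' modulated_a(c(0, 1.9, 10), mod)
#' @export
switch_modulation <- function(a_bar = 0.3, delta_a = 0, kappa = 5,
                              X_c = NULL, tau = 0) {
  stopifnot(is.numeric(a_bar), length(a_bar) == 1L, a_bar > 0,
            is.numeric(delta_a), length(delta_a) == 1L,
            is.numeric(kappa), length(kappa) == 1L, kappa > 0,
            is.null(X_c) || (is.numeric(X_c) && length(X_c) == 1L),
            is.numeric(tau), length(tau) == 1L, tau >= 0)
  structure(list(a_bar = a_bar, delta_a = delta_a, kappa = kappa,
                 X_c = X_c, tau = tau),
            class = "switch_modulation")
}

#' @export
print.switch_modulation <- function(x, ...) {
  xc <- if (is.null(x$X_c)) "<saddle-node midpoint>" else format(x$X_c)
  cat(sprintf("Switch modulation: a(X_T) = %g %+g * tanh(%g (X_T - %s))\n",
              x$a_bar, x$delta_a, x$kappa, xc))
  if (x$tau > 0) cat(sprintf("  with delay tau = %g\n", x$tau))
  invisible(x)
}

# Fill in X_c (saddle-node midpoint convention) if the user left it NULL.
resolve_mod <- function(mod, params) {
  if (is.null(mod)) return(NULL)
  if (is.null(mod$X_c)) mod$X_c <- midpoint_Xc(params, mod$a_bar)
  mod
}
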
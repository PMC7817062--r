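# Shared parameter vector for the compiled right-hand sides (src/models.c,
# src/ssa.cpp). Order matters and must match the C layout.
parms_vector <- function(params, mod = NULL, k_X = 0, delta = 1,
                         full_model = FALSE, t0 = 0, XT0 = 0) {
  c(params$b, params$K, params$n, params$a_prime, params$b_prime,
    params$K_prime, params$m, params$epsilon,
    k_X, params$a,
    as.numeric(!is.null(mod)),
    if (is.null(mod)) c(0, 0, 1, 0) else c(mod$a_bar, mod$delta_a,
                                           mod$kappa, mod$X_c),
    if (is.null(mod)) 0 else mod$tau,
    delta, as.numeric(full_model), t0, XT0)
}

new_trajectory <- function(df, model, params, mod = NULL, k_X = NA,
                           seed = NULL, extra = list()) {
  attr(df, "model") <- model
  attr(df, "params") <- params
  attr(df, "mod") <- mod
  attr(df, "k_X") <- k_X
  attr(df, "seed") <- seed
  for (nm in names(extra)) attr(df, nm) <- extra[[nm]]
  class(df) <- c("switch_trajectory", "data.frame")
  df
}

#' @export
print.switch_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory of model '%s': %d samples on t in [%g, %g]\n",
              attr(x, "model"), nrow(x), min(x$time), max(x$time)))
  cat("  variables:", paste(setdiff(names(x), "time"), collapse = ", "), "\n")
  if (!is.null(attr(x, "seed"))) cat("  seed:", attr(x, "seed"), "\n")
  invisible(x)
}

#' Integrate the deterministic model variants
#'
#' Simulates one of the non-spatial deterministic models with an adaptive
#' stiff-aware solver (deSolve's `lsoda`, rtol 1e-8 / atol 1e-10; the
#' \eqn{1/\epsilon} kinetics make the fast variable moderately stiff):
#' \describe{
#'   \item{`"transition"`}{constant production \eqn{dX_T/dt = k_X} drives
#'     the system across the activation threshold.}
#'   \item{`"oscillator"`}{production and active-state-driven degradation,
#'     \eqn{dX_T/dt = k_X - X_T X}; set `full_model = TRUE` to keep the
#'     \eqn{-X^2} term in the `X` equation.}
#'   \item{`"three_eq"`}{adds \eqn{da/dt = \delta^{-1}(H(X_T) - a)}, the
#'     switch shape relaxing on its own timescale.}
#' }
#' A modulation with `tau > 0` turns the run into a delay differential
#' equation, integrated with a cubic-interpolated history
#' (deSolve's `dede`); the history before the start is the constant initial
#' state.
#'
#' @param model one of `"transition"`, `"oscillator"`, `"three_eq"`.
#' @param params a [feedback_params()] object.
#' @param mod optional [switch_modulation()]; `NULL` for a static switch at
#'   `params$a`. An unset `X_c` is resolved by the saddle-node midpoint
#'   convention.
#' @param k_X protein production rate.
#' @param init named initial state (`X`, `X_T`, and `a` for `"three_eq"`);
#'   default starts empty and inactive (`X = 0`, `X_T = 0`).
#' @param t_end end time.
#' @param dt_out output sampling interval.
#' @param delta relaxation timescale of `a` (three-equation model).
#' @param full_model keep the \eqn{-X^2} degradation term (oscillator).
#' @return A `"switch_trajectory"` data.frame with columns `time`, `X`,
#'   `X_T` (and `a`).
#' @examples
#' p <- feedback_params()
#' tr <- simulate_switch("transition", p, k_X = 0.2, t_end = 15)
#' @export
simulate_switch <- function(model = c("transition", "oscillator", "three_eq"),
                            params, mod = NULL, k_X,
                            init = NULL, t_end, dt_out = 0.01,
                            delta = 1, full_model = FALSE) {
  model <- match.arg(model)
  stopifnot(t_end > 0)
  mod <- resolve_mod(mod, params)
  if (model == "three_eq" && is.null(mod))
    stop("the three-equation model needs a switch_modulation")
  if (is.null(init)) {
    init <- c(X = 0, X_T = 0)
    if (model == "three_eq")
      init <- c(init, a = unname(modulated_a(init[["X_T"]], mod)))
  }
  times <- seq(0, t_end, by = dt_out)
  pv <- parms_vector(params, mod, k_X, delta, full_model,
                     t0 = 0, XT0 = init[["X_T"]])
  delayed <- !is.null(mod) && mod$tau > 0 && model != "three_eq"
  func <- switch(model,
                 transition = if (delayed) "d_transition_dde" else "d_transition",
                 oscillator = if (delayed) "d_oscillator_dde" else "d_oscillator",
                 three_eq = "d_three_eq")
  args <- list(y = init, times = times, func = func, parms = pv,
               dllname = "dynswitch", initfunc = "initmod",
               rtol = 1e-8, atol = 1e-10)
  out <- if (delayed) do.call(deSolve::dede, args)
         else do.call(deSolve::lsoda, args)
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("integration of model '%s' failed (istate = %d)",
                 model, attr(out, "istate")[1]))
  df <- as.data.frame(out)
  names(df)[1] <- "time"
  new_trajectory(df, model, params, mod, k_X,
                 extra = list(delta = if (model == "three_eq") delta else NULL,
                              full_model = full_model))
}
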
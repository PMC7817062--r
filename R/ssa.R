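#' Discrete stochastic simulation (Gillespie direct method)
#'
#' Simulates the switch with integer molecule counts `n_X` (active) and
#' `n_Y` (inactive) at system size `omega` (molecules per unit
#' concentration). Reactions: activation (propensity
#' \eqn{\epsilon^{-1} f(n_X, a)\, n_Y}), inactivation
#' (\eqn{\epsilon^{-1} g(n_X)\, n_X}), production (\eqn{k_X \Omega}), and
#' -- for the oscillator only -- degradation of inactive
#' (\eqn{n_X n_Y/\Omega}) and active (\eqn{n_X(n_X-1)/\Omega}) protein.
#' Each degradation event consumes one molecule of the degraded species,
#' the active partner acting catalytically, which reproduces the
#' deterministic degradation flux \eqn{-X\,X_T} exactly. Concentration
#' -scale constants are \eqn{\Omega}-scaled: half-saturations become
#' \eqn{\Omega K}, the modulation steepness \eqn{\kappa/\Omega} and
#' midpoint \eqn{\Omega X_c}. The modulated basal rate is re-evaluated
#' after every reaction.
#'
#' @param model `"transition"` (no degradation) or `"oscillator"`.
#' @param params a [feedback_params()] object.
#' @param mod optional [switch_modulation()] (delay is not supported in
#'   the discrete model).
#' @param k_X production rate (concentration/time).
#' @param omega system size, integer \eqn{\ge 1}.
#' @param t_end end time.
#' @param init_counts named integer vector `c(n_X=, n_Y=)`; defaults to
#'   `n_X = 0`, `n_Y = 0` (empty system; production fills it).
#' @param dt_out output sampling interval.
#' @param seed optional RNG seed (recorded).
#' @param threshold optional concentration threshold; the first-passage
#'   time of `n_X` above `ceiling(omega * threshold)` is returned in the
#'   `first_passage` attribute.
#' @return A `"switch_trajectory"` with integer-count columns `n_X`,
#'   `n_Y` and concentration columns `X = n_X/omega`,
#'   `X_T = (n_X + n_Y)/omega`.
#' @export
simulate_ssa <- function(model = c("transition", "oscillator"),
                         params, mod = NULL, k_X, omega, t_end,
                         init_counts = c(n_X = 0, n_Y = 0),
                         dt_out = 0.01, seed = NULL, threshold = NULL) {
  model <- match.arg(model)
  stopifnot(omega >= 1, omega == round(omega), t_end > 0)
  mod <- resolve_mod(mod, params)
  if (!is.null(mod) && mod$tau > 0)
    stop("delayed modulation is not available in the discrete model")
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, t_end, by = dt_out)
  pv <- parms_vector(params, mod, k_X)
  res <- ssa_simulate_cpp(pv, omega,
                          init_counts[["n_X"]], init_counts[["n_Y"]],
                          times, model == "oscillator",
                          if (is.null(threshold)) -1
                          else ceiling(omega * threshold))
  df <- data.frame(time = times, n_X = res$n_X, n_Y = res$n_Y,
                   X = res$n_X / omega, X_T = (res$n_X + res$n_Y) / omega)
  new_trajectory(df, paste0("ssa_", model), params, mod, k_X, seed = seed,
                 extra = list(omega = omega,
                              first_passage = res$first_passage))
}
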
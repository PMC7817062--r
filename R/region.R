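#' Classify a run as sustainably oscillatory
#'
#' Applies the threshold-crossing period detector and requires at least
#' two retained up-crossings, the last of them in the final half of the
#' run (so damped transients do not count), and a mean period above
#' `min_period`.
#'
#' @inheritParams detect_period
#' @param min_period minimum mean period to count as oscillating.
#' @return The mean detected period, or 0 for a non-oscillatory run.
#' @export
sustained_period <- function(traj, up, down, min_period = 0.01) {
  ps <- detect_period(traj, up, down)
  if (ps$n < 1 || length(ps$up_times) < 2) return(0)
  t_end <- max(traj$time)
  if (max(ps$up_times) < t_end / 2) return(0)
  P <- mean(ps$values)
  if (!is.finite(P) || P <= min_period) return(0)
  P
}

#' Map the oscillatory region in the (k_X, delta_a) plane
#'
#' Simulates the production--degradation oscillator on a grid of production
#' rates and modulation amplitudes and records the detected period (0 when
#' the run is not sustainably oscillatory). The k_X interval supporting
#' oscillations widens as `delta_a` increases, and a modulation delay `tau`
#' extends the low-`k_X` side further.
#'
#' @param params a [feedback_params()] object.
#' @param k_X_grid,delta_a_grid numeric grids.
#' @param a_bar centre basal rate of the switch.
#' @param kappa modulation steepness.
#' @param tau modulation delay.
#' @param t_end simulated time per cell.
#' @param dt_out output sampling interval.
#' @return list with `period` (matrix, rows = `delta_a_grid`, cols =
#'   `k_X_grid`), `intervals` (data.frame `delta_a`, `k_lo`, `k_hi`,
#'   `width` of the oscillatory k_X interval on the grid), and the grids.
#' @export
oscillatory_region <- function(params, k_X_grid, delta_a_grid,
                               a_bar = 0.3, kappa = 5, tau = 0,
                               t_end = 200, dt_out = 0.02) {
  Xc <- midpoint_Xc(params, a_bar)
  th <- event_thresholds(params, a_bar)
  period <- matrix(0, nrow = length(delta_a_grid), ncol = length(k_X_grid),
                   dimnames = list(delta_a = delta_a_grid, k_X = k_X_grid))
  for (i in seq_along(delta_a_grid)) {
    da <- delta_a_grid[i]
    mod <- if (da == 0 && tau == 0) NULL
           else switch_modulation(a_bar, da, kappa, X_c = Xc, tau = tau)
    base <- if (is.null(mod)) feedback_params(a = a_bar, b = params$b,
              K = params$K, n = params$n, a_prime = params$a_prime,
              b_prime = params$b_prime, K_prime = params$K_prime,
              m = params$m, epsilon = params$epsilon) else params
    for (j in seq_along(k_X_grid)) {
      tr <- simulate_switch("oscillator", base, mod = mod, k_X = k_X_grid[j],
                            t_end = t_end, dt_out = dt_out)
      period[i, j] <- sustained_period(tr, th$up, th$down)
    }
  }
  intervals <- do.call(rbind, lapply(seq_along(delta_a_grid), function(i) {
    osc <- which(period[i, ] > 0)
    if (length(osc) == 0)
      data.frame(delta_a = delta_a_grid[i], k_lo = NA_real_, k_hi = NA_real_,
                 width = 0)
    else
      data.frame(delta_a = delta_a_grid[i], k_lo = k_X_grid[min(osc)],
                 k_hi = k_X_grid[max(osc)],
                 width = k_X_grid[max(osc)] - k_X_grid[min(osc)])
  }))
  list(period = period, intervals = intervals,
       k_X_grid = k_X_grid, delta_a_grid = delta_a_grid,
       a_bar = a_bar, kappa = kappa, tau = tau)
}

# Default sampling ranges for the random parameter survey. These bracket
# the standard parameter set; epsilon is sampled log-uniformly.
survey_default_ranges <- function() {
  list(a = c(0.05, 0.6), a_prime = c(0.01, 0.5),
       b = c(0.5, 2), b_prime = c(0.5, 2),
       K = c(0.5, 2), K_prime = c(0.5, 2),
       n = c(2, 8), m = c(2, 8),
       k_X = c(0.5, 3), epsilon = c(0.01, 1))
}

#' Random parameter survey of oscillation propensity
#'
#' Samples `n_sets` feedback parameter sets uniformly and independently
#' from `ranges` (log-uniformly for `epsilon`), checks each set for static
#' bistability by continuation, and, for bistable sets, simulates the
#' oscillator under every combination of modulation strength
#' `delta_a = i * a` (`i` in `i_multipliers`), steepness `kappa`, and delay
#' `tau`. A run counts as oscillating when the threshold-crossing detector
#' finds a sustained period above `min_period`. Non-bistable sets count as
#' non-oscillating under every condition.
#'
#' @param n_sets number of parameter sets to sample.
#' @param ranges named list of length-2 ranges (see
#'   `survey_default_ranges`); all entries user-overridable.
#' @param i_multipliers modulation amplitudes as multiples of the sampled
#'   basal rate `a`.
#' @param kappa_set,tau_set modulation steepness and delay values to cross.
#' @param t_end simulated time per run.
#' @param min_period minimum period to count as oscillating.
#' @param seed RNG seed (recorded in the result).
#' @return data.frame with one row per (i, kappa, tau) condition: columns
#'   `i`, `kappa`, `tau`, `n_osc`, `fraction`; attributes `n_sets`,
#'   `n_bistable`, `seed`, and `sets` (the sampled parameter table with a
#'   bistability flag).
#' @export
random_survey <- function(n_sets = 500,
                          ranges = survey_default_ranges(),
                          i_multipliers = c(-1, -0.5, 0, 0.5, 1),
                          kappa_set = c(1, 5, 10),
                          tau_set = c(0, 0.1, 0.2),
                          t_end = 200, min_period = 0.01, seed = 1) {
  set.seed(seed)
  defaults <- survey_default_ranges()
  ranges <- modifyList(defaults, ranges)
  draw <- function(nm) runif(n_sets, ranges[[nm]][1], ranges[[nm]][2])
  sets <- data.frame(a = draw("a"), a_prime = draw("a_prime"),
                     b = draw("b"), b_prime = draw("b_prime"),
                     K = draw("K"), K_prime = draw("K_prime"),
                     n = draw("n"), m = draw("m"), k_X = draw("k_X"),
                     epsilon = exp(runif(n_sets, log(ranges$epsilon[1]),
                                         log(ranges$epsilon[2]))))
  cond <- expand.grid(i = i_multipliers, kappa = kappa_set, tau = tau_set,
                      KEEP.OUT.ATTRS = FALSE)
  n_osc <- integer(nrow(cond))
  bistable <- logical(n_sets)
  for (s in seq_len(n_sets)) {
    par <- feedback_params(a = sets$a[s], b = sets$b[s], K = sets$K[s],
                           n = sets$n[s], a_prime = sets$a_prime[s],
                           b_prime = sets$b_prime[s],
                           K_prime = sets$K_prime[s], m = sets$m[s],
                           epsilon = sets$epsilon[s])
    folds <- tryCatch(static_folds(par, par$a), error = function(e) NULL)
    bistable[s] <- !is.null(folds)
    if (!bistable[s]) next
    Xc <- mean(folds$parameter)
    up <- folds$X[1]; down <- folds$X[2]
    if (!(up > down)) next  # degenerate near-cusp switch: no usable thresholds
    for (ci in seq_len(nrow(cond))) {
      mod <- if (cond$i[ci] == 0 && cond$tau[ci] == 0) NULL
             else switch_modulation(par$a, cond$i[ci] * par$a, cond$kappa[ci],
                                    X_c = Xc, tau = cond$tau[ci])
      tr <- tryCatch(
        simulate_switch("oscillator", par, mod = mod, k_X = sets$k_X[s],
                        t_end = t_end, dt_out = 0.05),
        error = function(e) NULL)
      if (is.null(tr)) next
      if (sustained_period(tr, up, down, min_period) > 0)
        n_osc[ci] <- n_osc[ci] + 1L
    }
  }
  out <- cbind(cond, n_osc = n_osc, fraction = n_osc / n_sets)
  attr(out, "n_sets") <- n_sets
  attr(out, "n_bistable") <- sum(bistable)
  attr(out, "seed") <- seed
  attr(out, "sets") <- cbind(sets, bistable = bistable)
  out
}
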